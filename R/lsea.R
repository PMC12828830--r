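# Lipid set enrichment analysis: weighted Kolmogorov-Smirnov running-sum
# enrichment score over species ranked by effect size, with a set-label
# permutation null yielding NES and p per subclass set.

#' Rank species by effect size
#'
#' Orders species by the ranking metric (log2 fold change, descending); ties
#' are broken by species name (lexicographic) so the order is a strict total
#' order and deterministic.
#'
#' @param stats [species_tests()] output (or any data frame with `name` and
#'   a metric column).
#' @param metric Metric column name (default `"log2fc"`).
#' @return Data frame `name`, `metric`, ordered top to bottom.
#' @export
rank_species <- function(stats, metric = "log2fc") {
  ord <- order(-stats[[metric]], stats$name)
  data.frame(name = stats$name[ord], metric = stats[[metric]][ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' The GSEA-style statistic: walking down the ranked list, set hits add
#' `|metric|^p` (normalised over the set's hits), misses subtract
#' `1/(N - n_set)`; ES is the signed maximum deviation of the running sum.
#'
#' @param ranked [rank_species()] output.
#' @param members Species names in the set.
#' @param p Weight exponent (default 1; `p = 0` gives the classic
#'   Kolmogorov-Smirnov statistic).
#' @return ES in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, members, p = 1) {
  hit <- ranked$name %in% members
  n <- nrow(ranked); nh <- sum(hit)
  if (nh == 0L) stop("set has no members on the ranked list")
  if (nh == n) stop("set covers the whole ranked list; miss weight undefined")
  w <- abs(ranked$metric)^p
  inc <- numeric(n)
  sw <- sum(w[hit])
  if (sw == 0) inc[hit] <- 1 / nh else inc[hit] <- w[hit] / sw
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  # signed maximum deviation; a tie (to within rounding) resolves to the
  # positive extremum
  hi <- max(rs); lo <- min(rs)
  if (hi >= -lo - 1e-9) hi else lo
}

#' NES and permutation p for one set
#'
#' Set-label permutation null: set membership is reshuffled over the ranked
#' list (same set size), `n_perm` times under a fixed seed.
#' `NES = ES / mean(|ES_perm|)` over same-sign permutations; the one-sided p
#' is the frequency of same-sign `|ES_perm| >= |ES|` with the +1 continuity
#' correction. When no permutation matches the observed sign, p is reported
#' as `1/(n_perm + 1)` (i.e. "< 1/n_perm") and NES falls back to the
#' all-permutation mean magnitude.
#'
#' @param ranked [rank_species()] output.
#' @param members Set member names.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param p Weight exponent passed to [enrichment_score()].
#' @return List: `es`, `nes`, `p`, `direction` (+1/-1), `n_perm`.
#' @export
nes_and_p <- function(ranked, members, n_perm = 1000, seed = 1, p = 1) {
  stopifnot(n_perm >= 100)
  es <- enrichment_score(ranked, members, p = p)
  nh <- sum(ranked$name %in% members)
  n <- nrow(ranked)
  perm <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      enrichment_score(ranked, ranked$name[sample.int(n, nh)], p = p)
    }, 0)
  })
  same <- sign(perm) == sign(es)
  if (any(same)) {
    nes <- es / mean(abs(perm[same]))
    pval <- (1 + sum(same & abs(perm) >= abs(es))) / (1 + sum(same))
  } else {
    nes <- es / mean(abs(perm))
    pval <- 1 / (n_perm + 1)
  }
  list(es = es, nes = nes, p = pval,
       direction = sign(es), n_perm = n_perm)
}

#' Build subclass x base lipid sets from a panel
#'
#' One set per (subclass, merged base class) combination with at least
#' `min_size` members, labelled `"<subclass> | <base>"` (e.g.
#' `"HexCer | C18-SPH/D"`).
#'
#' @param panel Panel data frame.
#' @param min_size Minimum set size (default 3).
#' @return Named list of character vectors (member species).
#' @export
build_lipid_sets <- function(panel, min_size = 3) {
  key <- paste(panel$subclass, "|", panel$spb_merged)
  sets <- split(panel$name, key)
  sets[lengths(sets) >= min_size]
}

#' Lipid set enrichment analysis
#'
#' Ranks species by log2 fold change over all tested (QC-passing) species
#' (`significant_only` restricts the list to `p_adj < alpha` first) and
#' scores every set.
#'
#' @param stats [species_tests()] output.
#' @param sets Named list of sets (see [build_lipid_sets()]).
#' @param n_perm Permutations per set (default 1000).
#' @param seed RNG seed (recorded in the output).
#' @param min_size Sets smaller than this on the ranked list are skipped.
#' @param significant_only Rank only species with `p_adj < alpha`.
#' @param alpha Significance cut for `significant_only`.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p`, `direction`;
#'   attribute `seed`.
#' @export
lsea <- function(stats, sets, n_perm = 1000, seed = 1, min_size = 3,
                 significant_only = FALSE, alpha = 0.01) {
  use <- if (significant_only) stats[stats$p_adj < alpha, , drop = FALSE] else stats
  ranked <- rank_species(use)
  res <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], ranked$name)
    if (length(members) < min_size || length(members) >= nrow(ranked)) return(NULL)
    r <- nes_and_p(ranked, members, n_perm = n_perm, seed = seed + i)
    data.frame(set = names(sets)[i], size = length(members),
               es = r$es, nes = r$nes, p = r$p, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, seed = seed)
}

#' Write the LSEA result TSV
#'
#' @param x [lsea()] output.
#' @param path File path.
#' @export
write_lsea <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
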