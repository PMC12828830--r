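# Random-effects meta-analysis of per-dataset differential-expression
# effects (DerSimonian-Laird), plus the per-study effect computation used
# for synthetic studies.

#' Sphingolipid-pathway gene lists
#'
#' The default genes tracked by the meta-analysis: lysosomal degradation
#' hydrolases and de novo ceramide-synthesis enzymes.
#'
#' @return Named list of character vectors (`lysosomal`, `synthesis`).
#' @export
default_gene_sets <- function() {
  list(
    lysosomal = c("GBA1", "GLB1", "GLA", "NEU1", "NEU3", "NEU4",
                  "HEXA", "HEXB", "GM2A"),
    synthesis = c("SPTLC1", "SPTLC2", "SPTLC3", "SPTSSA", "SPTSSB", "KDSR",
                  "CERS1", "CERS2", "CERS3", "CERS4", "CERS5", "CERS6",
                  "DEGS1", "DEGS2", "FADS3")
  )
}

#' Study effect from two-group summary statistics
#'
#' log2 fold change and its standard error from per-group means (on the
#' log2 expression scale), standard deviations and sizes:
#' `log2FC = mean_case - mean_ctrl`,
#' `SE = sqrt(sd_case^2/n_case + sd_ctrl^2/n_ctrl)`.
#'
#' @param mean_case,sd_case,n_case Case-group summary.
#' @param mean_ctrl,sd_ctrl,n_ctrl Control-group summary.
#' @return List: `log2fc`, `se`, `n_case`, `n_control`.
#' @export
effect_from_group_stats <- function(mean_case, sd_case, n_case,
                                    mean_ctrl, sd_ctrl, n_ctrl) {
  if (any(c(sd_case, sd_ctrl) <= 0) || any(c(n_case, n_ctrl) < 2))
    stop("need sd > 0 and n >= 2 in both groups")
  list(log2fc = mean_case - mean_ctrl,
       se = sqrt(sd_case^2 / n_case + sd_ctrl^2 / n_ctrl),
       n_case = n_case, n_control = n_ctrl)
}

#' Convert a symmetric 95% CI to a standard error
#'
#' `SE = (upper - lower) / (2 * 1.959964)`, assuming a normal Wald interval.
#'
#' @param ci_low,ci_high Interval bounds.
#' @return Standard error.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' DerSimonian-Laird random-effects pool
#'
#' Fixed-effect weights `w = 1/SE^2` give the heterogeneity statistic
#' `Q = sum w (y - ybar)^2`; the method-of-moments between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1/(SE^2 + tau2)` give the pooled estimate with a Wald 95% CI,
#' and `I2 = max(0, (Q - (k-1))/Q) * 100`. A single study returns itself
#' (`tau2 = 0`, `I2 = 0`). An optional REML estimator of tau2 is available
#' behind `method = "REML"`.
#'
#' @param y Per-study effects (log2FC).
#' @param se Per-study standard errors (all > 0).
#' @param method `"DL"` (default) or `"REML"`.
#' @return List: `k`, `estimate`, `se`, `ci` (length 2), `p` (two-sided
#'   Wald), `tau2`, `Q`, `i2`, `weights` (random-effects, percent).
#' @export
dl_pool <- function(y, se, method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(y)
  if (k == 0L) stop("no studies to pool")
  if (length(se) != k || any(!is.finite(se)) || any(se <= 0))
    stop("every study needs a finite SE > 0")
  w <- 1 / se^2
  yfix <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yfix)^2)
  if (method == "DL" || k == 1L) {
    tau2 <- if (k > 1L) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  } else {
    tau2 <- .reml_tau2(y, se)
  }
  wr <- 1 / (se^2 + tau2)
  est <- sum(wr * y) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  z <- stats::qnorm(0.975)
  i2 <- if (k > 1L && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(k = k, estimate = est, se = se_p,
       ci = c(est - z * se_p, est + z * se_p),
       p = 2 * stats::pnorm(-abs(est / se_p)),
       tau2 = tau2, Q = Q, i2 = i2,
       weights = 100 * wr / sum(wr))
}

# restricted maximum-likelihood tau2 by 1-d optimisation
.reml_tau2 <- function(y, se) {
  nll <- function(t2) {
    v <- se^2 + t2
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  stats::optimize(nll, c(0, max((max(y) - min(y))^2, 1e-6)))$minimum
}

#' Pool every gene in a long study-effect table
#'
#' @param effects Data frame: `dataset`, `gene`, `log2fc`, `se` (or
#'   `ci_low`/`ci_high`, converted via [se_from_ci()]), optional `n_case`,
#'   `n_control`.
#' @param method Pooling method, see [dl_pool()].
#' @return Data frame, one row per gene: `gene`, `k`, `pooled_log2fc`,
#'   `ci_low`, `ci_high`, `p`, `tau2`, `Q`, `i2`.
#' @export
pool_genes <- function(effects, method = "DL") {
  if (!"se" %in% names(effects)) {
    if (!all(c("ci_low", "ci_high") %in% names(effects)))
      stop("effects need an 'se' column or 'ci_low'/'ci_high'")
    effects$se <- se_from_ci(effects$ci_low, effects$ci_high)
  }
  res <- lapply(split(effects, effects$gene), function(d) {
    pe <- dl_pool(d$log2fc, d$se, method = method)
    data.frame(gene = d$gene[1], k = pe$k, pooled_log2fc = pe$estimate,
               ci_low = pe$ci[1], ci_high = pe$ci[2], p = pe$p,
               tau2 = pe$tau2, Q = pe$Q, i2 = pe$i2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Forest-plot table for one gene
#'
#' Per-study rows (estimate, 95% CI, random-effects weight percent) followed
#' by the pooled row; weights sum to 100.
#'
#' @param effects Study-effect table for one gene (`dataset`, `log2fc`,
#'   `se`).
#' @param method Pooling method.
#' @return Data frame: `row` (dataset id or `"pooled"`), `log2fc`,
#'   `ci_low`, `ci_high`, `weight_percent`.
#' @export
forest_table <- function(effects, method = "DL") {
  if (!"se" %in% names(effects))
    effects$se <- se_from_ci(effects$ci_low, effects$ci_high)
  pe <- dl_pool(effects$log2fc, effects$se, method = method)
  z <- stats::qnorm(0.975)
  rbind(
    data.frame(row = as.character(effects$dataset),
               log2fc = effects$log2fc,
               ci_low = effects$log2fc - z * effects$se,
               ci_high = effects$log2fc + z * effects$se,
               weight_percent = pe$weights,
               stringsAsFactors = FALSE),
    data.frame(row = "pooled", log2fc = pe$estimate,
               ci_low = pe$ci[1], ci_high = pe$ci[2],
               weight_percent = 100, stringsAsFactors = FALSE)
  )
}

#' Read / write study-effect TSVs
#'
#' Input TSV per dataset: `gene`, `log2fc`, `se` (or `ci_low`, `ci_high`),
#' `n_case`, `n_control`; output TSV per [pool_genes()].
#'
#' @param x Data frame.
#' @param path File path.
#' @name meta_io
#' @export
write_study_effects <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname meta_io
#' @export
read_study_effects <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc") %in% names(d)))
    stop("study-effect table lacks 'gene'/'log2fc'")
  d
}
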