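# MRM annotation: theoretical masses, transition library construction, and
# matching of vendor peak lists by precursor/product m/z and retention time.

# monoisotopic atomic masses (Da); D = deuterium
.atomic_mass <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, D = 2.01410177785)
.PROTON <- 1.007276466
.WATER  <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]

# glycosyl residue increments (condensed, i.e. free sugar minus H2O)
.residues <- list(
  hexose = c(C = 6L,  H = 10L, N = 0L, O = 5L),
  hexnac = c(C = 8L,  H = 13L, N = 1L, O = 5L),
  neuac  = c(C = 11L, H = 17L, N = 1L, O = 8L)
)

#' Elemental formula of a neutral sphingolipid species
#'
#' Assembles the ceramide core (sphingoid base condensed with the fatty acyl,
#' losing one water) and adds glycosyl residues per the head class: each
#' hexose contributes C6H10O5, each HexNAc C8H13NO5 and each NeuAc C11H17NO8.
#' Deuterium labels (internal standards) are carried as element `D`, replacing
#' the corresponding hydrogens.
#'
#' @param species A `sphingolipid_species` or a name parseable by
#'   [parse_species_name()].
#' @return Named integer vector over elements `C`, `H`, `N`, `O` (and `D`
#'   when labelled).
#' @examples
#' elemental_formula("Cer 18:1;O2/24:0")  # C42 H83 N O3
#' @export
elemental_formula <- function(species) {
  if (is.character(species)) species <- parse_species_name(species)
  # free sphingoid base: Cn H(2n+3-2db) N O(oh)
  f <- c(C = species$base_c,
         H = 2L * species$base_c + 3L - 2L * species$base_db,
         N = 1L,
         O = species$base_oh)
  # fatty acid Cm H(2m-2db) O2 (+O if 2-hydroxy); amide condensation loses H2O
  f <- f + c(C = species$acyl_c,
             H = 2L * species$acyl_c - 2L * species$acyl_db - 2L,
             N = 0L,
             O = 2L + species$acyl_oh - 1L)
  hg <- .head_groups[.head_groups$class_label == species$head_class, ]
  f <- f + hg$hexoses * .residues$hexose +
           hg$hexnac  * .residues$hexnac +
           hg$neuac   * .residues$neuac
  f <- as.integer(round(f)); names(f) <- c("C", "H", "N", "O")
  d <- species$deuterium
  if (!is.null(d) && d > 0L) {
    f[["H"]] <- f[["H"]] - d
    f <- c(f, D = d)
  }
  f
}

#' Monoisotopic mass of a formula
#'
#' @param formula Named integer vector of element counts (elements among
#'   C, H, N, O, D).
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  el <- names(formula)
  bad <- setdiff(el, names(.atomic_mass))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(.atomic_mass[el] * as.numeric(formula))
}

#' Adduct m/z for a neutral formula
#'
#' Positive-mode adducts used for ceramide/glycosphingolipid MRM.
#'
#' @param formula Named element-count vector (see [elemental_formula()]), or
#'   a single neutral mass in Da.
#' @param adduct One of `"[M+H]+"`, `"[M+H-H2O]+"`, `"[M+NH4]+"`.
#' @return Monoisotopic m/z (singly charged).
#' @examples
#' adduct_mz(elemental_formula("Cer 18:1;O2/24:0"), "[M+H]+")  # 650.6446
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  m <- if (is.numeric(formula) && is.null(names(formula)) && length(formula) == 1L)
    formula else monoisotopic_mass(formula)
  switch(adduct,
    "[M+H]+"     = m + .PROTON,
    "[M+H-H2O]+" = m + .PROTON - .WATER,
    "[M+NH4]+"   = m + .PROTON + 3 * .atomic_mass[["H"]] + .atomic_mass[["N"]],
    stop("unknown adduct label '", adduct, "'")
  )
}

#' Sphingoid-base fragment m/z
#'
#' Convention for the MRM product ion: the long-chain-base fragment
#' `[SPB + H - 2 H2O]+` (e.g. m/z 264.27 for an 18:1;O2 base). This is a
#' library-construction convention, flagged as such: the acquisition's actual
#' product ions are instrument-method specific. Deuterium labels are assumed
#' to sit on the acyl chain, so the base fragment is unlabelled.
#'
#' @param species A `sphingolipid_species` or parseable name.
#' @return Product-ion m/z in Da.
#' @export
spb_fragment_mz <- function(species) {
  if (is.character(species)) species <- parse_species_name(species)
  base <- c(C = species$base_c,
            H = 2L * species$base_c + 3L - 2L * species$base_db,
            N = 1L,
            O = species$base_oh)
  monoisotopic_mass(base) + .PROTON - 2 * .WATER
}

# deterministic retention-time model over the 11-min gradient: longer and
# more saturated species elute later; glycosylation advances elution
.predict_rt <- function(panel) {
  tc <- panel$base_c + panel$acyl_c
  db <- panel$base_db + panel$acyl_db
  oh <- (panel$base_oh - 2L) + panel$acyl_oh
  sugars <- with(.head_groups[match(panel$head_class, .head_groups$class_label), ],
                 hexoses + hexnac + 2 * neuac)
  rt <- 1.0 + 0.38 * (tc - 26) - 0.35 * db - 0.3 * oh - 0.55 * sugars
  pmin(10.8, pmax(0.25, rt))
}

#' Build an MRM transition library for a panel
#'
#' One transition per species: precursor = `[M+H]+` of the intact species
#' (class-default adduct, configurable per class), product = the sphingoid
#' base fragment, expected retention time from a deterministic elution model
#' over the 11-min gradient.
#'
#' @param panel Panel data frame ([parse_species_names()] output); may
#'   include internal-standard species (deuterated names).
#' @param adducts Named character vector mapping head classes to adduct
#'   labels; classes not named use `"[M+H]+"`.
#' @return Data frame: `name`, `adduct`, `precursor_mz`, `product_mz`,
#'   `expected_rt`.
#' @export
build_transition_library <- function(panel, adducts = character()) {
  sps <- lapply(panel$name, parse_species_name)
  adduct <- ifelse(panel$head_class %in% names(adducts),
                   unname(adducts[panel$head_class]), "[M+H]+")
  prec <- vapply(seq_along(sps), function(i)
    adduct_mz(elemental_formula(sps[[i]]), adduct[i]), 0)
  prod <- vapply(sps, spb_fragment_mz, 0)
  data.frame(name = panel$name, adduct = adduct,
             precursor_mz = prec, product_mz = prod,
             expected_rt = .predict_rt(panel),
             stringsAsFactors = FALSE)
}

#' Match acquired peaks to a transition library
#'
#' A peak matches a library entry when both precursor and product m/z lie
#' within `mz_tol` of the entry's transition. Among candidates the assignment
#' is greedy by increasing |RT delta| (deterministic nearest-RT tie-break);
#' each peak is annotated to at most one entry and each entry claims at most
#' one peak per injection.
#'
#' @param peaks Data frame with columns `injection_id`, `rt`, `precursor_mz`,
#'   `product_mz`, `area`.
#' @param library Data frame as from [build_transition_library()].
#' @param mz_tol m/z gate half-width in Da (default 0.3, unit-resolution
#'   quadrupole).
#' @param rt_tol Retention-time gate half-width in minutes (default 0.3).
#' @return List with `annotated` (peak columns plus `name`, `rt_delta`,
#'   `mz_delta`) and `unmatched` (unassigned peaks).
#' @export
match_peaks <- function(peaks, library, mz_tol = 0.3, rt_tol = 0.3) {
  stopifnot(mz_tol > 0, rt_tol > 0)
  req <- c("injection_id", "rt", "precursor_mz", "product_mz", "area")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stop("peak list lacks column(s): ", paste(miss, collapse = ", "))
  if (any(peaks$area < 0, na.rm = TRUE)) stop("negative peak areas")

  # duplicate transitions at identical RT are a library configuration error
  # (entries sharing a transition but separated in RT are legal dynamic-MRM
  # practice and resolved by the nearest-RT rule)
  if (nrow(library) > 1L) {
    key <- paste(round(library$precursor_mz / mz_tol), round(library$product_mz / mz_tol))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      rts <- sort(library$expected_rt[idx])
      if (any(diff(rts) < 1e-6))
        stop("library entries with identical transition and RT: ",
             paste(library$name[idx], collapse = ", "))
    }
  }

  np <- nrow(peaks)
  cand_peak <- integer(0); cand_lib <- integer(0); cand_drt <- numeric(0)
  for (j in seq_len(nrow(library))) {
    hit <- which(abs(peaks$precursor_mz - library$precursor_mz[j]) <= mz_tol &
                 abs(peaks$product_mz  - library$product_mz[j])  <= mz_tol &
                 abs(peaks$rt          - library$expected_rt[j]) <= rt_tol)
    if (length(hit)) {
      cand_peak <- c(cand_peak, hit)
      cand_lib  <- c(cand_lib, rep.int(j, length(hit)))
      cand_drt  <- c(cand_drt, peaks$rt[hit] - library$expected_rt[j])
    }
  }

  assigned_lib <- rep(NA_integer_, np)
  rt_delta <- rep(NA_real_, np)
  if (length(cand_peak)) {
    # greedy by |rt delta|; stable order for exact ties via (peak, lib) index
    ord <- order(abs(cand_drt), cand_peak, cand_lib)
    taken_entry <- new.env(hash = TRUE, parent = emptyenv())
    for (i in ord) {
      p <- cand_peak[i]
      if (!is.na(assigned_lib[p])) next
      ekey <- paste0(cand_lib[i], "\r", peaks$injection_id[p])
      if (!is.null(taken_entry[[ekey]])) next
      assigned_lib[p] <- cand_lib[i]
      rt_delta[p] <- cand_drt[i]
      taken_entry[[ekey]] <- TRUE
    }
  }

  ok <- !is.na(assigned_lib)
  annotated <- peaks[ok, , drop = FALSE]
  annotated$name <- library$name[assigned_lib[ok]]
  annotated$rt_delta <- rt_delta[ok]
  annotated$mz_delta <- annotated$precursor_mz - library$precursor_mz[assigned_lib[ok]]
  rownames(annotated) <- NULL
  unmatched <- peaks[!ok, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(annotated = annotated, unmatched = unmatched)
}

#' Read / write transition library and peak-list CSVs
#'
#' Vendor-export style CSVs with a header row.
#'
#' @param x Library or peak-list data frame.
#' @param path File path.
#' @name annotation_io
#' @export
write_transition_library <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_transition_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "precursor_mz", "product_mz", "expected_rt")
  miss <- setdiff(req, names(lib))
  if (length(miss)) stop("library lacks column(s): ", paste(miss, collapse = ", "))
  lib
}

#' @rdname annotation_io
#' @export
write_peak_list <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_peak_list <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("injection_id", "rt", "precursor_mz", "product_mz", "area")
  miss <- setdiff(req, names(pk))
  if (length(miss)) stop("peak list lacks column(s): ", paste(miss, collapse = ", "))
  pk
}
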