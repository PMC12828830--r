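# Pooled-QC anchored quality control: drift correction across and within
# batches, pooled-QC CV, dilution-series linearity, and species admission.

#' QC-anchored drift correction
#'
#' For each species and batch, the pooled-QC responses define a
#' piecewise-linear trend over injection order (nearest-QC extrapolation
#' beyond the bracketing QCs). Each injection's area is divided by the local
#' trend and rescaled by the grand median of all pooled-QC responses for that
#' species, aligning batches to a common QC level. Deterministic: repeated
#' application on drift-free data is the identity.
#'
#' A batch with fewer than two pooled QCs triggers a warning and falls back
#' to median-only scaling (flat trend at the batch QC median, or no scaling
#' when the batch has no QC at all).
#'
#' @param areas Numeric matrix, injections x species; rownames are injection
#'   ids matching `sequence$injection_id`.
#' @param sequence Injection-sequence manifest: `injection_id`, `role`
#'   (`study`/`pooled_qc`/`dilution_qc`), `batch`, `order`.
#' @return Matrix of corrected areas, same shape as `areas`.
#' @export
correct_drift <- function(areas, sequence) {
  stopifnot(is.matrix(areas), !is.null(rownames(areas)))
  seq_use <- sequence[match(rownames(areas), sequence$injection_id), , drop = FALSE]
  if (anyNA(seq_use$injection_id))
    stop("areas contain injections absent from the sequence manifest")
  is_qc <- seq_use$role == "pooled_qc"
  if (sum(is_qc) < 1L) stop("no pooled-QC injections in the sequence")

  corrected <- areas
  grand_med <- apply(areas[is_qc, , drop = FALSE], 2L, stats::median, na.rm = TRUE)

  for (b in unique(seq_use$batch)) {
    rows <- which(seq_use$batch == b)
    qc_rows <- rows[is_qc[rows]]
    ord <- seq_use$order[rows]
    if (length(qc_rows) < 2L) {
      warning("batch '", b, "' has ", length(qc_rows),
              " pooled QC(s); applying median-only scaling")
      if (length(qc_rows) == 1L) {
        trend <- areas[qc_rows, , drop = FALSE][rep(1L, length(rows)), , drop = FALSE]
      } else next
      corrected[rows, ] <- areas[rows, , drop = FALSE] / trend *
        rep(grand_med, each = length(rows))
      next
    }
    qc_ord <- seq_use$order[qc_rows]
    o <- order(qc_ord)
    qc_ord <- qc_ord[o]; qc_rows <- qc_rows[o]
    for (j in seq_len(ncol(areas))) {
      y <- areas[qc_rows, j]
      ok <- is.finite(y) & y > 0
      if (sum(ok) < 2L) next  # cannot estimate a trend for this species
      trend <- stats::approx(qc_ord[ok], y[ok], xout = ord, rule = 2)$y
      corrected[rows, j] <- areas[rows, j] / trend * grand_med[j]
    }
  }
  corrected
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` (sample standard deviation). Undefined (NA) when the
#' mean is non-positive or fewer than two finite values remain.
#'
#' @param x Numeric vector of pooled-QC responses for one species.
#' @return CV in percent, or `NA_real_`.
#' @export
compute_cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Default dilution-factor series
#'
#' The 13-point serial dilution of the pooled QC used for the
#' signal-concentration linearity gate.
#'
#' @return Numeric vector of dilution factors.
#' @export
default_dilution_factors <- function() {
  c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000)
}

#' Dilution-series linearity R^2
#'
#' Ordinary least squares of `log(area)` on `log(1/DF)`; the log-log scale
#' keeps the four-decade dilution range from being dominated by the
#' undiluted point. Points with zero or missing area (signal below detection
#' at high dilution) are dropped before the fit and counted; fewer than four
#' usable points leaves R^2 undefined (species rejected).
#'
#' @param areas Areas at each dilution point (one species).
#' @param dilution_factors Matching dilution factors (default the 13-point
#'   series).
#' @return R^2 with attribute `n_used`, or `NA_real_` (attribute kept).
#' @export
dilution_linearity <- function(areas, dilution_factors = default_dilution_factors()) {
  stopifnot(length(areas) == length(dilution_factors))
  ok <- is.finite(areas) & areas > 0
  n_used <- sum(ok)
  if (n_used < 4L) return(structure(NA_real_, n_used = n_used))
  fit <- stats::lm(log(areas[ok]) ~ log(1 / dilution_factors[ok]))
  # suppress the "essentially perfect fit" note: exact proportionality is a
  # legitimate (ideal) input here, not a numerical problem
  structure(suppressWarnings(summary(fit)$r.squared), n_used = n_used)
}

#' Per-species QC metrics
#'
#' CV across pooled-QC injections (computed on drift-corrected areas:
#' correction precedes filtering) and dilution-linearity R^2. A species is
#' accepted when CV < `cv_threshold` AND R^2 > `r2_threshold` (both strict,
#' per the printed inequality signs).
#'
#' @param corrected Corrected area matrix (injections x species).
#' @param sequence Injection-sequence manifest.
#' @param dilution_areas Matrix of raw areas for the dilution injections
#'   (points x species) or `NULL` to skip the linearity gate (R^2 = NA,
#'   species rejected with reason `r2`).
#' @param dilution_factors Dilution factors matching `dilution_areas` rows.
#' @param cv_threshold CV admission threshold, percent (default 25).
#' @param r2_threshold Linearity admission threshold (default 0.8).
#' @return Data frame: `name`, `cv_percent`, `dilution_r2`, `accepted`,
#'   `reject_reason` (`""`, `"cv"`, `"r2"` or `"cv;r2"`).
#' @export
qc_metrics <- function(corrected, sequence, dilution_areas = NULL,
                       dilution_factors = default_dilution_factors(),
                       cv_threshold = 25, r2_threshold = 0.8) {
  seq_use <- sequence[match(rownames(corrected), sequence$injection_id), , drop = FALSE]
  qc_rows <- which(seq_use$role == "pooled_qc")
  if (length(qc_rows) < 2L) stop("need at least two pooled-QC injections")
  cv <- apply(corrected[qc_rows, , drop = FALSE], 2L, compute_cv)
  r2 <- if (is.null(dilution_areas)) rep(NA_real_, ncol(corrected)) else {
    stopifnot(nrow(dilution_areas) == length(dilution_factors))
    vapply(colnames(corrected), function(sp) {
      if (!sp %in% colnames(dilution_areas)) return(NA_real_)
      as.numeric(dilution_linearity(dilution_areas[, sp], dilution_factors))
    }, 0)
  }
  pass_cv <- !is.na(cv) & cv < cv_threshold
  pass_r2 <- !is.na(r2) & r2 > r2_threshold
  reason <- paste0(ifelse(pass_cv, "", "cv"),
                   ifelse(pass_cv | pass_r2, "", ";"),
                   ifelse(pass_r2, "", "r2"))
  data.frame(name = colnames(corrected),
             cv_percent = unname(cv), dilution_r2 = unname(r2),
             accepted = pass_cv & pass_r2,
             reject_reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the QC admission filter
#'
#' @param metrics Output of [qc_metrics()].
#' @return List: `accepted` (species names passing both gates) and `audit`
#'   (rejection table with reasons).
#' @export
filter_species <- function(metrics) {
  list(accepted = metrics$name[metrics$accepted],
       audit = metrics[!metrics$accepted,
                       c("name", "cv_percent", "dilution_r2", "reject_reason"),
                       drop = FALSE])
}

#' Write the QC report TSV
#'
#' @param metrics [qc_metrics()] output.
#' @param path File path.
#' @export
write_qc_report <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the injection-sequence manifest CSV
#'
#' Columns `injection_id`, `role`, `batch`, `order`, `dilution_factor`
#' (and `sample_id` for study injections).
#'
#' @param x Manifest data frame.
#' @param path File path.
#' @name manifest_io
#' @export
write_manifest <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("injection_id", "role", "batch", "order")
  miss <- setdiff(req, names(mf))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  mf
}
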