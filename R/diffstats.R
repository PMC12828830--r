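# Case-control statistics: per-species Welch tests with Benjamini-Hochberg
# control, structural aggregation, lipid ratios, adjusted odds ratios, ROC
# models, severity regressions, and the clinical characteristics table.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1); thin, named
#' surface over `stats::p.adjust(method = "BH")` so the admission threshold
#' used across the pipeline has a single entry point.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorised Welch two-sample t over matrix columns; NA-tolerant.
# Degenerate columns: zero pooled se with zero difference -> t = 0, p = 1;
# zero se with nonzero difference -> infinite t, p = 0.
.welch_columns <- function(X1, X0) {
  n1 <- colSums(!is.na(X1)); n0 <- colSums(!is.na(X0))
  m1 <- colMeans(X1, na.rm = TRUE); m0 <- colMeans(X0, na.rm = TRUE)
  v1 <- (colSums(X1^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v0 <- (colSums(X0^2, na.rm = TRUE) - n0 * m0^2) / pmax(n0 - 1, 1)
  v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v0 / n0)^2 / pmax(n0 - 1, 1))
  zero_se <- se2 == 0
  tt[zero_se & (m1 - m0) == 0] <- 0
  df[zero_se] <- n1[zero_se] + n0[zero_se] - 2
  p <- 2 * stats::pt(-abs(tt), df)
  p[zero_se & (m1 - m0) == 0] <- 1
  p[zero_se & (m1 - m0) != 0] <- 0
  list(t = tt, df = df, p = p,
       n1 = n1, n0 = n0, m1 = m1, m0 = m0, v1 = v1, v0 = v0)
}

# pooled-variance (Student) variant, switchable from species_tests
.student_columns <- function(X1, X0) {
  n1 <- colSums(!is.na(X1)); n0 <- colSums(!is.na(X0))
  m1 <- colMeans(X1, na.rm = TRUE); m0 <- colMeans(X0, na.rm = TRUE)
  v1 <- (colSums(X1^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v0 <- (colSums(X0^2, na.rm = TRUE) - n0 * m0^2) / pmax(n0 - 1, 1)
  df <- n1 + n0 - 2
  vp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  se2 <- vp * (1 / n1 + 1 / n0)
  tt <- (m1 - m0) / sqrt(se2)
  zero_se <- se2 == 0
  tt[zero_se & (m1 - m0) == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  p[zero_se & (m1 - m0) == 0] <- 1
  p[zero_se & (m1 - m0) != 0] <- 0
  list(t = tt, df = df, p = p,
       n1 = n1, n0 = n0, m1 = m1, m0 = m0, v1 = v1, v0 = v0)
}

#' Per-species case-control tests
#'
#' Concentrations are log-transformed (natural log for testing) and compared
#' by Welch's unequal-variance t test (pooled-variance Student's t behind
#' `var_equal = TRUE`); p-values are Benjamini-Hochberg adjusted across all
#' tested species. Fold changes are reported in base 2:
#' `log2FC = mean(log2 case) - mean(log2 control)`. Group means and sds are
#' also reported on the nM scale. Non-positive cells are treated as missing;
#' species with an entire group missing are excluded and listed in the
#' `excluded` attribute.
#'
#' @param x Concentration table (data frame with species columns) or
#'   numeric matrix samples x species.
#' @param group Group label per sample.
#' @param case,control Labels of the case and control groups (defaults
#'   `"PD"`, `"control"`).
#' @param var_equal Use pooled-variance t instead of Welch.
#' @return Data frame: `name`, `n_case`, `n_control`, `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control` (nM scale), `log2fc`, `t`,
#'   `df`, `p`, `p_adj`.
#' @export
species_tests <- function(x, group, case = "PD", control = "control",
                          var_equal = FALSE) {
  M <- if (is.data.frame(x)) as.matrix(x[, species_columns(x), drop = FALSE]) else x
  stopifnot(nrow(M) == length(group))
  M[!is.na(M) & M <= 0] <- NA_real_
  L <- log(M)
  i1 <- group == case; i0 <- group == control
  if (!any(i1) || !any(i0)) stop("both groups must be non-empty")
  w <- if (var_equal) .student_columns(L[i1, , drop = FALSE], L[i0, , drop = FALSE])
       else .welch_columns(L[i1, , drop = FALSE], L[i0, , drop = FALSE])
  usable <- w$n1 >= 2 & w$n0 >= 2
  excluded <- colnames(M)[!usable]
  if (length(excluded))
    message("excluding ", length(excluded), " species with <2 values in a group")
  raw1 <- M[i1, , drop = FALSE]; raw0 <- M[i0, , drop = FALSE]
  out <- data.frame(
    name = colnames(M),
    n_case = w$n1, n_control = w$n0,
    mean_case = colMeans(raw1, na.rm = TRUE),
    sd_case = apply(raw1, 2L, stats::sd, na.rm = TRUE),
    mean_control = colMeans(raw0, na.rm = TRUE),
    sd_control = apply(raw0, 2L, stats::sd, na.rm = TRUE),
    log2fc = (w$m1 - w$m0) / log(2),
    t = w$t, df = w$df, p = w$p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[usable, , drop = FALSE]
  out$p_adj <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  structure(out, excluded = excluded)
}

#' Select panel species by structural class
#'
#' @param panel Panel data frame.
#' @param subclass,spb,acyl,base_c,acyl_hydroxyl Optional filters; `spb`
#'   matches the merged view labels (`"C18-SPH/D"`) as well as plain ones.
#' @param even_acyl Keep only even-numbered acyl chains.
#' @return Character vector of species names; errors (naming the selection)
#'   when nothing matches.
#' @export
select_species <- function(panel, subclass = NULL, spb = NULL, acyl = NULL,
                           base_c = NULL, acyl_hydroxyl = NULL,
                           even_acyl = FALSE) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(subclass)) keep <- keep & panel$subclass %in% subclass
  if (!is.null(spb)) keep <- keep & (panel$spb %in% spb | panel$spb_merged %in% spb)
  if (!is.null(acyl)) keep <- keep & panel$acyl %in% acyl
  if (!is.null(base_c)) keep <- keep & panel$base_c %in% base_c
  if (!is.null(acyl_hydroxyl)) keep <- keep & panel$acyl_hydroxyl == acyl_hydroxyl
  if (even_acyl) keep <- keep & panel$acyl_c %% 2L == 0L
  if (!any(keep))
    stop("no panel species match selection (subclass=", paste(subclass, collapse = ","),
         " spb=", paste(spb, collapse = ","), " acyl=", paste(acyl, collapse = ","), ")")
  panel$name[keep]
}

#' Sum concentrations over a species selection
#'
#' Per-sample total over the selected species; missing cells are treated as
#' absent (sum of available values) and a per-sample completeness count is
#' attached.
#'
#' @param x Concentration table.
#' @param species Species (column) names to sum.
#' @return Numeric vector (one total per sample) with attribute
#'   `n_observed`.
#' @export
aggregate_concentrations <- function(x, species) {
  miss <- setdiff(species, names(x))
  if (length(miss)) stop("species absent from table: ", paste(miss, collapse = ", "))
  M <- as.matrix(x[, species, drop = FALSE])
  structure(rowSums(M, na.rm = TRUE), n_observed = rowSums(!is.na(M)))
}

#' Subclass totals for a base/acyl restriction
#'
#' Per-sample summed concentration of each subclass, by default restricted
#' to the predominant C18-SPH/D base and C24 acyl chains (the restriction
#' under which the subclass totals are compared between groups). Subclasses
#' whose base kind is not SPH/SPD (DHS-Cer, PHS-Cer) are restricted by base
#' carbons instead.
#'
#' @param x Concentration table.
#' @param panel Panel data frame.
#' @param spb Merged-view base label (default `"C18-SPH/D"`); `NULL` for no
#'   base restriction.
#' @param acyl Acyl class label (default `"C24"`); `NULL` for none.
#' @return Data frame: `sample_id` (when present) and one column per
#'   subclass.
#' @export
subclass_totals <- function(x, panel, spb = "C18-SPH/D", acyl = "C24") {
  base_c <- if (!is.null(spb)) as.integer(sub("^C(\\d+)-.*$", "\\1", spb)) else NULL
  out <- if ("sample_id" %in% names(x)) data.frame(sample_id = x$sample_id,
                                                   stringsAsFactors = FALSE)
         else data.frame(row.names = seq_len(nrow(x)))
  for (sc in unique(panel$subclass)) {
    sel <- if (is.null(spb) || any(panel$subclass == sc & panel$spb_merged %in% spb))
      select_species(panel, subclass = sc, spb = spb, acyl = acyl)
    else  # non-SPH/D subclass: restrict by base carbons only
      select_species(panel, subclass = sc, base_c = base_c, acyl = acyl)
    out[[sc]] <- as.numeric(aggregate_concentrations(x, sel))
  }
  out
}

#' Acyl-chain length distribution
#'
#' Relative distribution of acyl-chain lengths among ceramides with a given
#' base (default C18-SPH/D, even-numbered chains): per-sample proportions by
#' acyl class, summing to 1.
#'
#' @param x Concentration table.
#' @param panel Panel data frame.
#' @param subclass Subclass (default `"Cer"`).
#' @param spb Base label, merged view (default `"C18-SPH/D"`).
#' @param even_only Keep only even-numbered acyl chains (default `TRUE`).
#' @param hydroxylated Include 2-hydroxy acyl species (default `FALSE`).
#' @return Data frame of proportions, one column per acyl class (plus
#'   `sample_id` when present); all-zero samples yield NA proportions.
#' @export
chain_distribution <- function(x, panel, subclass = "Cer", spb = "C18-SPH/D",
                               even_only = TRUE, hydroxylated = FALSE) {
  sel <- select_species(panel, subclass = subclass, spb = spb,
                        acyl_hydroxyl = if (hydroxylated) NULL else FALSE,
                        even_acyl = even_only)
  sub <- panel[match(sel, panel$name), ]
  classes <- sort(unique(sub$acyl))
  M <- as.matrix(x[, sel, drop = FALSE])
  tot <- rowSums(M, na.rm = TRUE)
  out <- if ("sample_id" %in% names(x)) data.frame(sample_id = x$sample_id,
                                                   stringsAsFactors = FALSE)
         else data.frame(row.names = seq_len(nrow(x)))
  for (cl in classes) {
    cols <- sel[sub$acyl == cl]
    num <- rowSums(M[, cols, drop = FALSE], na.rm = TRUE)
    out[[cl]] <- ifelse(tot > 0, num / tot, NA_real_)
  }
  out
}

#' Group comparison of chain-length proportions
#'
#' Welch t test per acyl class on the per-sample proportions, BH-adjusted
#' across classes.
#'
#' @param props [chain_distribution()] output.
#' @param group Group labels per sample.
#' @param case,control Group labels.
#' @return Data frame: `acyl`, group means, `t`, `p`, `p_adj`.
#' @export
chain_distribution_tests <- function(props, group, case = "PD", control = "control") {
  cols <- setdiff(names(props), "sample_id")
  M <- as.matrix(props[, cols, drop = FALSE])
  w <- .welch_columns(M[group == case, , drop = FALSE],
                      M[group == control, , drop = FALSE])
  data.frame(acyl = cols, mean_case = w$m1, mean_control = w$m0,
             t = w$t, p = w$p, p_adj = benjamini_hochberg(w$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Built-in lipid-ratio definitions
#'
#' HexCer/Cer, GM3/Hex2Cer, Hex3Cer/Hex2Cer and Cer/DHS-Cer, each restricted
#' to C18-SPH/D bases (C18-DHS for DHS-Cer) and C24 acyl chains by default.
#'
#' @param panel Panel data frame.
#' @param spb,acyl Restriction labels (defaults `"C18-SPH/D"`, `"C24"`;
#'   `acyl = NULL` pools all chains).
#' @return Named list of definitions, each `list(label, numerator,
#'   denominator)` with disjoint non-empty species sets.
#' @export
default_ratio_definitions <- function(panel, spb = "C18-SPH/D", acyl = "C24") {
  base_c <- as.integer(sub("^C(\\d+)-.*$", "\\1", spb))
  pick <- function(sc) {
    if (sc %in% c("DHS-Cer", "PHS-Cer"))
      select_species(panel, subclass = sc, base_c = base_c, acyl = acyl)
    else select_species(panel, subclass = sc, spb = spb, acyl = acyl)
  }
  defs <- list(
    "HexCer/Cer"       = list(num = "HexCer",  den = "Cer"),
    "GM3/Hex2Cer"      = list(num = "GM3",     den = "Hex2Cer"),
    "Hex3Cer/Hex2Cer"  = list(num = "Hex3Cer", den = "Hex2Cer"),
    "Cer/DHS-Cer"      = list(num = "Cer",     den = "DHS-Cer")
  )
  lapply(stats::setNames(names(defs), names(defs)), function(lab) {
    d <- defs[[lab]]
    num <- pick(d$num); den <- pick(d$den)
    if (length(intersect(num, den))) stop("ratio sets not disjoint for ", lab)
    list(label = lab, numerator = num, denominator = den)
  })
}

#' Per-sample lipid ratio
#'
#' `sum(numerator species) / sum(denominator species)`; a sample with a
#' non-positive denominator yields NA (counted in attribute `n_undefined`).
#' Scale-invariant: rescaling all concentrations of a sample leaves the
#' ratio unchanged.
#'
#' @param x Concentration table.
#' @param def Ratio definition (`list(label, numerator, denominator)`).
#' @return Numeric vector of ratios per sample.
#' @export
compute_ratio <- function(x, def) {
  num <- as.numeric(aggregate_concentrations(x, def$numerator))
  den <- as.numeric(aggregate_concentrations(x, def$denominator))
  bad <- !(den > 0)
  r <- ifelse(bad, NA_real_, num / den)
  structure(r, n_undefined = sum(bad), label = def$label)
}

#' Group comparison of lipid ratios
#'
#' Welch t test on the log ratio per definition, BH-adjusted across the
#' ratio family.
#'
#' @param x Concentration table.
#' @param defs List of ratio definitions (see
#'   [default_ratio_definitions()]).
#' @param group,case,control Group labels.
#' @return Data frame: `label`, geometric-mean ratios per group, `log2fc`,
#'   `t`, `p`, `p_adj`.
#' @export
ratio_tests <- function(x, defs, group, case = "PD", control = "control") {
  R <- vapply(defs, function(d) compute_ratio(x, d), numeric(nrow(x)))
  L <- log(R); L[!is.finite(L)] <- NA_real_
  w <- .welch_columns(L[group == case, , drop = FALSE],
                      L[group == control, , drop = FALSE])
  data.frame(label = vapply(defs, `[[`, "", "label"),
             gm_case = exp(w$m1), gm_control = exp(w$m0),
             log2fc = (w$m1 - w$m0) / log(2),
             t = w$t, p = w$p, p_adj = benjamini_hochberg(w$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of case status on
#' the exposure plus covariates; the exposure coefficient is exponentiated
#' to an odds ratio with a Wald 95% CI. Degenerate designs (constant
#' exposure, rank deficiency) and separation/non-convergence raise explicit
#' diagnostics rather than returning silent output.
#'
#' @param outcome Logical or two-level factor/character (case = `TRUE` or
#'   the `case` label).
#' @param exposure Numeric exposure (e.g. a log ratio or log level).
#' @param covariates Data frame of adjustment covariates (may be empty).
#' @param case Case label when `outcome` is not logical.
#' @return List: `or`, `ci` (length 2), `p`, `coef`, `covariates` (names
#'   adjusted for), `fit` (the glm object).
#' @export
logistic_adjusted_or <- function(outcome, exposure, covariates = NULL,
                                 case = "PD") {
  y <- if (is.logical(outcome)) outcome else outcome == case
  dat <- data.frame(.y = y, .x = exposure)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (stats::var(dat$.x) == 0)
    stop("exposure is constant: design is rank deficient")
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)")
  if (anyNA(stats::coef(fit))) stop("rank-deficient design (aliased coefficients)")
  co <- summary(fit)$coefficients
  if (abs(co[".x", "Estimate"]) > 15 || co[".x", "Std. Error"] > 100)
    stop("apparent separation: exposure coefficient diverged")
  est <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  z <- stats::qnorm(0.975)
  list(or = exp(est), ci = exp(c(est - z * se, est + z * se)),
       p = co[".x", "Pr(>|z|)"], coef = est,
       covariates = setdiff(names(dat), c(".y", ".x")), fit = fit)
}

#' AUC by the Mann-Whitney pairwise statistic
#'
#' Probability that a random case scores above a random control, ties
#' counted 1/2 — computed from average ranks, identical to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param score Numeric classifier score.
#' @param is_case Logical case indicator.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(score, is_case) {
  stopifnot(length(score) == length(is_case))
  ok <- !is.na(score) & !is.na(is_case)
  score <- score[ok]; is_case <- is_case[ok]
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("need both cases and controls")
  r <- rank(score)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC models for case-control discrimination
#'
#' Fits nested logistic models -- basic (age + sex), GSL species, ceramide
#' species, and the full model with every selected species -- where species
#' are those passing the significance rule `p_adj < threshold` in the
#' per-species tests. Lipid models include age and sex alongside species by
#' default (`include_demographics = FALSE` for lipid-only scores). AUC is
#' the Mann-Whitney statistic of the in-sample linear score; its 95% CI is a
#' seeded percentile bootstrap over samples (2000 resamples).
#'
#' @param x Concentration table.
#' @param cohort Cohort table with `group`, `age`, `sex` (rows aligned with
#'   `x`).
#' @param panel Panel data frame.
#' @param stats Output of [species_tests()] (computed from `x` if `NULL`).
#' @param p_adj_threshold Species selection rule (default 0.01).
#' @param include_demographics Include age and sex in lipid models.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Bootstrap seed.
#' @param case,control Group labels.
#' @return Data frame: `model`, `n_predictors`, `auc`, `ci_low`, `ci_high`;
#'   attribute `predictors` lists the species per model.
#' @export
roc_models <- function(x, cohort, panel, stats = NULL, p_adj_threshold = 0.01,
                       include_demographics = TRUE, n_boot = 2000, seed = 1,
                       case = "PD", control = "control") {
  if (is.null(stats)) stats <- species_tests(x, cohort$group, case, control)
  if (length(unique(cohort$group)) < 2L) stop("one-class input: need both groups")
  sig <- stats$name[stats$p_adj < p_adj_threshold]
  cer_sub <- c("Cer", "DHS-Cer", "PHS-Cer")
  gsl <- intersect(sig, panel$name[!panel$subclass %in% cer_sub])
  cer <- intersect(sig, panel$name[panel$subclass %in% cer_sub])
  models <- list(basic = character(0), gsl = gsl, ceramide = cer, full = sig)

  y <- cohort$group == case
  sexnum <- as.numeric(factor(cohort$sex))
  out <- data.frame(model = names(models), n_predictors = NA_integer_,
                    auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  preds <- list()
  for (k in seq_along(models)) {
    sp <- models[[k]]
    if (names(models)[k] != "basic" && length(sp) == 0L) {
      warning("no significant species for model '", names(models)[k], "'; skipped")
      preds[[names(models)[k]]] <- character(0)
      next
    }
    Z <- if (length(sp)) log2(as.matrix(x[, sp, drop = FALSE])) else NULL
    dat <- data.frame(.y = y)
    if (names(models)[k] == "basic" || include_demographics) {
      dat$age <- cohort$age; dat$sex <- sexnum
    }
    if (!is.null(Z)) dat <- cbind(dat, as.data.frame(Z, check.names = FALSE))
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    score <- stats::predict(fit, type = "link")
    auc <- auc_mw(score, dat$.y)
    boot <- .auc_boot_ci(score, dat$.y, n_boot, seed + k)
    out$n_predictors[k] <- ncol(dat) - 1L
    out$auc[k] <- auc; out$ci_low[k] <- boot[1]; out$ci_high[k] <- boot[2]
    preds[[names(models)[k]]] <- sp
  }
  structure(out, predictors = preds)
}

.auc_boot_ci <- function(score, is_case, n_boot, seed, level = 0.95) {
  n <- length(score)
  aucs <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(is_case[i])) < 2L) return(NA_real_)
      auc_mw(score[i], is_case[i])
    }, 0)
  })
  stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Lipid-severity association by multivariate linear regression
#'
#' Among cases only: ordinary least squares of the severity outcome on the
#' log2 lipid level with the stated covariates, one fit per lipid,
#' BH-adjusted across lipids. Zero-variance covariates and collinear
#' designs raise diagnostics.
#'
#' @param x Concentration table (cases' rows are selected via `cohort`).
#' @param cohort Cohort table with `group` and the outcome/covariate
#'   columns.
#' @param lipids Species (or aggregate column) names to test.
#' @param outcome Severity column name (e.g. `"updrs3"`, `"mmse"`).
#' @param covariates Covariate column names (default age, sex,
#'   disease_duration, ledd).
#' @param case Case label.
#' @return Data frame: `lipid`, `estimate`, `se`, `ci_low`, `ci_high`, `p`,
#'   `p_adj`, `n`.
#' @export
severity_association <- function(x, cohort, lipids, outcome = "updrs3",
                                 covariates = c("age", "sex", "disease_duration", "ledd"),
                                 case = "PD") {
  rows <- which(cohort$group == case)
  cov <- cohort[rows, covariates, drop = FALSE]
  for (v in covariates) {
    cv <- cov[[v]]
    if (!is.numeric(cv)) cv <- as.numeric(factor(cv))
    if (stats::var(cv, na.rm = TRUE) == 0)
      stop("zero-variance covariate '", v, "'")
    cov[[v]] <- cv
  }
  yv <- cohort[[outcome]][rows]
  res <- lapply(lipids, function(sp) {
    dat <- data.frame(.y = yv, .x = log2(x[rows, sp]), cov)
    dat <- dat[stats::complete.cases(dat) & is.finite(dat$.x), , drop = FALSE]
    fit <- stats::lm(.y ~ ., data = dat)
    if (anyNA(stats::coef(fit))) stop("collinear design for lipid '", sp, "'")
    co <- summary(fit)$coefficients
    ci <- stats::confint(fit, ".x")
    data.frame(lipid = sp, estimate = co[".x", "Estimate"], se = co[".x", "Std. Error"],
               ci_low = ci[1], ci_high = ci[2], p = co[".x", "Pr(>|t|)"],
               n = nrow(dat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}

# Brown-Forsythe variant of Levene's test (absolute deviations from group
# medians), used as the variance-homogeneity gate for clinical rows
.levene_p <- function(x, g) {
  med <- tapply(x, g, stats::median, na.rm = TRUE)
  z <- abs(x - med[as.character(g)])
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Clinical characteristics table
#'
#' One row per variable with per-group summaries and a between-group test:
#' continuous rows report mean +/- sd and use Student's t (variance pooling
#' decided by Levene's test) when both groups pass a Shapiro-Wilk normality
#' gate at 0.05, Mann-Whitney U otherwise; categorical rows report n (%)
#' and use Fisher's exact test. Case-only variables (severity scales) are
#' summarised without a test.
#'
#' @param cohort Cohort table with a `group` column.
#' @param continuous,categorical Variable names of each type; defaults pick
#'   up the generator's column set intersected with what is present.
#' @param case,control Group labels.
#' @return Data frame: `variable`, `type`, `control_summary`,
#'   `case_summary`, `test`, `p`.
#' @export
clinical_table <- function(cohort,
                           continuous = intersect(c("age", "bmi", "disease_duration",
                                                    "hy_stage", "updrs3", "mmse",
                                                    "ledd", "creatinine"),
                                                  names(cohort)),
                           categorical = intersect(c("sex", "hypertension", "diabetes",
                                                     "cardiovascular", "cerebrovascular",
                                                     "constipation"),
                                                   names(cohort)),
                           case = "PD", control = "control") {
  g <- cohort$group
  fmt_ms <- function(v) if (all(is.na(v))) "n/a"
    else sprintf("%.1f +/- %.1f", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
  rows <- list()
  for (v in continuous) {
    x1 <- cohort[[v]][g == case]; x0 <- cohort[[v]][g == control]
    both <- sum(!is.na(x1)) >= 3 && sum(!is.na(x0)) >= 3
    if (both) {
      norm <- stats::shapiro.test(x1[!is.na(x1)])$p.value > 0.05 &&
              stats::shapiro.test(x0[!is.na(x0)])$p.value > 0.05
      if (norm) {
        xv <- c(x1, x0); gv <- factor(rep(c(case, control), c(length(x1), length(x0))))
        ok <- !is.na(xv)
        eqv <- .levene_p(xv[ok], droplevels(gv[ok])) > 0.05
        p <- stats::t.test(x1, x0, var.equal = eqv)$p.value
        test <- if (eqv) "t" else "Welch t"
      } else {
        p <- stats::wilcox.test(x1, x0, exact = FALSE)$p.value
        test <- "Mann-Whitney"
      }
    } else { p <- NA_real_; test <- "" }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      control_summary = fmt_ms(x0), case_summary = fmt_ms(x1),
      test = test, p = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- cohort[[v]]
    lev <- sort(unique(stats::na.omit(x)))
    # counted level: TRUE/1 for flags, female for sex columns, else the last
    pos <- if (setequal(lev, c("F", "M"))) "F" else lev[length(lev)]
    n1 <- sum(x[g == case] == pos, na.rm = TRUE); N1 <- sum(g == case & !is.na(x))
    n0 <- sum(x[g == control] == pos, na.rm = TRUE); N0 <- sum(g == control & !is.na(x))
    tab <- rbind(c(n0, N0 - n0), c(n1, N1 - n1))
    p <- if (all(rowSums(tab) > 0)) stats::fisher.test(tab)$p.value else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      control_summary = sprintf("%d (%.1f%%)", n0, 100 * n0 / N0),
      case_summary = sprintf("%d (%.1f%%)", n1, 100 * n1 / N1),
      test = "Fisher", p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
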