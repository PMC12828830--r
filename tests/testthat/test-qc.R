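test_that("CV is the sample-sd-over-mean percentage with strict admission", {
  expect_equal(compute_cv(c(10, 10, 10)), 0)
  expect_equal(compute_cv(c(8, 10, 12)), 20)
  expect_true(is.na(compute_cv(c(5))))
  expect_true(is.na(compute_cv(c(-2, 2))))  # non-positive mean undefined
})

test_that("dilution linearity fits log signal on log dilution", {
  df <- default_dilution_factors()
  expect_equal(length(df), 13L)
  # exact proportionality to 1/DF
  expect_equal(as.numeric(dilution_linearity(1000 / df, df)), 1)
  # flat signal carries no concentration information
  r2 <- dilution_linearity(rep(500, 13) * exp(rnorm(13, 0, 1e-4)), df)
  expect_lt(as.numeric(r2), 0.5)
  # fewer than four usable points is undefined
  few <- c(100, 50, 20, rep(0, 10))
  out <- dilution_linearity(few, df)
  expect_true(is.na(out))
  expect_equal(attr(out, "n_used"), 3L)
})

test_that("admission thresholds are strict inequalities at the boundary", {
  # three pooled QCs with CV exactly 25% (7.5, 10, 12.5)
  areas <- cbind(exact = c(7.5, 10, 12.5), clean = c(10, 10, 10))
  rownames(areas) <- c("q1", "q2", "q3")
  seqm <- data.frame(injection_id = c("q1", "q2", "q3"), role = "pooled_qc",
                     batch = 1, order = 1:3)
  df <- default_dilution_factors()
  dil <- cbind(exact = 1000 / df, clean = 1000 / df)
  m <- qc_metrics(areas, seqm, dilution_areas = dil, dilution_factors = df)
  expect_equal(m$cv_percent[m$name == "exact"], 25, tolerance = 1e-12)
  expect_false(m$accepted[m$name == "exact"])
  expect_equal(m$reject_reason[m$name == "exact"], "cv")
  expect_true(m$accepted[m$name == "clean"])

  # R^2 exactly at the threshold is likewise rejected
  noisy <- 1000 / df * exp(sin(seq_len(13)))
  r2 <- as.numeric(dilution_linearity(noisy, df))
  dil2 <- cbind(exact = 1000 / df, clean = noisy)
  m2 <- qc_metrics(areas[, c(2, 2)], seqm, dilution_areas = dil2,
                   dilution_factors = df, r2_threshold = r2)
  expect_false(m2$accepted[2])
  expect_equal(m2$reject_reason[2], "r2")
})

test_that("drift correction is the identity on drift-free data", {
  set.seed(1)
  n_inj <- 23
  areas <- matrix(rep(c(100, 250), each = n_inj), ncol = 2,
                  dimnames = list(sprintf("i%02d", 1:n_inj), c("A", "B")))
  # study samples interleaved with constant-response QCs
  role <- rep("study", n_inj); role[c(1, 12, 23)] <- "pooled_qc"
  seqm <- data.frame(injection_id = rownames(areas), role = role,
                     batch = 1, order = 1:n_inj)
  areas[role == "study", ] <- areas[role == "study", ] * runif(20, 0.5, 2)
  out <- correct_drift(areas, seqm)
  expect_equal(out, areas, tolerance = 1e-12)
})

test_that("monotone drift is removed: post-correction QC CV drops", {
  cfg <- tiny_config(seed = 21, n = 25, drift_amplitude = 0.33,
                     drift_sine = 0, noise_cv = 0)
  panel <- generate_panel(cfg)
  run <- generate_injection_run(generate_cohort(cfg, panel), cfg, panel)
  areas <- area_matrix(
    match_peaks(run$peaks, run$library)$annotated,
    panel$name, run$manifest$injection_id)
  corrected <- correct_drift(areas, run$manifest)
  qc_id <- run$manifest$injection_id[run$manifest$role == "pooled_qc"]
  cv_pre <- apply(areas[qc_id, ], 2, compute_cv)
  cv_post <- apply(corrected[qc_id, ], 2, compute_cv)
  expect_gt(mean(cv_pre), 5)          # the drift is material before correction
  expect_true(all(cv_post < cv_pre))  # and strictly reduced for every species
})

test_that("two flat batches offset 1.5x are aligned to a common QC level", {
  ids <- sprintf("i%02d", 1:10)
  role <- rep(c("pooled_qc", "study", "study", "study", "pooled_qc"), 2)
  batch <- rep(1:2, each = 5)
  areas <- matrix(rep(c(100, 150), each = 5), ncol = 1,
                  dimnames = list(ids, "A"))
  seqm <- data.frame(injection_id = ids, role = role, batch = batch,
                     order = rep(1:5, 2))
  out <- correct_drift(areas, seqm)
  qc_b1 <- out[c(1, 5), 1]; qc_b2 <- out[c(6, 10), 1]
  expect_equal(median(qc_b1), median(qc_b2))
  # within-batch values rescale with their batch's QCs
  expect_equal(unname(out[2, 1] / out[1, 1]), 1)
})

test_that("within-injection species ratios survive a shared trend", {
  ids <- sprintf("i%02d", 1:11)
  role <- rep("study", 11); role[c(1, 6, 11)] <- "pooled_qc"
  trend <- seq(1, 2, length.out = 11)
  areas <- cbind(A = 100 * trend, B = 300 * trend)
  rownames(areas) <- ids
  seqm <- data.frame(injection_id = ids, role = role, batch = 1, order = 1:11)
  out <- correct_drift(areas, seqm)
  expect_equal(unname(out[, "B"] / out[, "A"]), rep(3, 11), tolerance = 1e-9)
})

test_that("a batch with a single pooled QC degrades to median scaling", {
  ids <- c("q1", "s1", "s2")
  areas <- matrix(c(100, 120, 90), ncol = 1, dimnames = list(ids, "A"))
  seqm <- data.frame(injection_id = ids, role = c("pooled_qc", "study", "study"),
                     batch = 1, order = 1:3)
  expect_warning(out <- correct_drift(areas, seqm), "median-only")
  expect_equal(unname(out[, 1]), c(100, 120, 90))
})

test_that("species failing injected QC noise are rejected with audited reasons", {
  set.seed(8)
  n_sp <- 10; noisy <- c(2, 4, 6, 8, 10)
  qc <- matrix(rep(1000, 6 * n_sp), nrow = 6)
  for (j in noisy) qc[, j] <- 1000 * exp(rnorm(6, 0, 0.45))  # ~45% CV
  colnames(qc) <- paste0("sp", 1:n_sp)
  rownames(qc) <- paste0("q", 1:6)
  seqm <- data.frame(injection_id = rownames(qc), role = "pooled_qc",
                     batch = 1, order = 1:6)
  df <- default_dilution_factors()
  dil <- matrix(rep(1000 / df, n_sp), ncol = n_sp,
                dimnames = list(NULL, colnames(qc)))
  m <- qc_metrics(qc, seqm, dilution_areas = dil, dilution_factors = df)
  flt <- filter_species(m)
  expect_setequal(flt$audit$name, paste0("sp", noisy))
  expect_true(all(flt$audit$reject_reason == "cv"))
  expect_setequal(flt$accepted, paste0("sp", setdiff(1:n_sp, noisy)))

  # a species failing both gates lists both reasons in one audit row
  dil2 <- dil; dil2[, 2] <- 1000
  m2 <- qc_metrics(qc, seqm, dilution_areas = dil2, dilution_factors = df)
  expect_equal(m2$reject_reason[2], "cv;r2")
  expect_equal(sum(filter_species(m2)$audit$name == "sp2"), 1L)
})
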