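test_that("per-species Welch t matches stats::t.test on log values", {
  set.seed(101)
  n1 <- 18; n0 <- 22
  X <- cbind(matrix(rlnorm(n1 * 12, 5, 0.4), n1),
             matrix(rlnorm(n1 * 0, 5, 0.4), n1))
  Y <- matrix(rlnorm(n0 * 12, 5.2, 0.5), n0)
  M <- rbind(X, Y)
  colnames(M) <- paste0("sp", 1:12)
  g <- rep(c("PD", "control"), c(n1, n0))
  st <- species_tests(M, g)
  for (j in 1:12) {
    ref <- t.test(log(M[g == "PD", j]), log(M[g == "control", j]))
    expect_equal(st$t[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-10)
    expect_equal(st$log2fc[j],
                 mean(log2(M[g == "PD", j])) - mean(log2(M[g == "control", j])),
                 tolerance = 1e-10)
  }
  # pooled-variance variant matches var.equal = TRUE
  st2 <- species_tests(M, g, var_equal = TRUE)
  ref2 <- t.test(log(M[g == "PD", 1]), log(M[g == "control", 1]), var.equal = TRUE)
  expect_equal(st2$p[1], ref2$p.value, tolerance = 1e-10)
})

test_that("identical group values give t = 0 and p = 1", {
  M <- matrix(rep(c(5, 7, 9, 5, 7, 9), 2), ncol = 2)
  colnames(M) <- c("a", "b")
  st <- species_tests(M, rep(c("PD", "control"), each = 3))
  expect_equal(st$t, c(0, 0))
  expect_equal(st$p, c(1, 1))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:1000) {
    p <- runif(sample(1:10, 1))^sample(c(1, 2, 0.5), 1)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("aggregation is additive over a partition and linear per column", {
  cfg <- tiny_config(seed = 31, n = 8)
  panel <- generate_panel(cfg)
  conc <- generate_cohort(cfg, panel)$concentrations
  parts <- split(panel$name, panel$subclass)
  tot_parts <- Reduce(`+`, lapply(parts, function(s)
    as.numeric(aggregate_concentrations(conc, s))))
  tot_all <- as.numeric(aggregate_concentrations(conc, panel$name))
  expect_equal(tot_parts, tot_all, tolerance = 1e-12)

  sel <- select_species(panel, subclass = "HexCer", spb = "C18-SPH/D", acyl = "C24")
  before <- as.numeric(aggregate_concentrations(conc, sel))
  conc2 <- conc
  conc2[[sel[1]]] <- 2 * conc2[[sel[1]]]
  after <- as.numeric(aggregate_concentrations(conc2, sel))
  expect_equal(after - before, conc[[sel[1]]], tolerance = 1e-12)

  expect_error(select_species(panel, subclass = "Cer", acyl = "C99"),
               "no panel species match")
})

test_that("chain-length proportions are normalised per sample", {
  cfg <- tiny_config(seed = 32, n = 8)
  panel <- generate_panel(cfg)
  conc <- generate_cohort(cfg, panel)$concentrations
  props <- chain_distribution(conc, panel)
  M <- as.matrix(props[, setdiff(names(props), "sample_id")])
  expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-9)

  # a sample with mass only in C24 gets proportion one there
  sel <- select_species(panel, subclass = "Cer", spb = "C18-SPH/D",
                        acyl_hydroxyl = FALSE, even_acyl = TRUE)
  conc0 <- conc
  conc0[1, sel] <- 0
  conc0[1, sel[panel$acyl[match(sel, panel$name)] == "C24"]] <- 50
  p0 <- chain_distribution(conc0, panel)
  expect_equal(p0$C24[1], 1)
  expect_equal(sum(p0[1, setdiff(names(p0), c("sample_id", "C24"))] == 0),
               ncol(p0) - 2L)
})

test_that("lipid ratios are scale-invariant and one for identical sets", {
  cfg <- tiny_config(seed = 33, n = 8)
  panel <- generate_panel(cfg)
  conc <- generate_cohort(cfg, panel)$concentrations
  defs <- default_ratio_definitions(panel)
  expect_setequal(names(defs),
                  c("HexCer/Cer", "GM3/Hex2Cer", "Hex3Cer/Hex2Cer", "Cer/DHS-Cer"))
  for (d in defs) expect_length(intersect(d$numerator, d$denominator), 0)

  r1 <- compute_ratio(conc, defs[["HexCer/Cer"]])
  conc_scaled <- conc
  conc_scaled[, panel$name] <- conc_scaled[, panel$name] * 3.7
  r2 <- compute_ratio(conc_scaled, defs[["HexCer/Cer"]])
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-12)

  same <- list(label = "x", numerator = defs[[1]]$numerator,
               denominator = defs[[1]]$numerator)
  expect_equal(unname(as.numeric(compute_ratio(conc, same))),
               rep(1, nrow(conc)))

  # zero denominator becomes missing and is counted
  conc0 <- conc
  conc0[1, defs[[1]]$denominator] <- 0
  r3 <- compute_ratio(conc0, defs[[1]])
  expect_true(is.na(r3[1]))
  expect_equal(attr(r3, "n_undefined"), 1L)
})

test_that("AUC equals brute force over pairs and the trapezoidal integral", {
  # 2 cases {2,3} vs 2 controls {1,2}: 3.5 of 4 pairs
  score <- c(2, 3, 1, 2); is_case <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_mw(score, is_case), 0.875)
  expect_equal(auc_brute(c(2, 3), c(1, 2)), 0.875)

  set.seed(55)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- c(sample(1:6, n1, TRUE) + rnorm(n1, 0, 0.01) * rbinom(n1, 1, 0.5),
           sample(1:6, n0, TRUE))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    a <- auc_mw(s, lab)
    expect_equal(a, auc_brute(s[lab], s[!lab]), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(s, lab), tolerance = 1e-12)
  }

  # perfect separation and null behaviour
  expect_equal(auc_mw(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(56)
  expect_equal(auc_mw(rnorm(4000), rep(c(TRUE, FALSE), 2000)), 0.5, tolerance = 0.05)
  expect_error(auc_mw(1:3, c(TRUE, TRUE, TRUE)), "both cases and controls")
})

test_that("adjusted odds ratios are consistent and diagnose degenerate input", {
  # true exposure coefficient log(2) recovered at large n
  set.seed(60)
  n <- 20000
  x <- rnorm(n); age <- rnorm(n, 65, 8)
  eta <- -0.2 + log(2) * x + 0.01 * (age - 65)
  y <- rbinom(n, 1, plogis(eta)) == 1
  fit <- logistic_adjusted_or(y, x, data.frame(age = age))
  expect_equal(fit$or, 2, tolerance = 0.08)
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])
  expect_equal(fit$covariates, "age")

  expect_error(logistic_adjusted_or(y, rep(1, n)), "rank deficient|constant")
  # separation raises a diagnostic, not a silent estimate
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- rep(c(FALSE, TRUE), each = 50)
  expect_error(suppressWarnings(logistic_adjusted_or(ys, xs)), "separation")
})

test_that("null-exposure odds-ratio CIs cover one at the nominal rate", {
  set.seed(61)
  hits <- 0; reps <- 400
  for (i in seq_len(reps)) {
    n <- 500
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5) == 1
    fit <- logistic_adjusted_or(y, x)
    if (fit$ci[1] <= 1 && 1 <= fit$ci[2]) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.985)
})

test_that("severity regressions recover known slopes and flag bad designs", {
  cfg <- tiny_config(seed = 62, n = 120)
  panel <- generate_panel(cfg)
  cd <- generate_cohort(cfg, panel)
  conc <- cd$concentrations; cohort <- cd$cohort
  lipid <- panel$name[1]
  # outcome built from the lipid with known slope on the log2 scale
  slope <- 4
  pd <- cohort$group == "PD"
  cohort$updrs3[pd] <- 30 + slope * log2(conc[pd, lipid]) + rnorm(sum(pd), 0, 2)
  res <- severity_association(conc, cohort, lipid, outcome = "updrs3")
  expect_true(res$ci_low < slope && slope < res$ci_high)
  expect_lt(res$p, 1e-3)

  cohort$ledd[pd] <- 600
  expect_error(severity_association(conc, cohort, lipid), "zero-variance")
})

test_that("null severity CIs cover zero at the nominal rate", {
  set.seed(63)
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    n <- 80
    dat <- data.frame(sample_id = 1:n, sp = rlnorm(n, 5, 0.3))
    coh <- data.frame(group = "PD", age = rnorm(n, 67, 7),
                      sex = sample(c("F", "M"), n, TRUE),
                      disease_duration = rnorm(n, 7, 2),
                      ledd = rnorm(n, 650, 200),
                      updrs3 = rnorm(n, 35, 10))
    res <- severity_association(dat, coh, "sp")
    if (res$ci_low <= 0 && 0 <= res$ci_high) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.91)
})

test_that("the clinical table formats counts and tests as reported tables do", {
  set.seed(70)
  n <- 250
  cohort <- data.frame(
    group = rep(c("control", "PD"), each = n),
    age = rnorm(2 * n, 67.4, 7.5),
    sex = "M", stringsAsFactors = FALSE)
  cohort$sex[sample(which(cohort$group == "control"), 85)] <- "F"
  cohort$sex[sample(which(cohort$group == "PD"), 86)] <- "F"
  tab <- clinical_table(cohort, continuous = "age", categorical = "sex")
  sex_row <- tab[tab$variable == "sex", ]
  expect_equal(sex_row$control_summary, "85 (34.0%)")
  expect_equal(sex_row$case_summary, "86 (34.4%)")
  expect_equal(sex_row$test, "Fisher")

  # identical distributions: p near one for the continuous row
  cohort2 <- cohort
  cohort2$age <- rep(rnorm(n, 67, 7), 2)
  tab2 <- clinical_table(cohort2, continuous = "age", categorical = character(0))
  expect_gt(tab2$p[1], 0.95)
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  set.seed(71)
  for (i in 1:30) {
    a <- sample(0:8, 1); b <- sample(1:8, 1)
    c <- sample(0:8, 1); d <- sample(1:8, 1)
    ref <- fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(fisher_enum(a, b, c, d), ref, tolerance = 1e-9)
  }
  # and the clinical table's categorical row uses that test
  cohort <- data.frame(group = rep(c("control", "PD"), each = 20),
                       flag = rep(c(TRUE, FALSE), c(25, 15))[sample(40)])
  tab <- clinical_table(cohort, continuous = character(0), categorical = "flag")
  n1 <- sum(cohort$flag[cohort$group == "PD"])
  n0 <- sum(cohort$flag[cohort$group == "control"])
  expect_equal(tab$p, fisher_enum(n0, 20 - n0, n1, 20 - n1), tolerance = 1e-9)
})

test_that("ROC models rank nested predictor sets sensibly on effect data", {
  cfg <- generator_config(seed = 77, n_per_group = 150)
  panel <- generate_panel(cfg)
  cd <- generate_cohort(cfg, panel)
  st <- species_tests(cd$concentrations, cd$cohort$group)
  roc <- roc_models(cd$concentrations, cd$cohort, panel, stats = st,
                    n_boot = 300, seed = 5)
  full <- roc[roc$model == "full", ]
  basic <- roc[roc$model == "basic", ]
  expect_gt(full$auc, basic$auc)
  expect_true(full$ci_low <= full$auc && full$auc <= full$ci_high)
  expect_equal(basic$auc, 0.5, tolerance = 0.1)  # matched demographics
  # a perfectly separating species yields AUC 1 for its model
  conc2 <- cd$concentrations
  conc2$sep <- ifelse(cd$cohort$group == "PD", 100, 1) * exp(rnorm(nrow(conc2), 0, 0.01))
  st2 <- st
  st2 <- rbind(st2, st2[1, ])
  st2$name[nrow(st2)] <- "sep"; st2$p_adj[nrow(st2)] <- 1e-10
  panel2 <- rbind(panel, panel[panel$name == "GM3 18:1;O2/24:0", ])
  panel2$name[nrow(panel2)] <- "sep"
  roc2 <- roc_models(conc2, cd$cohort, panel2, stats = st2, n_boot = 100, seed = 5)
  expect_equal(roc2$auc[roc2$model == "full"], 1, tolerance = 1e-6)
})
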