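test_that("the default panel has the stated composition and coverage", {
  panel <- generate_panel()
  expect_equal(nrow(panel), 119L)
  expect_setequal(unique(panel$subclass),
                  c("Cer", "DHS-Cer", "PHS-Cer", "HexCer", "Hex2Cer",
                    "Hex3Cer", "HexNAcHex3Cer", "GM3"))
  expect_true(all(c("C16-SPH", "C17-SPH", "C18-SPH", "C19-SPH",
                    "C18-SPD", "C18-DHS", "C18-PHS") %in% panel$spb))
  expect_true(any(panel$acyl_hydroxyl))
  expect_equal(range(panel$acyl_c), c(16L, 26L))
  expect_false(anyDuplicated(panel$name) > 0)
})

test_that("all generator output is reproducible from the single seed", {
  cfg <- tiny_config(seed = 17, n = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ra <- generate_injection_run(a, cfg)
  rb <- generate_injection_run(b, cfg)
  expect_identical(ra$peaks, rb$peaks)
  ma <- generate_meta_studies(cfg)
  expect_identical(ma, generate_meta_studies(cfg))
  # a different seed moves the data
  cfg2 <- tiny_config(seed = 18, n = 10)
  expect_false(identical(generate_cohort(cfg2)$concentrations[, 2],
                         a$concentrations[, 2]))
})

test_that("cohort tables have the designed size, demographics and truth record", {
  cfg <- generator_config(seed = 23, n_per_group = 250)
  cd <- generate_cohort(cfg)
  expect_equal(nrow(cd$concentrations), 500L)
  expect_equal(nrow(cd$cohort), 500L)
  expect_equal(sum(cd$cohort$group == "PD"), 250L)
  expect_equal(sum(cd$cohort$sex == "F" & cd$cohort$group == "control"), 85L)
  expect_equal(mean(cd$cohort$age), 67.4, tolerance = 1)
  expect_true(all(is.na(cd$cohort$updrs3[cd$cohort$group == "control"])))
  expect_true(all(cd$concentrations[, -1] > 0))
  # truth record designates strong effects as expected-significant
  tr <- cd$truth
  expect_true(all(abs(log2(tr$effects[tr$expected_significant])) >= 0.2))
  expect_true(all(tr$expected_significant %in% tr$affected))
  expect_setequal(names(tr$effects), generate_panel(cfg)$name)
})

test_that("a null effect map leaves the groups exchangeable", {
  # the shared per-sample factor correlates species, so p-values from one
  # cohort are correlated: average over replicate cohorts before judging
  # calibration
  mean_p <- numeric(20); n_sig <- integer(20)
  for (i in 1:20) {
    cfg <- generator_config(seed = 29 + i, n_per_group = 60,
                            effect_multipliers = null_multipliers)
    cd <- generate_cohort(cfg)
    if (i == 1) expect_length(cd$truth$affected, 0)
    st <- species_tests(cd$concentrations, cd$cohort$group)
    mean_p[i] <- mean(st$p)
    n_sig[i] <- sum(st$p_adj < 0.01)
  }
  expect_lt(abs(mean(mean_p) - 0.5), 0.08)
  expect_lte(sum(n_sig), 3)
})

test_that("the default effects move the designed aggregate by the designed ratio", {
  cfg <- generator_config(seed = 37, n_per_group = 250)
  panel <- generate_panel(cfg)
  cd <- generate_cohort(cfg, panel)
  sel <- select_species(panel, subclass = "HexCer", spb = "C18-SPH/D", acyl = "C24")
  tot <- aggregate_concentrations(cd$concentrations, sel)
  pd <- cd$cohort$group == "PD"
  ratio <- mean(tot[pd]) / mean(tot[!pd])
  expect_gte(ratio, 1.05)
  expect_lte(ratio, 1.13)
})

test_that("injection runs have the stated QC cadence and dilution structure", {
  cfg <- generator_config(seed = 41, n_per_group = 60, samples_per_batch = 40,
                          noise_cv = 0)
  cd <- generate_cohort(cfg)
  run <- generate_injection_run(cd, cfg)
  mf <- run$manifest

  # injection order strictly increasing within each batch
  for (b in unique(mf$batch))
    expect_true(all(diff(mf$order[mf$batch == b]) > 0))

  # never more than qc_interval study injections between pooled QCs
  for (b in unique(mf$batch)) {
    roles <- mf$role[mf$batch == b]
    runs <- rle(roles == "study")
    expect_lte(max(runs$lengths[runs$values]), cfg$qc_interval)
    expect_gte(sum(roles == "pooled_qc"), 2L)
  }

  # the 13-point dilution series sits in the first batch, monotone at zero noise
  dil <- mf[mf$role == "dilution_qc", ]
  expect_equal(nrow(dil), 13L)
  expect_equal(sort(dil$dilution_factor), sort(default_dilution_factors()))
  areas <- area_matrix(match_peaks(run$peaks, run$library)$annotated,
                       generate_panel(cfg)$name, mf$injection_id)
  dil_o <- dil[order(dil$dilution_factor), "injection_id"]
  for (sp in colnames(areas)[c(1, 50, 100)])
    expect_true(all(diff(areas[dil_o, sp]) < 0))

  # pooled QC is the mean of all study extracts
  expect_equal(run$truth$qc_concentration,
               colMeans(as.matrix(cd$concentrations[, -1])), tolerance = 1e-12)
})

test_that("meta-study sets honour their size totals and heterogeneity", {
  cfg <- generator_config(seed = 51)
  ms <- generate_meta_studies(cfg)
  eff <- ms$effects
  one <- eff[eff$gene == "GLA", ]
  expect_equal(nrow(one), 18L)
  expect_equal(sum(one$n_case), 166L)
  expect_equal(sum(one$n_control), 140L)
  expect_true(all(one$se > 0))

  # tau = 0: observed between-study variance is explained by sampling error
  cfg0 <- generator_config(seed = 52, tau = 0,
                           gene_effects = c(G1 = -0.4))
  vars <- replicate(60, {
    cfgi <- cfg0; cfgi$seed <- cfg0$seed + sample.int(1e6, 1)
    e <- generate_meta_studies(cfgi)$effects
    var(e$log2fc) - mean(e$se^2)
  })
  expect_equal(mean(vars), 0, tolerance = 0.01)
})
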