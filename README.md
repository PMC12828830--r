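# sphingoquant

Targeted plasma sphingolipidomics for case-control studies: a tested R
pipeline from MRM peak lists to pooled effect sizes.

Plasma ceramides and glycosphingolipids (GSLs) are quantified in targeted
LC-MS/MS assays as hundreds of species — combinations of a head group
(Cer, HexCer, Hex2Cer, Hex3Cer, HexNAcHex3Cer, GM3), a sphingoid base
(sphingosine SPH, sphingadiene SPD, dihydrosphingosine DHS,
phytosphingosine PHS) and an N-acyl chain — and compared between a disease
group and controls. `sphingoquant` implements the full analysis chain for
such studies, with a synthetic-data generator that emulates the acquisition
(pooled QC every 10 samples, 13-point dilution series, batch drift) and
carries ground truth for every guarantee the test suite checks.

The pipeline stages, each an exported function family:

1. **Nomenclature** — parse/format shorthand species names
   (`Cer 18:1;O2/24:0`, legacy `d18:1/24:0` accepted), classify by
   subclass, base (`C18-SPH/D` merged view) and acyl class (`C24`).
2. **Annotation** — theoretical masses (`[M+H]+` precursors, sphingoid-base
   fragment products), transition libraries, and peak matching by
   precursor/product m/z (0.3 Da) and retention time (0.3 min) with a
   deterministic nearest-RT assignment.
3. **Quantification** — class-matched internal standards at 10 nM,
   `conc = area ratio x IS conc x volume factor`, LSI level 2/3 recorded
   per species.
4. **QC** — pooled-QC piecewise-linear drift correction over injection
   order with inter-batch alignment; admission filters CV < 25% (strict)
   and dilution-linearity R^2 > 0.8 (strict, log-log fit).
5. **Statistics** — Welch t tests on log concentrations with
   Benjamini-Hochberg control; subclass/base/acyl aggregation; lipid
   ratios with adjusted odds ratios; Mann-Whitney AUC ROC models with
   bootstrap CIs; severity regressions; a clinical characteristics table.
6. **LSEA** — weighted Kolmogorov-Smirnov enrichment score over species
   ranked by log2 fold change, set-label permutation null, NES and p per
   subclass x base set.
7. **Meta-analysis** — DerSimonian-Laird random-effects pooling of
   per-study log2FC (tau^2, Q, I^2, forest tables) for GSL-degradation and
   ceramide-synthesis genes.

The statistic at the core of each stage is implemented natively and proven
against an independent oracle in the test suite (brute-force step-up for
BH, all-pairs AUC and the trapezoidal ROC integral, an explicit
running-sum walk for the enrichment score, hand-executed DerSimonian-Laird
formulas and `metafor` as cross-check, hypergeometric enumeration for
Fisher's exact test).

## Worked example

```r
library(sphingoquant)

cfg <- generator_config(seed = 1, n_per_group = 250)  # the default design
res <- run_pipeline(cfg)

head(res$stats[order(res$stats$p_adj), c("name", "log2fc", "t", "p_adj")], 5)
#>              name log2fc     t    p_adj
#>  Cer 16:1;O2/20:0 -0.302 -7.70 9.03e-12
#>  Cer 16:1;O2/24:0 -0.288 -7.39 2.53e-11
#>  Cer 19:1;O2/24:0 -0.284 -7.40 2.53e-11
#>  Cer 16:1;O2/22:0 -0.277 -7.31 2.65e-11
#>  Cer 17:1;O2/22:0 -0.294 -7.32 2.65e-11
sum(res$stats$p_adj < 0.01)
#> [1] 28
```

28 of 119 species pass the p_adj < 0.01 cut; the strongest signals are the
depleted noncanonical-base (C16/C17/C19) ceramides the generator plants,
each down about 0.3 log2 units. Ratios of GSLs to their degradation
products are elevated in the case group:

```r
res$ratio_stats[, c("label", "gm_case", "gm_control", "log2fc", "p_adj")]
#>             label gm_case gm_control log2fc    p_adj
#> 1      HexCer/Cer   2.000      1.900 0.0739 8.56e-04
#> 2     GM3/Hex2Cer   1.993      1.802 0.1449 3.95e-10
#> 3 Hex3Cer/Hex2Cer   0.494      0.442 0.1602 2.29e-13
#> 4     Cer/DHS-Cer  17.429     14.892 0.2270 6.10e-26
```

Enrichment concentrates where the effects were planted — HexCer and
Hex3Cer sets with C18 bases up (NES 2.41 and 2.16), dihydroceramides down
(NES -1.94) — and the 18-study meta-analysis recovers the designed
expression shifts:

```r
res$meta$pooled[res$meta$pooled$gene %in% c("GLA", "GBA1", "KDSR"),
                c("gene", "pooled_log2fc", "ci_low", "ci_high", "p")]
#>    gene pooled_log2fc ci_low  ci_high        p
#> 10 GBA1        -0.278 -0.549 -0.00640 4.48e-02
#> 11  GLA        -0.379 -0.621 -0.13633 2.19e-03
#> 16 KDSR         0.565  0.353  0.77634 1.67e-07
```

`write_pipeline_outputs(res, "out/")` writes the volcano, QC report,
ratio, ROC, LSEA, clinical and meta tables plus a markdown run report with
a content-hash manifest.

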