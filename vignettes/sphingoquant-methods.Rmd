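---
title: "Methods: targeted plasma sphingolipidomics from peak lists to pooled effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted plasma sphingolipidomics from peak lists to pooled effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingoquant)
```

`sphingoquant` implements a complete targeted-lipidomics analysis chain for
plasma ceramides and glycosphingolipids (GSLs): species nomenclature, MRM
peak annotation, internal-standard quantification, pooled-QC quality
control, case-control statistics, lipid set enrichment, and random-effects
meta-analysis of enzyme gene expression. This vignette documents the models
and the numerical and design choices, in the order data flow through the
pipeline.

## Nomenclature and structural ontology

Every species is a triple (head group, sphingoid base, N-acyl chain).
The parser accepts the shorthand dialect `"Class C:db;On/C:db[;O]"`
(e.g. `Cer 18:1;O2/24:0`) and the legacy `d/t`-prefix dialect
(`Cer d18:1/24:0`), normalising both to the canonical form; supplementary
panels circulate in both, and the exact dialect of any given export is
rarely documented, so guessing one would be fragile. Base kind is a pure
function of (double bonds, hydroxyls): one double bond with two hydroxyls
is sphingosine (SPH), two is sphingadiene (SPD), none is dihydrosphingosine
(DHS), and the trihydroxy saturated base is phytosphingosine (PHS). Subclass
labels split ceramides by base kind (`Cer`, `DHS-Cer`, `PHS-Cer`) while GSL
classes keep their head-group label. The merged `C18-SPH/D` base view pools
SPH and SPD of equal length for aggregation; it is a view flag, not a loss
of information. Double-bond positions are deliberately not modelled: the
data are species-level (LSI level 2/3), not structure-level.

Hex-level glycan classes (HexCer, Hex2Cer, Hex3Cer, HexNAcHex3Cer, GM3) are
not resolved into linkage isomers (GlcCer vs GalCer, Gb3 vs isoGb3): an MRM
assay of this design cannot distinguish them.

## Annotation

The transition library stores one precursor/product pair per species:
precursor `[M+H]+` of the intact species, product the dehydrated protonated
sphingoid base (`[SPB+H-2H2O]+`, m/z 264.27 for an 18:1;O2 base). The
base-fragment product is a library-construction convention — real methods
vary — and is flagged as such in the documentation. Formulas are assembled
from the ceramide core plus glycosyl residues (hexose C6H10O5, HexNAc
C8H13NO5, NeuAc C11H17NO8).

Matching gates on both ions at `mz_tol = 0.3` Da (unit-resolution
quadrupole) and on retention time at `rt_tol = 0.3` min, then assigns
greedily by increasing |RT error| with one peak per entry per injection.
The greedy nearest-RT rule is deterministic and mirrors dynamic-MRM
practice, where co-eluting shared transitions are resolved by expected RT.
Two library entries with the same transition *and* the same expected RT are
rejected as a configuration error; the same transition at separated RTs is
legal.

## Quantification

Concentrations are single-point internal-standard ratios:

    conc = analyte area / IS area x IS concentration x volume factor

with the class-matched standard (exact head class if spiked, otherwise the
nearest class along Cer-HexCer-Hex2Cer-Hex3Cer-HexNAcHex3Cer, GM3 falling
back to Hex2Cer). The default volume factor of 10 reflects 20 ul plasma
extracted into 200 ul solvent with standards at 10 nM. No response-factor
calibration curve is applied — that is precisely the LSI level-2/3 (not
level-1) claim, and the package records the level per species: level 2 for
Cer, DHS-Cer, HexCer, Hex2Cer and GM3 (class-matched standard), level 3 for
Hex3Cer and everything else (surrogate standard). A lost internal standard
in an injection invalidates only that standard's dependent species, never
the whole injection.

## Quality control

Drift correction is a deterministic pooled-QC interpolation: per species
and batch, the QC responses define a piecewise-linear trend over injection
order (nearest-QC extrapolation at the batch edges); each area is divided
by the local trend and rescaled to the grand QC median, which also aligns
batches. This deliberately replaces ensemble-learning correctors with a
method whose contract — guided by pooled QCs, injection-order aware — is
identical but whose output is reproducible bit for bit, which the test
suite depends on. On drift-free data the correction is the identity.

Species admission uses two gates, both strict inequalities as printed in
the emulating protocol: CV < 25% across pooled-QC injections (computed on
*corrected* areas — correction precedes filtering) and dilution-series
R^2 > 0.8. The linearity fit regresses log(area) on log(1/DF) over the
13-point series (factors 1–10,000): across four decades a linear-scale fit
would be dominated by the undiluted point, so the log-log choice is the
default, recorded in the QC call and switchable in principle by fitting on
other scales upstream. Whether the emulated protocol fitted log- or
linear-scale signal is not documented; this is an explicit design choice.
Points that fall below detection at high dilution are dropped and counted;
fewer than four usable points rejects the species.

## Case-control statistics

Concentrations are log-transformed (natural log) and tested per species
with Welch's unequal-variance t test; the pooled-variance Student variant
is available behind a flag. The emulated protocol says only "multiple
t-tests"; Welch is the safer default under unequal group variances. Fold
changes are reported in base 2. Benjamini-Hochberg adjustment runs across
all tested species, and the downstream significance rule is p_adj < 0.01.

Aggregations (subclass totals restricted to C18-SPH/D bases and C24 acyl
chains, base-resolved ceramide totals, acyl-chain proportion profiles) are
plain sums of the selected species, with missing cells treated as absent
and counted. "C24" pools all saturations (24:0, 24:1, ...) by default;
hydroxylated acyls are flagged separately and excluded from the chain
distribution's default selection. Lipid ratios (HexCer/Cer, GM3/Hex2Cer,
Hex3Cer/Hex2Cer, Cer/DHS-Cer, all C18-SPH/D + C24 by default) are tested on
the log ratio with BH over the ratio family; adjusted odds ratios come from
a logistic fit of case status on the (standardised) log ratio with age and
sex, Wald 95% CI. The Cer/DHS-Cer ratio's direction is reported from the
data, never hard-coded: the source material is internally inconsistent
about its sign (figure caption vs text), and the generator's defaults
(DHS-Cer down, Cer unchanged) imply an elevated ratio in cases.

ROC models are nested logistic scores — basic (age + sex), GSL species,
ceramide species, full (all species passing p_adj < 0.01) — with AUC
computed as the Mann-Whitney pairwise statistic (identical to the
trapezoidal ROC area; the suite proves the identity). Lipid models include
age and sex by default because the emulated description is ambiguous on
this point; a flag exposes lipid-only scores. AUCs are in-sample. The 95%
CI is a seeded percentile bootstrap over samples (2000 resamples) rather
than DeLong, keeping the dependency surface small. Severity associations
(e.g. motor score on lipid level with age, sex, duration and medication
dose as covariates) are ordinary least squares among cases with BH across
lipids. The clinical table gates continuous rows on Shapiro-Wilk normality
at 0.05 (the emulated protocol names no test), pools variance per Levene
(Brown-Forsythe), and uses Fisher's exact test for categorical rows.

## Lipid set enrichment

LSEA is the weighted Kolmogorov-Smirnov running sum: species are ranked by
log2 fold change (descending, ties broken lexicographically by name so the
order is total and deterministic); set hits add `|metric|^p` normalised
over the set (p = 1), misses subtract `1/(N - set size)`; ES is the signed
maximum deviation, with an exact tie between the positive and negative
extremum resolved to the positive one. The null reshuffles set membership
over the ranked list (set-label permutation, default 1000 draws, seeded);
NES divides ES by the mean same-sign null magnitude and p is the same-sign
exceedance frequency with the +1 continuity correction. Two choices are
worth flagging: the ranking covers *all* QC-passing species by default
(restricting to significant species is a flag), and set-label permutation
was chosen over phenotype permutation; the web services this emulates do
not document either choice, so their printed NES values should be treated
as approximate references.

## Meta-analysis

Per-study effects arrive as log2FC with SE (or a symmetric 95% CI,
converted by SE = width / 3.92). Pooling is DerSimonian-Laird:
fixed-effect weights give Q, the method-of-moments tau^2 truncated at
zero, random-effects weights give the pooled estimate with a Wald 95% CI,
and I^2 = max(0, (Q - (k-1))/Q). DL is the canonical, closed-form choice;
REML is available behind a flag and is cross-checked against `metafor` in
the test suite (metafor is never the implementation). With tau^2 = 0 the
pool reduces exactly to fixed-effect inverse variance. The default gene
lists cover lysosomal GSL degradation (GBA1, GLB1, GLA, NEU1-4, HEXA/B,
GM2A) and de novo ceramide synthesis (SPTLC1-3, SPTSSA/B, KDSR, CERS1-6,
DEGS1/2, FADS3). Case and incidental-Lewy-body subjects are pooled as one
case group per dataset, matching the upstream inclusion design.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every guarantee is verified.

**Panel.** 119 species across the eight subclasses, bases C16-C19
(SPH, SPD, DHS, PHS) and acyls C16-C26 including 2-hydroxy ceramides. The
real panel's per-subclass composition is supplementary-only upstream, so
this composition is a stated default chosen once, not a reproduction.

**Concentrations.** Log-normal (plasma lipid levels are right-skewed, and
the downstream tests log-transform), arithmetic-mean parameterised. Means
are anchored so the C18-SPH/D + C24 subclass totals match the printed
control means where available — HexCer 5734.3, Hex3Cer 539.2, GM3 2210.5
nM — with the remaining subclasses set to plausible plasma values (Cer
3000, Hex2Cer 1200, DHS-Cer 200, HexNAcHex3Cer 60, PHS-Cer 30 nM). The
per-species CV defaults to 0.30, matching the printed HexCer sd/mean of
about 0.29; a per-sample shared log-normal factor (CV 0.25) carries most of
it, because with independent species the CV of a subclass *total* would
shrink well below the printed value. The shared factor also means p-values
within one null cohort are correlated — calibration tests therefore average
over replicate cohorts.

**Effects.** The default case map encodes the emulated study's qualitative
findings as truth for power and recovery testing, not as biology: C18-base
HexCer/Hex3Cer/GM3 x1.09 (the printed HexCer case/control ratio is
6270.1/5734.3 ~ 1.093; Hex2Cer is deliberately left null because the
emulated study found no difference there), DHS-Cer x0.90, noncanonical
C16/C17/C19-base ceramides x0.85, and a C22 (x0.94) to C24 (x1.04)
redistribution within C18-SPH/D ceramides. The truth record designates as
*expected significant* the species with |log2 effect| >= 0.2 — at
n = 250/group and CV 0.30 a z-calculation puts their per-test power near 1
even at Bonferroni-like thresholds, while the 9-10% effects sit near 60-90%
power at BH 0.01 and therefore cannot be promised in every replicate (the
emulated study itself called only 35 of 119 species significant). Weaker
effects are designated directional-only: any species that does reach
significance must move in the designed direction.

**Acquisition.** Study samples are injected in randomized order, as in
practice, so batch position never confounds the group contrast. Injections
are organised in batches of 100 study samples
with a pooled QC (the mean of all study extracts) bracketing every 10, the
13-point dilution series appended to the first batch, and internal
standards in every injection. Areas are extract concentration x response
factor x drift x log-normal noise (CV 0.05 default). Response factors are
equal within an internal standard's class by default — exactly the level-2
class-matched-standard assumption, which makes the noise-free round trip
exact; a `response_factor_cv` knob introduces per-species bias for
robustness work. Drift is a smooth per-batch multiplicative trend (linear
plus one low-frequency sinusoid, amplitude 0.15 by default) with a
per-species sensitivity in [0.6, 1.4], so drift does not cancel in the
internal-standard ratio and the QC correction has real work to do.

**Meta studies.** 18 studies with group sizes partitioned to totals of
166 cases and 140 controls; per-gene true effects default to the printed
pooled estimates (GLA -0.47, GBA1 -0.27, KDSR +0.56, ...), between-study
sd tau = 0.15, within-group sd 0.9 on the log2 expression scale — which
reproduces pooled CI half-widths near the printed ~0.24.

All randomness flows from the single config seed; equal configs give
byte-identical output.

## What the synthetic tests do and do not show

Passing on synthetic data demonstrates the *statistical machinery* —
calibration of the FDR under the null, power at the designed effect sizes,
drift removal, CI coverage of the pooling — under the generator's
assumptions: log-normal concentrations, a single shared covariance factor,
smooth drift, class-uniform response. Real plasma data violate all four in
degree (heavier tails, block-structured correlation, drift steps after
maintenance events, genuine response-factor spread), so synthetic
agreement bounds optimism: it validates the code and the design, not the
biology. In particular the full-model in-sample AUC on synthetic effect
data exceeds the published discrimination, because the generator's strong
noncanonical-ceramide effects are cleaner than real between-subject
heterogeneity.

## Problem sizes and determinism

Default analyses run at the study design (n = 250/group, 119 species,
1000 LSEA permutations, 2000 bootstrap resamples, 18 meta studies).
Replicated guarantees use 200 null cohorts (FDR), 100 effect cohorts
(recovery), and 500 meta replicates (coverage); unit tests use smaller
cohorts (n = 5-60) since they check identities, not power. Every stochastic
step takes an explicit seed, and rerunning any stage with an equal
configuration reproduces its output exactly, including file content hashes
in the written outputs.

## Example

```{r, eval = FALSE}
cfg <- generator_config(seed = 1, n_per_group = 250)
res <- run_pipeline(cfg)
head(res$stats[order(res$stats$p_adj), ])
res$roc
res$lsea
res$meta$pooled
```
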