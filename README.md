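# lipidald

Plasma lipidomics analysis for X-linked adrenoleukodystrophy (ALD)
biomarker studies.

ALD is caused by pathogenic *ABCD1* variants that impair peroxisomal
β-oxidation, so very long-chain fatty acids (VLCFA, ≥C22:0) accumulate and
are incorporated into many plasma lipid classes — lysophosphatidylcholines
(LPC), phosphatidylcholines (PC), triglycerides (TG), cholesterol esters
(CE) and others. `lipidald` implements the full analysis chain such a study
needs, for researchers working with untargeted LC-MS lipidomics feature
tables, targeted isotope-dilution assays (LPC(26:0), total C26:0), and
clinically stratified cohorts:

- **Lipid chemistry.** Generic class formulas with radyl ("R") slots are
  expanded over (total carbons *n*, total double bonds *d*) grids into
  sum-composition species, e.g. LPC(*n*:*d*) = C(n+8)H(2n+18−2d)NO₇P. Each
  species gets a neutral monoisotopic mass and an adduct m/z catalog
  (m/z = (M + shift)/|z|, electron-mass-corrected shifts).
- **Annotation.** Accurate-mass lookup of features against the catalog
  within a ppm window, one accepted identity per feature (smallest |ppm|,
  deterministic tie-breaks), optional per-class retention-time windows.
- **Semi-quantification.** abundance = (analyte area / class internal
  standard area) × (IS amount / plasma volume), in arbitrary units (A.U.);
  targeted concentrations from labeled-standard area ratios
  (ratio × amount/volume, e.g. 72 nmol/L at ratio 0.072 with 0.01 nmol in
  10 µL).
- **Cohort stratification.** Cerebral ALD, adrenal insufficiency and
  spinal-cord severity (severe: EDSS > 6; mild restricted to age > 55 in
  males, age > 40 in females), with strict boundary conventions and logged
  exclusions.
- **Differential statistics.** Per lipid: Shapiro–Wilk-routed Welch *t* /
  Mann–Whitney *U* tests, fold change as the ratio of group means,
  Benjamini–Hochberg adjustment per contrast (Bonferroni and Holm also
  reported), volcano classification (elevated: FC > 1.5 and adjusted
  p < 0.05), Kruskal–Wallis + Dunn for multi-group comparisons,
  Spearman/Pearson correlation, PCA and PLS-DA scores.
- **Chain profiling.** Per-class LOESS trend of log₂FC vs total chain
  length and (length × unsaturation) heatmap matrices.
- **Biomarker layers.** X-inactivation vs LPC(26:0) linear correlation and
  post-transplant exponential decay fits
  C(t) = P + (C₀ − P)·e^(−kt).
- **Synthetic studies.** A seeded generator producing cohorts, lipidomes
  with planted chain-length effects (log₂FC = β·max(0, n−n₀)·s(d)),
  targeted biomarkers, XCI couplings and post-HCT trajectories, so every
  stage is testable end to end without patient data.

## Worked example

```r
library(lipidald)

study  <- simulate_ald_study(simulation_config(seed = 1))
cohort <- study$cohort
ald    <- cohort$sample_id[cohort$group %in% c("CALD", "noCALD")]
ctrl   <- cohort$sample_id[cohort$group == "control"]

v <- volcano(study$abundance, ald, ctrl, groups = c("ALD", "control"))
glance(v)
#>   n_lipids n_tested n_welch n_mann_whitney n_elevated n_lower
#> 1      291      291     126            165         21       0

chain_trend(v, "LPC")$spearman_fit
#> [1] 0.97

glance(fit_hct_decay(study$hct))
#>   baseline plateau     k half_life sigma  n
#> 1     418.    198. 0.194      3.57  41.2 48

correlate(study$xci$xci_fraction, study$xci$lpc26, "pearson")$estimate
#> [1] 0.81
```

Reading: of 291 simulated lipids, 21 are significantly elevated in ALD
(> 1.5-fold, BH-adjusted p < 0.05) and none are lower — the VLCFA
asymmetry the generator plants. The LPC fold changes rise monotonically
with chain length (Spearman of the LOESS fit vs carbons = 0.97). The
post-transplant LPC(26:0) course decays from ≈ 418 nmol/L toward a
plateau of ≈ 198 nmol/L with rate 0.19/month, and X-inactivation skewing
correlates with LPC(26:0) at r = 0.81 in this draw (population target
0.79). `autoplot()` renders each result (volcano, chain trend, heatmap,
PCA/PLS-DA scores, decay fit).

A command-line wrapper covers the same pipeline
(`inst/scripts/lipidald simulate|build-db|annotate|quantify|compare|chain-profile|correlate|hct-trend`).

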