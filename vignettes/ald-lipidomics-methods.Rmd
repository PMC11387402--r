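---
title: "Methods: lipid chemistry, stratified statistics, and the synthetic ALD study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid chemistry, stratified statistics, and the synthetic ALD study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidald)
```

`lipidald` analyses plasma lipidomes of X-linked adrenoleukodystrophy
(ALD) cohorts: it annotates LC-MS features by accurate mass, converts
peak areas to semi-quantitative abundances, compares clinically defined
patient strata lipid by lipid, profiles the chain-length structure of
the differences, and models two targeted biomarker layers
(X-inactivation coupling and post-transplant decay of LPC(26:0)). This
vignette records the models, the defaults and why they were chosen, and
what the synthetic study generator does and does not emulate.

## Lipid chemistry

A lipid class is a generic formula with radyl slots. For a sum
composition with total radyl carbons $n$ and total double bonds $d$,
every class reduces to

$$\mathrm{C}_{n + a}\,\mathrm{H}_{2n + b - 2d}\,X$$

with class constants $a$, $b$ and a fixed heteroatom block $X$, because
each acyl chain contributes $\mathrm{C}_n\mathrm{H}_{2n-2d}\mathrm{O}_2$
and each condensation removes one water. The constants shipped in
`inst/extdata/lipid_classes.yaml` are the unique values consistent with
building each class from glycerol/sphingoid backbone + headgroup +
fatty acyls (the test suite re-derives every class from that
composition identity independently). For sphingolipids $d$ counts the
sphingoid 4,5-ene, and the formulas assume the common d-type (dihydroxy)
sphingoid base.

Monoisotopic masses are exact weighted sums over a CODATA-derived
element table; adduct m/z is $(M + s)/|z|$ with electron-mass-corrected
shifts $s$ (for $[\mathrm{M+H}]^+$, $s$ is the proton mass 1.007276 Da).
The engine reproduces the targeted assay's printed precursor for 1-acyl
LPC(26:0): neutral mass 635.4890 Da, $[\mathrm{M+H}]^+$ 636.4963 →
636.50 at the instrument's two decimals. The deuterated internal
standard D4-LPC(26:0) computes to 640.52, while targeted assays commonly
print 640.50; we treat that as a unit-resolution acquisition setting and
do not force agreement.

Defaults worth knowing:

- **Radyl grids** (total carbons): 10–30 for 1-radyl classes, 20–60 for
  2-radyl, 30–80 for TG, 40–88 for cardiolipin; $d$ 0–12. These cover
  every species a VLCFA-focused plasma study reports (ALD pushes LPC/CE
  beyond 26 carbons and TG beyond 60) with headroom; the grid is
  configuration, not truth, and chemically impossible corners simply
  yield species nobody annotates.
- **Adducts**: $[\mathrm{M+H}]^+$, $[\mathrm{M+NH_4}]^+$,
  $[\mathrm{M+Na}]^+$, $[\mathrm{M-H}]^-$, $[\mathrm{M+HCOO}]^-$ — the
  workhorse electrospray set for methanol/ammonium mobile phases;
  configurable per class.
- **Annotation tolerance**: 5 ppm default. High-resolution Orbitrap data
  (resolution ~280,000) justify a few ppm; the exact window is
  configuration. One identity is accepted per feature — smallest |ppm
  error|, ties broken by adduct priority then lexicographic name, which
  makes annotation deterministic and order-independent. True isobars
  exist (LPC($n$:$d$) and LPE($n{+}3$:$d$) share a formula); without
  retention-time windows the lexicographically first name wins, so
  supplying per-class RT windows is the way to separate them.

## Semi-quantification

Abundance = (analyte area / class internal-standard area) ×
(IS amount / plasma volume). With amounts in nmol and volume in µL the
scale factor is nmol/µL ≡ mmol/L, but because per-species response
factors are not calibrated the output is labelled arbitrary units
(A.U.). All downstream statistics are ratio- and rank-based, so any
per-sample multiplicative response drift cancels exactly (tested as an
invariance). Missing or zero IS areas flag the (class, sample) pair and
propagate `NA` — never zero-fill, which would fabricate depletion.

Targeted isotope-dilution concentrations use the same ratio law against
a labeled standard; 0.01 nmol of D4-LPC(26:0) in 10 µL plasma makes an
area ratio of 0.072 equal 72 nmol/L, the healthy upper reference limit
scale of the LPC(26:0) assay.

## Cohort stratification

Male patients are grouped three ways: cerebral ALD present/absent,
adrenal insufficiency present/absent, and spinal-cord severity. Because
cerebral disease and adrenal failure rarely first appear after roughly
age 55, the "absent" strata have age-restricted variants (age > 55,
strict) that are less contaminated by patients who may still convert;
severity uses EDSS > 6 as severe (any age) versus mild (EDSS ≤ 6)
restricted to age > 55. EDSS exactly 6 is mild. Patients without an
EDSS score leave the severity contrast only, and every exclusion is
logged with a reason.

Women enter the severity contrast above age 40 (spinal-cord disease is
rare before the fourth decade). Two severity rules are implemented: an
EDSS threshold (default, severe EDSS > 6) and a recorded
spinal-cord-disease flag; published cohorts have used both, and they can
disagree on real records (flag-positive women with EDSS ≤ 6), so the
rule is a configuration choice rather than a constant. The synthetic
generator emits records on which both rules agree.

## Differential statistics

Per lipid and contrast: Shapiro–Wilk on each group routes to Welch's
*t*-test (both groups p ≥ 0.05) or the Mann–Whitney *U* test; groups
under n = 3 force the rank test. The U test uses the exact null when
the smaller group has n ≤ 8 without ties, otherwise the tie-corrected
normal approximation with continuity correction. Fold change is the
ratio of group means — validated against the published targeted-assay
tables, where the ratios of printed group means reproduce all twelve
printed fold changes within the precision of the printed digits
(`reproduce_reference_tables()`); tests run on raw abundances by
default with a log2 toggle, since the routing already diverts heavy
tails to the rank test. Benjamini–Hochberg adjustment is applied across
all lipids within one contrast ("per-comparison"); Bonferroni and Holm
are reported alongside. Volcano labels use the adjusted p (elevated:
FC > 1.5 and p < 0.05; lower: FC < 1/1.5), matching the convention of
counting discoveries after FDR correction even when axes show raw p.
Kruskal–Wallis with hand-rolled Dunn z-tests (no installed package
provides Dunn's post hoc) covers multi-group comparisons; pairwise p
are BH-adjusted within their family.

PCA operates on log2-transformed, centered abundances via SVD; PLS-DA
(two components, via mixOmics) against one-hot labels is used for
visualization only — no cross-validated classification claims.

## Chain profiling

Within a class, log2 fold changes are plotted against total chain
length with a LOESS curve (span 0.75, degree 2 — standard smoother
defaults; the curve type, not its span, is the methodological choice),
evaluated on the integer carbon numbers present, and summarized by the
Spearman correlation of the fitted curve with chain length. Unsaturation
is never smoothed: the (length × unsaturation) heatmap carries the
comparison's log2FC values through exactly.

## Biomarker layers

X-inactivation skewing toward the variant allele is correlated with
plasma LPC(26:0) (Pearson, two-sided). Post-transplant trajectories are
fit by Levenberg–Marquardt nonlinear least squares to
$C(t) = P + (C_0 - P)e^{-kt}$ — baseline $C_0$, plateau $P$, decay rate
$k$ per month — pooling points across patients; `glance()` reports the
half-life $\ln 2 / k$. The plateau is a real feature of the biology:
levels fall after transplantation but stay above the healthy reference
limit.

## The synthetic study generator

`simulate_ald_study()` produces a full study from one seed, with all
stage seeds derived deterministically (regeneration is bit-identical,
and the planted truth travels with each table).

What it emulates:

- **Cohort structure**: 92 male patients engineered to the study-style
  stratification counts (24 cerebral, 68 non-cerebral of whom 21 over
  55, 50 with adrenal insufficiency, 15 severe, 17 mild over 55), 65
  women (54 over 40, split 28 mild / 26 severe), 12 + 12 healthy
  controls, 12 transplanted cerebral patients.
- **Lipidome effects**: per-lipid baselines are log-normal (sdlog 1
  across lipids); disease groups get
  $\log_2\mathrm{FC} = \beta_g \cdot \max(0, n - n_0) \cdot s(d)$ with
  hinge $n_0$ = 20/40/60 carbons for 1/2/3-chain classes, saturation
  damping $s(d) = \max(0, 1 - d/d_{max})$, and
  $\beta_{\mathrm{CALD}} = 0.18 > \beta_{\mathrm{noCALD}} = 0.12$ per
  carbon — a VLCFA enrichment that grows with chain length and fades
  with unsaturation, stronger in cerebral disease. Multiplicative
  measurement noise at CV 0.2, a mid-range lipidomics repeatability.
- **Targeted biomarkers**: healthy LPC(26:0) is log-normal with its
  97.5th percentile at the 72 nmol/L upper reference limit (median 36,
  sdlog 0.35); patient groups use published-scale means (cerebral 600,
  non-cerebral 395, female severe 337 / mild 235 nmol/L). Total C26:0
  couples to LPC(26:0) on the log scale with noise derived at
  generation time so the population correlation hits the 0.7 target.
- **XCI coupling**: fractions uniform on (0,1), LPC(26:0) linear in the
  fraction with Gaussian noise of variance
  $\sigma^2 = b^2\sigma_x^2(1/r^2 - 1)$, so the population Pearson r is
  exactly the configured 0.79.
- **Post-transplant decay**: per-patient exponential decay with
  log-normal random effects; defaults $C_0$ = 435 nmol/L, $P$ = 185.5,
  $k$ = 0.167/month were solved from the published group means 435 →
  219 (12 months) → 190 nmol/L, and plateaus are floored strictly above
  the 72 nmol/L reference limit.

What it does not emulate: raw spectra or chromatography (feature tables
are the ingestion boundary), retention-time structure, correlated
lipid-lipid covariance, batch effects, missingness mechanisms, age or
diet effects on the lipidome, or any genotype model. Passing tests on
synthetic data therefore demonstrate that the *pipeline arithmetic and
inference behave as specified under the planted statistical structure*,
not that the biological effect sizes are those of any real cohort.

## Numerical choices and edge cases

- Zero-variance groups: Welch on two equal constant groups returns
  p = 1 (statistic 0) instead of erroring; zero-variance correlation
  inputs return `NA` with a warning.
- Constant lipid rows are dropped (with a warning) before PCA/PLS-DA;
  log2 transforms guard zeros with half the smallest positive value.
- Catalog queries use binary search on the sorted m/z vector and are
  exact with respect to a linear scan (property-tested on 10⁴ random
  windows).
- LOESS uses `surface = "direct"` so span-1, degree-1 fits reproduce
  collinear data exactly.
- The decay fit starts from data-driven values (baseline mean, minimum
  value, k = 0.1/month) with non-negativity bounds; Levenberg–Marquardt
  tolerates the plateau/baseline collinearity of short series.
- Missing values are empty fields in all I/O, never zeros; duplicate
  lipid rows and decimal-comma dialects are hard errors.

## Problem sizes

The shipped test suite exercises the default 291-lipid grid with the
full 104-sample male cohort for pipeline tests; FDR calibration uses
200 null replicates of 300 lipids at n = 20 per group; coupling
calibrations use 500 replicates at n = 28 (XCI) and 200 replicates of
12 trajectories (decay). These sizes give the calibration assertions
comfortable Monte-Carlo margins while keeping a full run in a few
minutes on one core.

## Known limitations

- Annotation assigns exactly one identity per feature; co-eluting
  isobars and adduct deconvolution across features are out of scope.
- Semi-quantification is relative; absolute concentrations require
  response-factor calibration the package deliberately does not model.
- The female severity rules can disagree on real records; results for
  borderline EDSS values depend on the configured rule.
- PLS-DA scores are descriptive; no permutation testing or
  cross-validation is provided.
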