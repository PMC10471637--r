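---
title: "Predicting hamstring graft diameter from MRI: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hamstring graft diameter from MRI: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftsize)
```

## The clinical problem

In anterior cruciate ligament (ACL) reconstruction with a doubled
semitendinosus + gracilis (ST + GT) four-strand autograft, the graft's
diameter is fixed by the patient's anatomy, not chosen by the surgeon.
Grafts of 7 mm or less are associated with a higher re-rupture risk, so
knowing the expected diameter *before* surgery lets the surgeon plan an
alternative graft or preparation technique. Both tendons are visible on the
same knee MRI used to diagnose the rupture, which makes a simple
measurement-based prediction attractive: no extra imaging, no extra cost.

## The prediction rule

On a transverse MRI slice each tendon's cross-section is measured along its
longest axis (major diameter, $D$) and shortest axis (minor diameter, $d$),
at the 0.1-mm resolution of the measurement software. The predicted graft
diameter is

$$\mathrm{PGD} \;=\; \frac{D_{ST} + d_{ST}}{2} \;+\; \frac{D_{GT} + d_{GT}}{2},$$

rounded **up** to the next full millimetre. The ceiling rule reflects tunnel
fit: intraoperatively a graft passes through a larger tunnel but not a
smaller one. We read "rounded up by excess" strictly as the ceiling
function, so an exact integer maps to itself — a graft predicted at exactly
7.00 mm fits a 7-mm tunnel and is not bumped to 8.

Because the four inputs each carry one decimal, the two per-tendon means
are exact at two decimals and so is their sum. The implementation performs
this arithmetic on integer tenths of a millimetre, so no hidden binary
floating-point rounding can move a value across the ceiling boundary:
two-decimal exactness is asserted by construction, never produced by
rounding.

```{r}
predicted_graft_diameter(4.6, 4.0, 3.4, 3.0)
```

## Validation statistics

The package validates the rule the way method-comparison studies in
clinical measurement do.

**Agreement with the surgical size.** The rounded prediction is compared to
the intraoperative graft diameter (integer mm from the surgical report).
Each patient is classified as concordant, under-predicted (prediction
smaller than the actual graft) or over-predicted; rates carry exact
Clopper–Pearson binomial confidence intervals. Clopper–Pearson is the
default because it is exact at these sample sizes; the Wilson score
interval is available as an option. Chance-corrected agreement uses
linearly weighted Cohen's $\kappa$ with disagreement weights
$w_{ij} = |i-j|/(k-1)$ over a grid of consecutive integer sizes spanning
the observed range — unobserved interior sizes stay in the grid so the
weights keep their millimetre meaning. $\kappa$ is interpreted on McHugh's
verbal scale after rounding to two decimals (so $\kappa = 0.797$ reads
0.80, "Strong"); without the rounding step the conventional band labels
cannot reproduce published usage. When both raters put all mass in one
category the expected disagreement is zero and $\kappa$ is undefined: the
result is flagged degenerate rather than coerced to 0 or 1.

**Reader reproducibility.** Intra-reader (reader 1, baseline vs one-month
repeat) and inter-reader (reader 1 vs reader 2 at baseline) agreement of
the per-tendon mean diameter $(D+d)/2$ — the quantity that feeds the rule —
is summarised by Bland–Altman bias (mean difference) and coefficient of
repeatability, $\mathrm{CoR} = 1.96 \times SD$ of the paired differences;
95% of absolute differences between repeated readings are expected to fall
below the CoR. The alternative CoR definition $2.77 \times$ within-subject
SD is documented but not used. Difference orientations are fixed
(baseline − repeat; reader 1 − reader 2) so the sign of a bias is
interpretable. Whether the inter-reader comparison should use the baseline
session or the average of both sessions is genuinely open in study
protocols; the default is baseline, with `inter_session = "mean"`
available.

**Distribution comparison.** Predicted and actual diameters are summarised
as median and IQR (linear interpolation of order statistics, the "type 7"
convention — published IQRs cannot adjudicate the convention without raw
data, so we use the most common one). The Wilcoxon signed-rank test
compares the **rounded** prediction to the actual size. This is a
deliberate like-for-like choice: the raw two-decimal PGD sits almost
surely strictly below its own ceiling, so testing it against integer
surgical sizes would detect the rounding offset itself (differences
concentrated near +0.5 mm) rather than any failure of the prediction. On
integer pairs most differences are zero; zeros are discarded before
ranking (Wilcoxon's original procedure; Pratt's method is available), tied
absolute differences receive midranks, and the null distribution of the
rank sum is computed exactly by dynamic programming over the doubled
midranks whenever at most 25 non-zero differences remain — the DP stays
valid under ties, where the classical no-ties tables do not — and by a
normal approximation with tie and continuity corrections otherwise. When
every difference is zero the test is degenerate and reported with p = 1.

## The synthetic cohort generator

No patient-level data accompany the published rule, so the package ships a
seeded generator that emulates the *structure* of such a study and makes
every pipeline stage testable end to end:

* true per-tendon mean diameters drawn per patient from Normal
  distributions; major/minor axes derived from the mean and a fixed
  cross-section eccentricity (`major = e × minor`);
* eight measurements per patient (2 readers × 2 sessions × 2 tendons),
  each the true axis length plus independent Normal reader noise,
  quantized to the 0.1-mm grid;
* an actual (intraoperative) size generated **relative to the true,
  noise-free rounded PGD**: 1 mm above it with probability `p_under`,
  below it with probability `p_over` (2 mm below in a configurable
  fraction of over-prediction cases, default 1/6), equal otherwise. Tying
  the actual size to the noise-free prediction keeps biological
  discordance and measurement noise separately controllable; the true
  values are stored in the cohort's metadata for audit and
  parameter-recovery tests.

The calibrated defaults are the package's reference study conditions:
n = 92 patients, ST mean 4.3 ± 0.45 mm, GT mean 3.2 ± 0.40 mm,
eccentricity 1.25, reader noise SD 0.03 mm, quantum 0.1 mm,
`p_under` = 8/92, `p_over` = 6/92, 79% male, ages uniform on 18–55. The
tendon distributions and eccentricity are *calibration choices, not
measured population quantities*: they are set once so that the true PGD
median falls near 7.5 mm, actual sizes concentrate on 7–9 mm with median
8 mm, concordance sits near 85% and repeatability coefficients land in the
few-hundredths-of-a-millimetre range typical of this measurement. The
noise SD of 0.03 mm reproduces repeatability coefficients of roughly
0.06–0.11 mm once quantization is accounted for.

```{r}
cohort <- simulate_cohort(calibrated_default_config(seed = 1))
report <- study_report(cohort)
report$agreement
report$reproducibility
```

Two consequences of the model are worth knowing. First, reader noise
occasionally pushes the measured PGD across a millimetre boundary
(expected absolute PGD measurement error ≈ 0.03 mm at the defaults), so
the concordance measured through the full pipeline runs two to three
percentage points *below* the generative `p_equal` — the generator's
probabilities are recovered exactly only against its own recorded true
predictions. Second, with noise well below the 0.1-mm quantum, repeated
measurements usually land on the same grid point, which keeps the CoR far
below the grid size; the closed form
$\mathrm{CoR} = 1.96\sqrt{2}\,\sigma_{noise}$ for repeated
single-axis readings holds to within a few percent only when the noise SD
is comparable to or larger than the quantum (the package tests this at
SD 0.2 mm).

What the generator does **not** emulate: side/sex/age effects on tendon
size, between-slice selection variability, reader drift over time,
correlated noise between the two axes of one tendon, and non-Normal tendon
size distributions. Passing tests on synthetic cohorts therefore validate
the statistical machinery and the pipeline's bookkeeping, not the clinical
accuracy of the rule on any real population.

## Numerical and design choices

* **Grid exactness.** Diameters are snapped to the 0.1-mm grid on ingest
  and all means/sums are computed on integer tenths; the ceiling is taken
  after snapping to a 10⁻⁹ grid so float representations of exact decimals
  (e.g. `4.05 + 3.95`) are never bumped a millimetre up.
* **Display rounding.** JSON reports carry full precision; integer
  percentages (rounded half away from zero), two-decimal millimetres and
  three-decimal $\kappa$ appear only in the markdown rendering and print
  methods, so downstream consumers never double-round. Note that 6/92 =
  6.52% displays as 7%.
* **Degenerate inputs.** Empty cohorts, all-zero difference vectors,
  single-category $\kappa$ tables and missing actual sizes each have a
  defined, flagged outcome rather than an error or a silent number.
* **Exclusions are loud.** Records excluded from any stage (incomplete
  measurements, missing actual size) are counted and reported; tests
  reconcile the counts so silent drops cannot pass.
* **Reader reconciliation.** The headline prediction uses reader 1 at
  baseline by default; averaging both readers and sessions
  (`reconcile = "mean"`) is provided because protocols differ on this
  point and the choice is not derivable from printed results.
* **Problem sizes in tests.** Property tests run at sizes chosen for tight
  Monte-Carlo bounds at interactive speed: 1000 random $\kappa$ tables,
  Bland–Altman closed-form recovery at n = 10,000, discordance-probability
  recovery over 200 replicates of n = 92, and 2000 null replicates for the
  signed-rank type-I error.

## Limitations

The package validates a measurement rule's statistics; it does not touch
image acquisition, slice selection, or segmentation, and it cannot
reproduce cohort-level published statistics that depend on undeposited raw
data ($\kappa$, biases, CoRs, medians) — those are covered by
property-based tests and by simulation under the calibrated defaults
instead. The agreement analysis assumes integer millimetre surgical sizes;
half-millimetre graft sizing systems would need a finer category grid.
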