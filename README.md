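# graftsize

Pre-operative prediction of hamstring autograft diameter for ACL
reconstruction, with the complete statistical validation pipeline a
method-comparison study needs.

## The problem

In ACL reconstruction with a doubled semitendinosus + gracilis (ST + GT)
four-strand graft, the graft diameter is dictated by the patient's tendons.
Grafts of 7 mm or less carry a higher re-rupture risk, so surgeons want the
expected size *before* surgery. Both tendons are visible on the same knee
MRI used to diagnose the rupture: measuring each tendon's major (D) and
minor (d) cross-sectional diameters on one transverse slice gives the
predicted graft diameter

```
PGD = (D_ST + d_ST)/2 + (D_GT + d_GT)/2,   rounded up to the next full mm
```

(ceiling, because a graft fits a larger tunnel but not a smaller one; exact
integers are not bumped). `graftsize` implements this rule and everything
needed to validate it against surgical reports:

- **Agreement**: concordant / under- / over-prediction rates with exact
  Clopper–Pearson confidence intervals, and linearly weighted Cohen's κ
  over the integer millimetre grid, banded on McHugh's verbal scale.
- **Reproducibility**: Bland–Altman bias and coefficient of repeatability
  (CoR = 1.96 × SD of paired differences) for intra-reader and
  inter-reader comparisons of the per-tendon mean diameter.
- **Distribution comparison**: median/IQR summaries and a Wilcoxon
  signed-rank test (exact under ties via dynamic programming at small n).
- **Synthetic cohorts**: a seeded generator emulating the study structure
  (2 readers × 2 sessions × 2 tendons, 0.1-mm quantization, reader noise,
  integer surgical sizes concentrated on 7–9 mm) so the whole pipeline is
  testable without patient data.
- **Reports**: JSON (full precision) and markdown (display-rounded) study
  reports from any cohort CSV, plus a command-line interface.

## Worked example

```r
library(graftsize)

# the rule itself: ST 4.6/4.0 mm, GT 3.4/3.0 mm
predicted_graft_diameter(4.6, 4.0, 3.4, 3.0)
#>   mean_st_mm mean_gt_mm pgd_raw_mm pgd_rounded_mm
#> 1        4.3        3.2        7.5              8
```

The per-tendon means are 4.30 and 3.20 mm; their sum, 7.50 mm, rounds up
to an 8-mm graft.

```r
# a full synthetic study under the calibrated defaults (n = 92)
cohort <- simulate_cohort(calibrated_default_config(seed = 1))
report <- study_report(cohort)

report$agreement
#> Predicted vs actual graft size agreement
#>   concordant: 75/92 (82%, 95% CI 72-89%)
#>   under-predicted: 10/92 (11%, 95% CI 5-19%)
#>   over-predicted: 7/92 (8%, 95% CI 3-15%)
#>   weighted kappa: 0.704 (Moderate)

report$reproducibility
#> Reproducibility of per-tendon mean diameter (Bland-Altman)
#>   intra-reader ST  bias -0.00 mm, CoR 0.08 mm (n = 92)
#>   intra-reader GT  bias  0.00 mm, CoR 0.07 mm (n = 92)
#>   inter-reader ST  bias -0.00 mm, CoR 0.08 mm (n = 92)
#>   inter-reader GT  bias  0.00 mm, CoR 0.09 mm (n = 92)
```

Read: 75 of 92 simulated patients have the rounded prediction equal to the
surgical size; the exact 95% CI for that rate is 72–89%. Repeat readings
of the same tendon agree to within ±0.07–0.09 mm (95% of differences),
with no systematic bias — the measurement is far more repeatable than the
1-mm granularity the decision needs.

The same pipeline runs from the shell on any cohort CSV
(`patient_id,age_years,sex,side,actual_graft_mm,reader,session,tendon,major_mm,minor_mm`,
one measurement per row):

```sh
Rscript inst/cli/graftsize.R simulate --n 92 --seed 1 --out cohort.csv
Rscript inst/cli/graftsize.R report --input cohort.csv --out report.json --markdown report.md
```

## Package layout

- `R/cohort-data.R` — cohort container, CSV I/O, validation
- `R/graft-prediction.R` — the PGD rule
- `R/agreement.R` — classification, exact CIs, weighted κ, bands
- `R/reproducibility.R` — Bland–Altman analyses
- `R/descriptive.R` — median/IQR, Wilcoxon signed-rank
- `R/synthetic-cohort.R` — the seeded generator
- `R/report.R`, `R/cli.R` — study reports and the CLI
- `vignettes/graft-size-prediction.Rmd` — methods, calibration rationale,
  numerical choices, limitations
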