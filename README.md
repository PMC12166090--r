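# immunofront

Region-resolved immune scoring and prognosis from H&E nuclei maps in
colorectal cancer.

Modern computational-pathology pipelines turn an H&E-stained whole-slide
image into (1) a table of nucleus centroids, each classified as epithelial,
lymphocyte, neutrophil, plasma cell, eosinophil, mitosis or connective, and
(2) a tissue-type label raster (background, adipose, muscle, stroma,
lymphoid aggregate, debris, normal epithelium, tumor epithelium, mucin).
`immunofront` implements everything downstream of those models for
quantifying the immune microenvironment separately at the tumor invasive
front and in the tumor center, and for testing whether the resulting scores
predict recurrence. It is aimed at computational pathology groups who have
nuclei/tissue model outputs and want a reproducible, fully tested scoring
and survival stage — without the neural networks themselves, which are out
of scope.

## What it computes

* **Invasive front**: the line equidistant between the tumor-epithelium
  mask and the muscle∪adipose mask (zero contour of the difference of
  distance transforms), omitting stretches that border normal mucosa.
  Tumor cells within 500 µm of the line form the *front*, the rest the
  *center*.
* **Lymphoid structures**: connected components of lymphocytes linked at
  ≤ 20 µm; components > 500 cells are lymphoid aggregates, > 50 000 lymph
  nodes. Members (and everything inside a lymph-node hull) are excluded
  from scoring.
* **IELs**: lymphocytes inside the region formed by dilating tumor
  epithelial cells by 25 µm and subtracting 12.5 µm-dilated connective
  cells. Scored as the ratio of tumor cells with ≥ 1 adjacent IEL to those
  without.
* **Region scores**: for cell type *g* ∈ {Lym, Eos} and region
  *R* ∈ {F, C, A},

  ```
  g_R = |{unique cells of type g within 200 µm of their nearest tumor cell,
          attributed to R via that tumor cell}| / n_tumor(R)
  ```

  Unique counting by nearest tumor cell makes double counting impossible
  and conserves front + center against the whole-slide count exactly.
  Distance profiles in 10 µm bins up to 500 µm describe the spatial decay.
* **Patient aggregation and normalization**: tumor-cell-weighted slide
  averages; per-cohort min-max scaling anchored at the 5th/95th
  percentiles of stage II cases (values above 1.0 are kept, not clipped).
* **Survival**: time to recurrence censored at 60 months; Kaplan–Meier
  quartile splits (cuts from the full cohort) with Wald tests against the
  lowest quartile; univariate and multivariate Cox models (Efron ties,
  log1p-transformed scores) reporting HR, 95% CI, p, and AIC-based model
  comparison.
* **Synthetic data**: slide and cohort generators with known ground truth
  (true front geometry, planted structures, expected counts, true hazard
  ratios) so every stage is testable without patient data.

## Worked example

Simulate one slide under the default study conditions, run the full
per-slide chain, and fit a multivariate Cox model on a simulated cohort:

```r
library(immunofront)

sim <- simulate_slide(slide_sim_spec(), seed = 42)
res <- process_slide(sim$map, sim$cells)
res$front
#> <front_line> 1 polyline(s), total length 3992 um
res$scores[, c("slide_id", "LymF", "LymC", "EosF", "EosC", "IEL",
               "n_tumor_front", "n_tumor_center")]
#>   slide_id      LymF      LymC       EosF       EosC      IEL n_tumor_front
#> 1       S1 0.5798458 0.5140187 0.05231278 0.03990907 3.343597          1816
#>   n_tumor_center
#> 1           7918
```

The slide has 1816 front and 7918 center tumor cells; each front tumor cell
is accompanied by 0.58 unique lymphocytes and 0.052 eosinophils within
200 µm (both higher at the front than in the center, as the generator's
distance-decaying intensities imply), and tumor cells with an adjacent IEL
outnumber those without 3.3 : 1. The recovered front line is the analytic
midline of the simulated stroma gap (`sim$truth$front_y_um`).

```r
cohort <- simulate_cohort(cohort_sim_spec(), seed = 42) # true EosF HR = 0.70
d <- transform_scores(build_ttr(cohort$frame))
cox_fit(Surv(ttr_months, ttr_event) ~ EosF + LymF + IEL + age + sex +
          location + pT + pN + chemo + msi, d)
#> <cox_fit> n=1122, events=231 (0 rows dropped), AIC=3039.9
#>           term    hr ci_low ci_high        p
#>           EosF 0.375  0.138    1.02 5.57e-02
#>           LymF 1.440  0.576    3.61 4.33e-01
#>            IEL 1.310  0.868    1.99 1.96e-01
#>            age 1.020  1.010    1.04 2.35e-04
#>           sexM 1.460  1.100    1.92 7.78e-03
#>  locationright 1.020  0.787    1.32 8.80e-01
#>             pT 1.600  1.330    1.92 8.28e-07
#>             pN 1.830  1.570    2.14 1.35e-14
#>          chemo 1.120  0.844    1.48 4.38e-01
#>         msiMSS 1.270  0.887    1.81 1.93e-01
```

One replicate is noisy — the EosF confidence interval (0.14–1.02) covers
the generating hazard ratio of 0.70, and across replicates the median
estimate centres on it (see the acceptance script below). The staging
covariates generated with strong effects (pT, pN) come out highly
significant, as they should.

A thin command-line wrapper with subcommands `simulate`, `regions`,
`structures`, `score`, `normalize`, `survival` and `run-all` is installed
at `system.file("scripts", "immunofront", package = "immunofront")`.

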