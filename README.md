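# ccfv — choriocapillaris flow voids and geographic atrophy growth

`ccfv` is an R package for analysing the relationship between
choriocapillaris (CC) perfusion and the growth of geographic atrophy (GA)
on en face swept-source OCT angiography. It is aimed at ophthalmic imaging
researchers who have per-eye, per-visit en face slabs — a CC OCTA
angiogram, a sub-RPE structural image, and optionally a drusen elevation
map and an inner-retinal angiogram — and want a reproducible pipeline from
raw slabs to cohort-level inference. Because longitudinal SS-OCTA cohorts
are rarely shareable, the package also ships a synthetic-scene generator
with a known conversion law, so every stage can be validated against
ground truth.

## What it computes

**Flow-void (FV) quantification.** After compensating the CC angiogram for
RPE/Bruch's-membrane shadowing using the structural slab, a pixel is a
flow void when its intensity falls below

```
T = mu_n - k * sigma_n        (k = 1)
```

where `mu_n`, `sigma_n` are the mean and SD of CC OCTA intensity in a
normative database of normal eyes. FV% is the FV area divided by the
region of interest — the whole 6 x 6 mm scan or a 2° band (~571 µm, 48 px)
around the GA margin — excluding drusen (equivalent diameter > 25 µm),
retinal-vessel projection artifacts, and the baseline GA itself.

**GA growth.** GA is segmented from sub-RPE hyper-transmission, visits are
registered by vessel landmarks, and growth is measured on the square-root
scale to remove the dependence on baseline lesion size:

```
growth rate = (sqrt(A_followup) - sqrt(A_baseline)) / months   [µm/month]
```

**Pixel-level conversion model.** For every pixel within 40 px (~480 µm)
of the baseline GA margin, a Firth bias-reduced logistic regression models
conversion to atrophy at follow-up:

```
logit P(converted) = b0 + b1*d + b2*d^2 + b3*FV
```

with `d` the distance to the margin. The Jeffreys-prior penalty
`l(b) + 0.5*log det I(b)` keeps every estimate finite even under complete
separation, which plain maximum likelihood cannot guarantee for rare
events in small rings. `exp(b3)` is each eye's adjusted odds ratio for
baseline FV.

**Clustered inference.** Two eyes of one patient are correlated, so
cohort-level tests permute at the patient level: a clustered Spearman
correlation of FV% with growth rate (patient-block permutation, exact when
the cohort is small), and a clustered Wilcoxon signed-rank test of the
per-eye FV coefficients (patient-level sign flips).

## Worked example

Simulate a small cohort (4 eyes from 3 patients on a 128-px grid) and run
the full pipeline:

```r
library(ccfv)

g <- scan_geometry(grid_size_px = 128, field_of_view_mm = 6 * 128 / 500)
params <- scene_params(geometry = g, ga_radius_px = 18, ga_foci = 1,
                       drusen_count = 4)
cohort <- make_cohort(n_patients = 3, eyes_per_patient = c(2, 1, 1),
                      params = params, seed = 42)
pairs <- lapply(cohort$scenes, `[[`, "pair")
pid <- cohort$manifest$patient_id[match(names(pairs), cohort$manifest$eye_id)]
res <- run_pipeline(pairs, pid, pipeline_config())
print(res)
```

```
Cohort: 4 eyes from 3 patients (0 multifocal)
  FV% whole scan:  19.19 +/- 4.42
  FV% 2-deg band:  19.57 +/- 4.91
  GA growth: 25.83 +/- 10.71 um/month (310.0 um/year)
  Spearman r (whole scan): 0.800, p = 0.5
  Spearman r (2-deg band): 0.800, p = 0.5
  Median OR (FV): 1.309; positive coefficients 3/4
  Clustered Wilcoxon on FV coefficients: p = 0.25
```

Reading the output: mean FV% is reported for both ROIs; the growth rate is
the square-root-area rate in µm/month (and annualized); the Spearman rows
give the clustered correlation of FV% with growth (with only 3 patients
the exact permutation p cannot go below 1/3, hence p = 0.5 despite
r = 0.8); the median odds ratio summarizes the per-eye Firth coefficients
(here the cohort was simulated with a true conversion OR of 1.33), and the
clustered Wilcoxon p tests whether those coefficients are centred at zero.

The Firth fitter is also usable directly as an ordinary modelling
function, including on separated data:

```r
d <- data.frame(y = c(0, 0, 0, 1, 1), x = c(1, 2, 3, 4, 5))
summary(firth_glm(y ~ x, d))
```

```
Firth bias-reduced logistic regression
Call: firth_glm(formula = y ~ x, data = d)

n = 5, penalized log-likelihood = -1.4121 (20 iterations)

             Estimate Std. Error Odds ratio z value Pr(>|z|)
(Intercept) -4.076584   3.574984   0.016965 -1.1403   0.2542
x            1.179216   1.021404   3.251824  1.1545   0.2483
```

A command-line interface wraps the same functions
(`inst/scripts/ccfv simulate|run|report`); `run` writes `fv_summary.csv`,
`growth_summary.csv`, `eye_fits.csv` and `cohort_stats.json`, and `report`
renders a Markdown summary with FV-versus-growth scatter plots.

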