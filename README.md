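# amclear

Clearance kinetics of black carbon in airway macrophages.

The area of black inclusions in airway macrophages (AM BC, µm²) retrieved
by induced sputum is an internal biomarker of long-term exposure to
combustion-derived particulate air pollution. `amclear` is an analysis
package for the kinetic question behind that biomarker: how fast does AM BC
respond when a person's exposure changes? It targets longitudinal panel
designs in which groups with different exposure histories — newcomers from
highly polluted cities (LMIC), newcomers from moderately polluted
high-income countries (HIC), and long-term residents of the destination
(BE) — are sampled repeatedly over about a year.

The package implements the full pipeline:

* **Image quantification** — per-cell carbon area from micrographs and
  binary cell masks (automatic Otsu/IsoData thresholding, pixel→µm²
  calibration such as 146 px = 10 µm at 100×), with slide summaries as the
  median and 90th percentile of ≥25 cells.
* **Kinetics** — a Bayesian hierarchical single-exponential decay model,
  \( y_{ij} \sim \mathrm{LogNormal}(\log R_{0i} - k_i t_{ij}, \sigma_y) \)
  with subject-level \( \log R_{0i} \sim N(\log R_{0g}, \sigma_{R,g}) \),
  \( k_i \sim N(k_g, \sigma_{k,g}) \), fitted by MCMC (JAGS); group-level
  initial quantity \(R_0\) (µm²), decay constant \(k\) (day⁻¹,
  unconstrained in sign) and clearance half-life \( t_{1/2} = \ln 2 / k \)
  with 95% credible intervals. Residents' \(R_0\) can be anchored to their
  first measurement; newcomers' \(R_0\) is extrapolated to the arrival day.
* **Model selection and checking** — DIC comparison (group-effect vs
  pooled, covariate models) and posterior predictive checks with
  loess-smoothed group profiles.
* **Method agreement** — Bland–Altman on the natural-log scale (limits at
  mean ± 2 SD), Spearman correlation with Fisher-z or bootstrap CI, and
  ICC(2,1), for comparing two quantification routes per cell.
* **Synthetic data** — a cohort generator reproducing the panel design
  (3 × 15 subjects, 8 visits ≈ 42 days apart, 85% induction success,
  newcomer arrival latency, right-skewed per-cell areas) and a synthetic
  micrograph generator with exact pixel ground truth, so the entire
  pipeline is testable with no external data.

## Worked example

```r
library(amclear)

ds  <- generate_cohort(cohort_config(seed = 11))     # synthetic panel
fit <- fit_hierarchical_model(build_design(ds, kinetic_model_spec()),
                              mcmc = mcmc_config(seed = 11))
summarize_groups(fit)[, c("group", "r0_mean", "k_mean",
                          "half_life_days", "half_life_lower",
                          "half_life_upper")]
#>   group   r0_mean       k_mean half_life_days half_life_lower half_life_upper
#> 1  LMIC 1.0510053  0.012631224       54.87569        48.67273        63.23167
#> 2   HIC 0.4493842  0.001713133      404.60783       193.49225             Inf
#> 3    BE 0.2306972 -0.001901308            Inf      4985.94321             Inf
```

The simulated LMIC newcomers (generated at a true \(R_0 = 1.122\) µm²,
\(k = 0.013\)/day) are recovered with a clearance half-life near 53–55
days; the HIC and BE groups' \(k\) intervals reach zero — no demonstrable
net clearance at stable exposure — so their half-life upper bounds are
unbounded (`summarize_groups()` also reports the posterior mass of
\(k \le 0\)).

The numbered scripts under `analysis/` run the whole study narrative
(simulate → quantify images → fit kinetics → model selection/PPC →
method agreement) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/03_fit_kinetics.R   # etc.
```

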