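---
title: "Screening the plasma proteome for carotenoid correlates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the plasma proteome for carotenoid correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotscreen)
```

## The problem

Plasma carotenoids (α-carotene, β-carotene, β-cryptoxanthin,
lutein/zeaxanthin, lycopene) are chromatography-measured micronutrient
biomarkers that are rarely assayed in low-resource settings. If circulating
proteins tracked carotenoid concentrations, protein panels — which are far
easier to multiplex — could serve as surrogate markers. `carotscreen`
implements the statistical side of that idea: a proteome-wide screen that
asks, protein by protein, whether relative abundance measured by
multiplexed isobaric labelling (iTRAQ-style) predicts the log2 plasma
concentration of a carotenoid, while respecting the batch structure that
multiplexing induces.

The design this package targets: plasma samples are quantified in plexes of
7 study samples plus one pooled quality-control channel; reporter-ion
intensities are log2-transformed and referenced to the within-plex median
of each protein, so a value is interpretable only relative to its plex; a
protein may be entirely undetected in a plex (missingness operates at the
plex level); carotenoid concentrations are measured independently by HPLC
and left-censored at a detection limit.

## The model

For one (protein, carotenoid) pair, with plexes indexed by $r$ and samples
within plex by $k$:

$$N_{rk} = b_0 + B_r + b_1 P_{rk} + \varepsilon_{rk}, \qquad
B_r \sim N(0, \sigma_B^2), \quad \varepsilon_{rk} \sim N(0, \sigma_e^2),$$

where $N_{rk}$ is the log2 carotenoid concentration and $P_{rk}$ the
protein's log2 relative abundance. The random intercept $B_r$ absorbs the
shared plex-level measurement effects; the slope $b_1$ is the quantity of
interest, reported after transformation as the percent change in
concentration per 2-fold increase in relative abundance,
$(2^{b_1}-1)\times 100$.

### Estimation

`relme()` estimates the model by *profile REML*. With
$\lambda = \sigma_B^2/\sigma_e^2$ fixed, the generalized-least-squares
fixed effects and the residual variance have closed forms through the
within-group transform $\tilde v_i = v_i - \theta_r \bar v_r$,
$\theta_r = 1-(1+n_r\lambda)^{-1/2}$, which whitens the compound-symmetric
covariance exactly. The restricted likelihood is therefore a 1-D function
of $\lambda$, maximized over $\log\lambda$ by a 33-point log-spaced grid on
$[10^{-8}, 10^{6}]$ followed by `stats::optimize()` refinement (tolerance
$10^{-9}$ on $\log\lambda$). The boundary $\hat\lambda = 0$ is accepted and
reduces the fit to pooled ordinary least squares; this is reported via the
`boundary` flag, with all plex BLUPs exactly zero. The tests verify the
fit against a dense-$\lambda$-grid brute force using dense matrix algebra
(an independent code path) and against `lme4::lmer`, which agrees to
better than $10^{-4}$ in $b_1$.

Plex deviations are predicted by the standard shrinkage formula
$\hat B_r = \frac{n_r\hat\lambda}{1+n_r\hat\lambda}\,\bar e_r$ with
$\bar e_r$ the plex-mean fixed-part residual, so every $|\hat B_r|$ is
bounded by its raw mean residual and all $\hat B_r \to 0$ as
$\hat\lambda \to 0$.

### Inference and summaries

* **Test.** $H_0\!: b_1 = 0$ uses a two-sided Wald test with a standard
  normal reference, treating $\lambda$ as known at $\hat\lambda$. With
  roughly 500 observations over 72 plexes the normal reference is adequate
  (the suite checks nominal type-I error and CI coverage by simulation). A
  $t$ reference with estimated degrees of freedom would be a reasonable
  alternative at small $n$; it is deliberately not the default, and the
  small-$n$ caveat below applies.
* **Correlation.** $r$ is the Pearson correlation between observed $N_{rk}$
  and the model prediction $\hat b_0 + \hat b_1 P_{rk} + \hat B_r$, signed
  by $\hat b_1$ (the correlation of data with fitted values is non-negative
  by construction, so the slope carries the sign); $R^2 = r^2$ identically.
* **FDR.** Per analyte, the full vector of per-protein Wald p-values is
  converted to q-values, $q_{(i)} = \hat\pi_0\min_{j\ge i} m p_{(j)}/j$.
  $\hat\pi_0$ comes from the Storey–Tibshirani smoother (natural cubic
  spline, df = 3, over $\lambda = 0.05,\dots,0.95$, read off at 0.95), with
  a conservative fallback to $\hat\pi_0 = 1$ — the Benjamini–Hochberg
  step-up — when fewer than 100 p-values are available or the smoother
  leaves $(0, 1]$. q-values are computed per analyte, not pooled across
  analytes, matching per-table FDR reporting.

### Data preparation

* `median_center()` subtracts the within-plex per-protein median (midpoint
  convention for even counts — the convention is not dictated by the data
  and matters only for even channel counts). By default the pooled QC
  channel does not enter the median (it is a laboratory normalization aid,
  not a study sample); `include_qc = TRUE` restores the 8-channel median.
  The operation is idempotent, so re-centering already-centered input is
  harmless.
* `filter_detection()` keeps proteins detected in **strictly** more than
  `min_fraction` (default 10%) of analytic samples — at a 500-sample
  denominator, $n = 50$ is dropped and $n = 51$ kept.
* `prepare_response()` excludes below-detection-limit samples rather than
  imputing them (no LOD/√2 substitution); the exclusion list is reported so
  that response length plus exclusions always equals the sample count.
* Fits are complete-case per protein; each record carries its own $n$.
  Proteins with fewer than `min_n` complete observations (default 10) or
  fewer than 2 plexes are skipped and logged, not fitted.

## The synthetic stated world

Because the motivating study's raw data are not deposited, validation runs
against a generator that emulates the design end to end, with ground truth
known:

* **Layout:** 72 plexes × 7 study samples (+1 pooled QC per plex, flagged
  and excluded from analysis); 504 slots of which 500 are used
  (`n_analytic = 500` subsamples slots at random — which four slots went
  unused is not knowable, so it is randomized rather than guessed).
* **Detection:** per-plex detected-protein counts are rounded
  $N(589, 65^2)$ truncated to $[1, 4705]$ — the reported per-plex yield and
  catalogue size. A protein undetected in a plex is missing for all its
  samples.
* **Abundance:** detected values are drawn $N(0, 1)$ on the log2 scale and
  median-centered within plex. The abundance distribution is not stated
  anywhere; normal on the log2 scale is the conventional assumption, and
  unit SD matches the scale of median-referenced reporter-ion data.
* **Carotenoids:** generated from the model itself. Default marginals are
  anchored to the published survey of 500 Nepalese school-aged children:
  log2-scale mean $=\log_2(\text{median})$ and SD $=\log_2(Q_3/Q_1)/1.349$
  from the printed medians and IQRs; the detection limit sits at the
  lognormal quantile reproducing the printed detectable counts
  (497/500/500/481/171 of 500; analytes detected in all samples get a
  limit 6 SD below the mean, i.e. effectively uncensored). The plex
  random-intercept share of log2 variance is fixed at 10% — a modest batch
  share chosen once; no batch decomposition is published. Below-limit
  values are retained with a flag so the censoring policy lives entirely in
  `prepare_response()`.
* **Truth:** per-analyte `truth_table`s carry $b_0$, planted slopes
  (defaulting to all-null), $\sigma_B$, $\sigma_e$ and the detection limit,
  and are written alongside the data for recovery tests.

What a green test does and does not establish: the generator draws
independent normal abundances, so it exercises the estimator, the FDR
machinery and the plumbing, but not correlated proteins, heavy-tailed
intensities, informative missingness, or carotenoid assay error — all
present in real data. Recovery results here are statements about the
method under its own assumptions.

## Numerical choices and degenerate inputs

* $\lambda$ search bracket $[10^{-8}, 10^{6}]$; an optimum at the lower
  edge is reported as the boundary $\hat\lambda = 0$ (OLS); an optimum
  pinned at the upper cap sets `converged = FALSE`.
* Noise-free input drives $\hat\sigma_e^2$ to zero; the likelihood is
  guarded against $\log 0$ and the fixed effects remain exact.
* Constant predictors, a single plex, or sub-floor $n$ raise typed
  conditions (`relme_no_slope_variance`, `relme_insufficient_groups`,
  `relme_skip`) that `screen_analyte()` converts into logged skips.
* `wald_p()` with $\text{se} = 0$ and a nonzero slope warns and returns 0.
* Correlation cells with fewer than 3 complete samples are `NA`, never
  extrapolated; analyte-pair p-values use the Fisher-z normal
  approximation (the large-sample choice; the exact test is not specified
  for this design).
* Even-count medians: midpoint convention.
* Ties in q-ranking are broken by p; records are sorted by ascending q
  then p.

## Known limitations

* Under heavy censoring (e.g. a lycopene-like analyte detectable in ~34%
  of samples) complete-case $n$ per protein can fall to the floor of 10,
  where the normal-reference Wald test is anti-conservative and q-value
  control degrades; raising `min_n` is the remedy, at the cost of testable
  proteins. The screen reports per-record $n$ precisely so such rows can
  be judged.
* One protein at a time: no multi-protein models, no imputation, no
  protein–protein adjustment. The protein correlate matrix
  (`proteome_correlation_matrix()`) is descriptive, computed from the
  normalized abundances of the q < 0.05 records over shared samples.
* The fitted $R^2$ uses BLUP-inclusive predictions, so it reflects both
  the protein and the plex structure; it is not the marginal variance
  explained by the protein alone.

## Pipeline

`run_simulate()` / `run_screen()` wrap the workflow as a file-based
pipeline (TSV in, TSV out, DCF config, JSON manifest, per-protein skip
log), with a thin command-line front-end in `inst/cli/carotscreen.R`.
Formatted association tables print r and R² to 2 decimals, p and q in
scientific notation and the percent effect to 1 decimal, mirroring the
conventional table layout; `_full` companions keep full precision.

```{r example, eval = FALSE}
cfg <- default_config(
  planted = c("beta-cryptoxanthin|PROT00001=0.5",
              "beta-cryptoxanthin|PROT00002=-0.5"),
  data_dir = "carot_data", out_dir = "carot_out")
run_simulate(cfg)
res <- run_screen(cfg)
print(res[["beta-cryptoxanthin"]])
```
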