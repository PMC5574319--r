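---
title: "OPLS-DA metabolomics with SUS-plots and correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OPLS-DA metabolomics with SUS-plots and correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsmet)
```

## The analysis this package implements

`oplsmet` implements the chemometric chain used to compare the serum and
brain metabolic profiles of a disease model group against a sham control
and several drug treatments from binned ^1^H-NMR spectra:

1. **Preprocessing** — exclusion of spectral regions (residual water),
   total-area normalization, and column scaling.
2. **Two-class OPLS-DA** per comparison, with cross-validated Q² and
   permutation validation.
3. **Marker extraction** — S-plot coordinates, VIP scores, and fold
   changes with Benjamini–Hochberg (BH) adjustment.
4. **SUS-plot comparison** of two treatment models sharing a common
   disease reference, with shared/unique region classification and Venn
   summaries.
5. **Correlation networks** per group, with structural-similarity edges
   and up/down node directions.

Every stage is exercised against a **synthetic study generator** with
known ground truth, so the whole pipeline is testable without any
external data. A single disease group is conventionally named `M`; the
sham control `NC`; treatments default to `HD`, `Ber`, `Bai`, `Jas`.

## The OPLS-DA model

For a column-centered (optionally scaled) matrix $X$ ($n$ samples
$\times$ $p$ variables) and a class vector encoded $y \in \{-1,+1\}$
(alphabetical order, then centered), the model splits predictor
variation into a part correlated with the class and parts orthogonal to
it. Each orthogonal component is extracted by

$$w = X^\top y / \|X^\top y\|, \quad t = Xw, \quad p = X^\top t / t^\top t,$$
$$w_o = p - (w^\top p)\, w, \quad t_o = X w_o / \|w_o\|^2, \quad
X \leftarrow X - t_o p_o^\top,$$

and after `n_orthogonal` deflations a single predictive PLS component
$(w, t_p, p_p, c)$ is fitted on the deflated matrix. With zero
orthogonal components the procedure reduces *exactly* to one-component
PLS-DA; the test suite asserts this against an independent NIPALS
oracle to 1e-8. Reported statistics:

* `r2x` — fraction of the sum of squares of $X$ captured by the
  predictive plus orthogonal components (partitioned as
  `r2x_predictive` / `r2x_orthogonal`; the partition is verified to
  close to 1e-8).
* `r2y` — in-sample explained class variance.
* `q2` — cross-validated $1 - \mathrm{PRESS}/\mathrm{TSS}$.

**Sign convention.** The predictive score sign is fixed so the
alphabetically second class has positive mean $t_p$; renaming classes
flips every predictive sign and nothing else.

**Cross-validation.** Stratified 7-fold by default (the convention in
commercial chemometrics software; the fold count is a configuration
value, not a claim about any particular study). Scaling statistics are
re-estimated inside every training fold, so held-out samples never leak
into the centering/scaling. The orthogonal component count is chosen by
a parsimony rule: the smallest count whose Q² is within 0.01 of the
maximum over candidates.

An explicit `fold_id` argument allows pinning the fold structure. This
matters when samples are duplicated (technical replicates): with random
fold assignment a duplicate's twin lands in training with probability
$(k-1)/k$ and Q² inflates by roughly 0.15 in our measurements, whereas
with duplicates sharing a fold the fitted models are identical and Q² is
exactly invariant.

**Permutation validation.** Class labels are shuffled (shuffles equal to
the true labeling are rejected and redrawn), the model is refitted and
re-cross-validated per shuffle, and R²Y/Q² are recorded against the
Pearson correlation between permuted and true class vectors. The OLS
lines of R²Y and Q² on the absolute correlation are fitted including the
observed point at correlation 1, and their intercepts reported: a valid
model shows the observed Q² above the whole permuted scatter and a low
Q² intercept. The full-scale convention for such validation plots is
2000 permutations; the pipeline default is 200 to keep desk-scale runs
fast, and the count is one configuration value (`permutations`).

## Marker evidence

* **S-plot**: per variable, $\mathrm{cov}_j = t_p^\top x_j / (n-1)$ and
  $\mathrm{corr}_j = \mathrm{cov}_j / (s_{t_p} s_{x_j})$, always
  computed from *centered, unscaled* data so `corr` is a true Pearson
  correlation regardless of the model's scaling. Reliable
  high-magnitude markers fall far from the origin in the upper-right or
  lower-left quadrant. Whether the covariance axis should instead be
  computed from Pareto-scaled data is genuinely open in the field;
  centered-raw is the default here and the scaled variant can be
  obtained by passing a scaled matrix.
* **VIP** over the single predictive component:
  $\mathrm{VIP}_j = \sqrt{p\, w_j^2 / \sum_k w_k^2}$, so the mean
  squared VIP is exactly 1 and `VIP > 1` is the conventional cut.
* **Fold change** `mean(group) / mean(reference)` with Welch's
  two-sided t-test (pooled-variance optional) and BH step-up adjustment.
  The BH implementation is compared against an exhaustive step-up
  oracle and `stats::p.adjust` on random vectors. One caution: BH is
  *not* idempotent — re-adjusting already-adjusted values inflates
  them — so adjusted values are computed once from raw p-values only.
* The combined `marker_table()` flags `selected` markers by
  `|corr| >= 0.6 & VIP > 1 & adjusted_p < 0.05`; the correlation cut is
  a package default (configurable), the other two are the conventional
  cuts.

## SUS-plot classification

Two models sharing a reference class are overlaid by their
`corr(t_p, X)` profiles, sign-aligned so positive always means
"elevated in the non-reference class". Shared effects fall on the
diagonals, model-unique effects near the axes. "Close to" is quantified
angularly, since no numeric rule is standard:

| parameter | default | meaning |
|---|---|---|
| `vip_cut` | 1.0 | classify only metabolites with `max(vip_a, vip_b)` above it |
| `diag_angle_deg` | 20° | half-width of the shared bands around ±45° |
| `axis_angle_deg` | 15° | half-width of the unique bands around the axes |
| `corr_floor` | 0.3 | points with both \|corr\| below it stay unclassified |

Points between regions are `unclassified` rather than forced into a
region. The classifier is verified point-by-point against a brute-force
angular oracle, and a marker planted with equal sign in both treatments
is classified `shared_positive` in 100% of 50 simulation replicates at
effect size 2 and n = 8 per group.

A power caveat worth stating plainly: a marker planted in only one
treatment is *not* reliably classified `unique_a` at n = 8. Its
correlation in the other model is a null sample correlation with
standard deviation $\approx 1/\sqrt{n-1} = 0.26$, while landing inside
a 15° axis wedge requires roughly $|corr_b| \le \tan(15°)\,corr_a
\approx 0.19$; the measured rate is ~0.28. Unique-effect calls at this
sample size are suggestive, not reliable, and the deterministic
geometry is what the package guarantees.

## Correlation networks

Within one group's samples, all metabolite pairs are tested by Pearson
correlation with the t-transform p-value
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; pairs with `|r|` above the threshold
and raw `p < 0.05` become solid edges signed by the correlation.
Conventional thresholds differ by matrix: 0.65 for serum, 0.85 for
brain networks. At n = 8 the p-rule alone requires `|r| > 0.707`, so
every edge passing the brain threshold automatically satisfies it —
asserted as a consistency property in the tests. The p-values are
deliberately *not* multiplicity-corrected by default (matching the
convention the thresholds come from); `bh = TRUE` switches the screen
to BH-adjusted p-values. Structural-similarity edges (dotted,
candidate substrate–product pairs) come from a user-supplied symmetric
matrix thresholded at 0.8 by default; computing similarities from
chemical structures is out of scope. Node directions are up/down calls
from Welch tests against a comparison group: disease and control panels
are colored by disease-vs-control, treatment panels by
treatment-vs-disease. Correlation is not causation; the structural
edges only flag where a high correlation could reflect a biochemical
transformation.

## The synthetic world

`default_study_design()` states the simulated study once:

* six groups (`NC` reference, `M` disease, four treatments), n = 8 per
  group; 42 metabolites for the brain preset, 26 for serum — the group
  and metabolite counts of the kind of study this pipeline targets;
* ten planted markers shifted by two within-group SDs in `M`
  (alternating sign); each treatment restores a characteristic subset
  halfway toward the reference, creating shared and treatment-unique
  structure;
* two five-metabolite correlation blocks at rho = 0.6 emulating
  pathway-driven covariation;
* concentrations are multivariate normal on the log scale and
  exponentiated (positive, right-skewed, ~20% CV at the default
  `noise_sd = 0.2`) — so planted standardized effects are exact on the
  latent log scale; the raw-scale attenuation at this noise level is
  negligible (measured ~2.05 for a planted 2.0). A linear-scale
  fallback truncates negative draws at zero.

Spectra are rendered from a *fictional but ppm-plausible* peak library
(1–3 Lorentzians per metabolite, 0.003–0.008 ppm half-widths, i.e. a
few Hz at 500 MHz) on a 0.5–9.5 ppm axis, integrated into 0.04 ppm
bins, with Gaussian baseline noise and bin centers reported in
descending ppm. Lorentzians are truncated at 100 half-widths so peaks
have compact support while keeping >99% of the analytic area (the
rendered integral matches closed-form quadrature to 1%). The generator
does **not** emulate free-induction decays, phasing, baseline drift,
J-coupling multiplets, peak-position jitter, or real chemical shifts —
so a green test establishes the statistical machinery, not robustness
to spectral artifacts.

## Numerical and design choices

* Class encoding −1/+1 on a centered response; balanced designs make
  the centering a no-op.
* Zero-variance columns are dropped with a warning by variance-based
  scalings (they carry no discriminant information); centering keeps
  them.
* Degenerate fits (no covariance between predictors and class) are
  rejected with an explicit error rather than returning NaNs.
* Water exclusion defaults to 4.7–5.1 ppm, the conventional residual
  water window; it is a configuration value, as are the normalization
  target and every threshold above.
* The pipeline derives one seed per stage from the root seed
  (`seed + 7919 * offset mod 2^31 - 1`), so a rerun with the same
  configuration is byte-identical, and the run manifest records the
  configuration and its FNV-1a hash for re-creation. Configs are
  interchanged as JSON.
* Infarct volumetry: `I% = (Vc − Vi)/Vc × 100` with `Vc` the intact
  contralateral hemisphere and `Vi` the intact ipsilateral regions
  (edema-corrected). Negative values (measurement noise) are returned
  with a warning, not clamped.

## Known limitations

* **Joint marker recovery at n = 8 is not near-certain.** With ten
  planted markers at effect size 2 among 42 metabolites, the weakest
  marker's sample |corr| (~0.55 at n = 16) interleaves with the largest
  of 32 null correlations (~0.57). Averaged per marker, over 96% of
  markers land in the top 12 by |corr| with VIP > 1; but the joint
  event "all ten simultaneously" holds in only ~60–70% of replicates.
  Claims about complete marker panels at this sample size should be
  treated accordingly.
* Unique-effect SUS calls are underpowered at n = 8 (see above).
* Two-class models only; no multi-class OPLS-DA, no Hotelling T²
  ellipses, no back-scaled loading pseudospectra.
* Correlation-edge p-values assume bivariate normality through the
  t-transform; heavy-tailed raw-scale data are handled only insofar as
  the log-normal world is mild.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_pipeline_config("brain", seed = 1, permutations = 200)
res <- run_pipeline(cfg, "my_run")
res$models[["NC_vs_M"]]          # fit statistics
head(res$markers[["NC_vs_M"]])   # marker evidence table
res$sus[["HD_Ber"]]$venn$counts  # shared/unique tallies
```

The command-line front end (`inst/cli/oplsmet-cli.R`) wraps the same
calls as `simulate`, `run-all`, and `infarct` subcommands.
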