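---
title: "Image-quality confounding in brain connectome analyses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-quality confounding in brain connectome analyses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large population imaging cohorts derive *structural* connectomes from
diffusion MRI (dMRI; white-matter tract volume between atlas regions) and
*functional* connectomes from resting-state functional MRI (rs-fMRI;
correlated BOLD fluctuations between regions). Scan quality is not noise in
the usual sense: signal-to-noise ratio (SNR), head motion, and the spatial
mismatch between the scan and the brain atlas all vary *systematically*
with participant characteristics — older participants and men move more,
higher BMI degrades the fMRI SNR. Quality therefore acts as a confounder:
associations between connectivity measures and age, sex or BMI partly
reflect quality, not biology. This package implements the full assessment
pipeline — quality metrics, connectome construction, null-normalized graph
measures, and the two-model regression comparison that quantifies the
confounding — together with a calibrated synthetic-cohort generator, so
every stage is testable without access-controlled cohort data.

## Quality metrics

All three metrics are on a "lower is better" scale.

**Inverse SNR.** From two volumes acquired back-to-back (two trailing
b = 0 volumes for dMRI; two volumes after magnetization stabilization for
rs-fMRI),
$$\mathrm{iSNR} = -\,\frac{\mathrm{mean}(I_1, I_2)}
{\mathrm{sd}(I_1 - I_2)/\sqrt{2}},$$
computed over brain-masked voxels. Two interpretation choices are not fixed
by the formula and are resolved as follows: the mean pools the masked
voxels of *both* volumes (symmetric in the two acquisitions), and the
standard deviation uses the sample ($n-1$) denominator (unbiased noise
estimate from a single difference image). Identical volumes give a
zero-variance difference and raise an error rather than returning
$-\infty$.

**Head motion.** The mean volume-to-volume translation in mm,
$\sum_{i=2}^{N} \sqrt{\Delta X_i^2+\Delta Y_i^2+\Delta Z_i^2}/(N-1)$, from
the translational realignment parameters. Rotations are parsed from the
6-column parameter files but do not enter the metric. The default file
dialect is rotations-then-translations; the opposite order is selectable
because realignment tools disagree and the convention cannot be inferred
from the file itself.

**Atlas mismatch.** One minus the Dice coefficient of the scan's brain mask
and the atlas mask, $1 - 2|A\cap B|/(|A|+|B|)$, on voxel counts in the
native grid (voxel dimensions are ignored — the metric is a pure overlap).

## Connectomes and consensus thresholding

Structural edge weights are tract volume (voxels visited × voxel volume)
relative to intracranial volume; pairs joined by fewer than two tracts are
treated as spurious and zeroed. Functional edge weights are Pearson
correlations of region-mean BOLD series after residualizing each series on
an intercept plus eight nuisance regressors (six motion parameters, CSF and
WM means); negative correlations are set to zero *after* the residual
correlation is computed. Diagonals are always zero.

Group consensus: structural connectomes enter binarized (weight > 0), so
the group average is an edge *prevalence*; functional connectomes enter as
weights. The consensus is proportionally thresholded to a target sparsity
(default 0.80): the top $K=\mathrm{round}((1-s)\cdot 4371)$ edges by group
value are retained — exactly 874 edges for 94 regions at $s=0.80$. The
alternative literal reading ("present in at least 80% of participants") is
available as `mode = "prevalence"`, but the rank-based rule is the default
because it fixes the edge count, which the prevalence cut does not
guarantee. Ties are broken by larger group value, then (row, column) order,
making masks deterministic and nested across sparsities. Overall
connectivity (the mean over all 4371 pairs, zeros included) is computed
*before* masking and is therefore sparsity-independent.

## Graph measures and null normalization

On each masked individual network: average node degree $\nu$ (binary,
"wiring cost"), weighted clustering coefficient, and weighted global
efficiency (mean inverse shortest-path length with edge length $1/w$;
disconnected pairs contribute 0). Clustering uses the Onnela geometric-mean
triangle form on max-normalized weights; the source analysis toolbox offers
several weighted variants without the original study stating which, so this
choice is the main comparability knob and is deliberately isolated in one
function. For binary weights it reduces to the ordinary clustering
coefficient (tested).

Clustering and efficiency are normalized by their means over `n_null = 100`
random networks of the same size, edge count and *binary degree sequence*,
produced by double-edge-swap rewiring (default 10 swap attempts per edge).
Weights travel with their edges — the constraint "same size, sparsity, and
binary degree" fixes topology only, so the weight multiset is preserved and
not reshuffled. Each participant gets an independent, seeded ensemble (the
per-participant seeds are recorded for audit); rigid graphs (e.g. complete
graphs) are correctly their own nulls because invalid swaps are rejected.
The rewiring, clustering and shortest-path kernels are compiled (Rcpp) and
the rewiring consumes exactly three R-RNG draws per attempt, so tests can
verify it against an interpreted mirror draw for draw.

## The confounding analysis

All regressions are fully standardized (outcome and predictors z-scored;
relative WMH volume is log10-transformed first, being strongly
right-skewed). **Model 1** regresses a connectivity measure on the seven
demographic/clinical covariates: age, sex (0 = male, 1 = female), education
(ordinal 1–3), BMI, diabetes status (ordinal 0–3), CVD history, log-WMH.
**Model 2** adds the three modality-matched quality metrics. The sex and
diabetes codings reproduce the published sign conventions (a positive sex
coefficient means higher values in women); diabetes is a single ordinal
because the published tables report one coefficient per variable, and the
rare "other type" category (0.6%) sits at the top of the ordinal.

The effect of adjustment is summarized by the signed percent change
$(\beta_2-\beta_1)/\beta_1 \times 100$, applied identically to $R^2$ pairs.
The signed-relative form is the one consistent with every published cell,
including sign flips (0.058 → −0.081 gives −240%) and strengthened negative
effects (−0.018 → −0.076 gives +322%); magnitude-based alternatives fail
those cells. A change is flagged *relevant* when the coefficient is
significant (α = 0.05, either model — the published tables themselves
report changes where only the adjusted model is significant) and moves by
more than 10%. No multiple-testing correction is applied, matching the
source analysis.

Determinants of quality are estimated by one standardized regression per
metric on the seven covariates. The full model is the default; a
forward-selection mode (entry α = 0.05) is provided because the published
table captions mention forward selection while the methods text describes
plain regression and all covariates carry coefficients — the full model is
what reproduces those tables.

The *motion–aging equivalence* converts a motion increment into the age
change producing the same standardized outcome shift:
$|\beta_{motion}/\beta_{age}| \cdot (\Delta_{motion}/SD_{motion}) \cdot
SD_{age}$. The exact derivation behind the published figure is not
reproduced in the available text; this ratio-of-standardized-effects form
is adopted because it reproduces the published 18.3 years from the
published inputs (−0.249, −0.074, 0.16 mm, 8.7 y, Δ = 0.1 mm) and is the
standard conversion between standardized effects. A sensitivity mode
excludes participants with dMRI motion above 1.0 mm and refits everything.

## The synthetic cohort

The generator's default preset is calibrated once to the published
characteristics of a large Dutch population cohort (n = 5110, ages 40–75,
type 2 diabetes oversampled) and is not a tuning dial; it defines the study
conditions under which the pipeline is tested.

**Covariates.** Age is drawn from a normal distribution truncated to
[40, 75] whose *parent* parameters are moment-matched (numerically, at
config build) so the truncated distribution has exactly the target mean
59.4 and SD 8.7 — naive truncation would shrink the SD to about 8.0. Sex
and CVD are Bernoulli (49.4%, 12.6%), education and diabetes categorical,
BMI normal (26.6, 4.2). Relative WMH volume is log10-normal with
$\mu = \log_{10}(0.016)$ and $\sigma$ fitted analytically from the
published quartiles (0.005–0.050); it is correlated with age (Gaussian
copula, default r = 0.4) because lesion burden rises with age. The
published study does not report its covariate correlation matrix, so
$R^2$ values of the quality regressions (e.g. 0.297 for dMRI motion) are
structure-dependent and treated as calibration-sensitive, not as targets.

**Quality metrics.** Each standardized metric is
$\sum_k \beta_k z_k + \varepsilon$ with the published coefficient sets and
residual variance completing the outcome to unit variance (configurations
implying explained variance ≥ 1 are rejected). Residuals are drawn jointly:
for each configured target correlation (dMRI iSNR–motion 0.298, rs-fMRI
0.522) the generator *solves* for the residual correlation that combines
with the realized covariate-induced covariance to produce the target on the
observed scale — setting the residual correlation to the target directly
would overshoot, because the shared BMI/age dependence already contributes
≈ 0.15 to the rs-fMRI pair. Metrics are then linearly rescaled to the
published means/SDs (iSNR is the negative of SNR, e.g. −22 ± 6.5 for
dMRI). A mean/SD-preserving exponential tilt (`motion_skew`) can give the
motion metrics their realistic right-skewed tail for the exclusion
analysis; the default is 0 so refitted coefficients are unattenuated.

**Connectomes.** A fixed geometric template (seeded separately from the
cohort) places 47 regions per hemisphere and assigns each region pair an
edge-presence probability with logistic distance decay — later decay for
intra-hemispheric pairs — and a distance-decaying weight. The decay
parameters were calibrated once so that the consensus mask at sparsity 0.80
yields a mean masked node degree ≈ 17.8 and an interhemispheric edge
fraction that falls with sparsity, as in the published consensus networks.
Each participant's matrix is the template with Bernoulli edge presence
(SC), log-normal multiplicative edge noise (SC; preserves nonnegativity) or
additive clipped noise (FC), rescaled so the participant's overall
connectivity equals $\mu + \sigma u_i$ exactly, where
$u_i = \sum_k \beta_k z_k + \varepsilon_i$ uses the published
adjusted-model coefficient set for overall connectivity (SC: 5.3·10⁻³ ±
0.6·10⁻³; FC: 0.32 ± 0.03). Overall connectivity is therefore linear in
the configured predictors by construction, and refitting the two-model
analysis on generated data recovers the coefficients up to sampling error.

**What the generator does not emulate.** Edge-level covariate effects (all
confounding acts through a single per-subject scale); realistic tract
geometry; the magnitudes of the normalized clustering coefficient and
efficiency (published 2.31 and 0.84 for SC), which depend on the real
cortical topology; and individual zeroing of consensus FC edges — simulated
FC weights on consensus edges are essentially never zero, so the simulated
FC node degree is pinned at its ceiling (18.6 rather than the published
16.7 ± 0.7) and its regression row is skipped with a warning. Passing tests
therefore demonstrate correctness of the *pipeline mechanics* and of
parameter recovery under a known truth, not realism of every marginal
statistic.

**Volume fixtures.** Minimal 4D arrays with known ground truth: a constant
intensity sphere plus white noise scaled so the iSNR estimator's
expectation is $-\mathrm{snr}$; an alternating-shift motion trace whose
mean volume-to-volume translation is exactly the requested value; and an
atlas mask obtained by keeping the innermost $m$ voxels of the brain mask
with $m$ solved from the mismatch target — the achieved mismatch is exact
on integer counts and stored in the truth record. The brain mask is eroded
by a margin exceeding any applied shift so the masked signal stays constant
under motion.

## Numerical and reproducibility choices

All randomness flows from one root seed through a documented
linear-congruential splitting scheme (`split_seed()`; streams: 1 cohort,
2 quality, 3/4 SC/FC connectomes, 5 per-participant null ensembles,
6 sweep). Identical configurations give byte-identical outputs, including
the pipeline's CSV files. Thresholding tie-breaks, the rewiring proposal
rule (three RNG draws per attempt, rejection on self-loops, duplicate or
coincident edges), and the constant-outcome and zero-variance error paths
are all deterministic and tested. Null-ensemble normalization divides by
ensemble means and raises an error on a zero mean rather than returning
non-finite values.

Problem sizes used by the test suite are the package's own choices: full
cohort size (n = 5110) for calibration and parameter-recovery checks
(Monte-Carlo over 20 seeds for the quality models, 6 for the connectivity
model), n = 500 with 50 null networks per ensemble for the sparsity-grid
trend summary, and 100 nulls (the published count) everywhere a single
ensemble is examined.

## Worked example

```{r example}
library(connqc)

cfg <- qc_config(n = 500, seed = 1)
out <- run_pipeline(cfg, out_dir = tempfile("qc_run"), n_null = 100)

# confounding of the age association with overall structural connectivity
led <- out$ledgers$sc
led[led$outcome == "overall" & led$term == "age", ]

# the motion-aging equivalence implied by the fitted model
out$motion_age_years

# sparsity robustness of the graph measures
cn <- generate_connectomes(out$cohort, out$quality, cfg, modalities = "SC")
sw <- sparsity_sweep(cn$sc, seq(0.60, 0.90, 0.05), n_null = 50, seed = 2)
sw$summary
```

## Limitations

The generator reproduces the published *regression structure*, not the
imaging physics: no k-space simulation, no EPI distortion fields, no
physiologic noise spectra, and no tractography. Region identities are
integer labels with an odd/even hemisphere convention; atlas geometry is
not modelled. The confounding analysis is regression adjustment exactly as
published — no causal mediation or measurement-error modelling — so
"percent change on adjustment" quantifies association shifts, not causal
quality effects.
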