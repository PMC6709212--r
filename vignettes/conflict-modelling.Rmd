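---
title: "Modelling approach-avoidance conflict: the joint choice-RT model and its fMRI pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling approach-avoidance conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcconflict)
```

# The scientific problem

In the aversion-reward conflict (ARC) task a participant repeatedly chooses
between a safe option (a guaranteed $0.01, no aversive stimulation) and a
risky option (a reward between $0.05 and $0.95, with a 10%, 50% or 90%
chance of aversive stimulation). When the two options are subjectively
matched the participant experiences approach-avoidance conflict, the
behavioral hallmark of which is slowed responding. Because participants
differ enormously in where that balance point lies, any analysis that wants
to locate *conflict* — rather than merely *deliberation* — in the brain must
first locate each participant's own decision boundary. This package
implements that programme: a joint hierarchical Bayesian model of choices
and response times that yields a per-trial conflict estimate, and a
model-based fMRI pipeline that uses those estimates as parametric
modulators under the variable-epoch convention, with permutation-based
TFCE/FWE inference at the group level.

# The joint choice-RT model

For participant $j$ and trial $i$, the choice $y_{ij}$ (1 = risky) is
Bernoulli with probability
$$\theta_{ij} = \mathrm{logistic}(\beta_{0j} + \beta_{1j}\,[\text{50% risk}]
 + \beta_{2j}\,[\text{90% risk}] + \beta_{3j}\, \tilde r_{ij}),$$
where the risk indicators use 10% as the reference level and
$\tilde r$ is the reward standardized to mean 0, SD 1 over the pooled
design. Conflict is the inverse distance to the decision boundary,
$$d_{ij} = 0.25 - (0.5 - \theta_{ij})^2 \in [0, 0.25],$$
maximal when the choice is a coin flip. Response times are gamma
distributed with shape $k_j$ and mean
$$\mu_{ij} = \alpha_{0j} + \alpha_{1j} d_{ij},$$
so the same parameters must explain both data streams: the RT likelihood
sharpens single-trial estimates of $\theta$, and hence of $d$. All
participant-level parameters are partially pooled through normal group
distributions; the model is fitted by Hamiltonian Monte Carlo (implemented
in compiled code in this package, with a non-centered parameterization,
dual-averaging step-size adaptation toward 0.8 acceptance, and a diagonal
mass matrix estimated during warmup). The default schedule is four chains
of 2000 steps (1000 burn-in, thinning 4), retaining 1000 draws, and
convergence is screened with the between-/within-chain $\hat R$ statistic
(warning above 1.1).

## The conflict-scale choice

The model equations bound $d$ at 0.25, yet the slope of interest is often
read as "seconds of slowing at maximal conflict", which presumes $d$
rescaled to $[0,1]$. The package follows the equations by default
(`conflict_scale = "raw"`, so a slope of 1.824 corresponds to 0.456 s of
slowing at $d = 0.25$) and exposes `conflict_scale = "unit"` for the
rescaled convention; every function that touches $d$ respects the flag.
Nothing statistical depends on the choice — it is a reparameterization —
but reported slopes do.

## Priors

The prior family follows robust-logistic practice: Student-t with
$\eta = 5$ degrees of freedom on the choice group means. For the scale we
depart from the conventional 2.5: on a standardized reward predictor in
this task, reward sensitivities of order 10 on the logit scale are not
merely plausible but typical, and a scale-2.5 prior would penalize exactly
the regime the task is designed to produce. We therefore use scale 10
(still proper and weakly informative for this design), half-normal(0, 5)
on the choice group SDs, normal(1, 1) on the baseline-RT group mean,
normal(0, 2) on the conflict-slope group mean, half-normal(0, 0.5) on the
RT group SDs, and gamma(2, 0.1) on the participant gamma shapes. All are
overridable via `model_spec(prior = ...)`. The baseline-RT mean is
nominally positivity-constrained; the sampler enforces validity through
the likelihood (any non-positive gamma mean has zero posterior density),
which is equivalent in the regime the data occupy.

## Point estimates and model comparison

Per-trial conflict for the fMRI stage uses *modal* participant-level
estimates: the argmax of a Gaussian-kernel density (Silverman bandwidth)
per parameter, with the posterior mean available as a sensitivity option.
Model comparison uses WAIC on the deviance scale with one *trial* as the
pointwise unit — a trial's Bernoulli and gamma log-densities are summed
into a single term, the joint model's natural observation unit. Posterior
predictive fit is summarized as the RMSE between predicted and observed
per-participant risky-choice rates. Three variants are compared: the
hierarchical model, a non-hierarchical equivalent (one shared parameter
set), and a hierarchical variant with risk-by-reward interactions.

# The synthetic-data generator

The behavioral generator reproduces the study conditions: 108 trials,
risk counterbalanced 36/36/36, rewards uniform on the cent grid within
risk level, one seeded trial order shared by all participants, Bernoulli
choices from the logistic model, gamma RTs with conflict-dependent means,
and a 3.5 s response window implemented as censoring (choice and RT both
missing). Participants with more than 20% missing trials are flagged for
exclusion, mirroring the behavioral exclusion rule. Defaults place the
group choice coefficients at the reported group effects
($\beta_1 = -1.922$, $\beta_2 = -4.180$, $\beta_3 = 10.652$) with an
intercept of 2.0 — not reported directly; chosen so that the simulated
cohort is approach-biased at 10% risk while mostly avoiding at 90%.
Baseline RT is 1.0 s (typical under a 3.5 s window) and the conflict
slope corresponds to 0.456 s at maximal conflict. Between-participant SDs
(4, 1.5, 2, 3 for the choice coefficients; 0.15 s and 0.5 for the RT
parameters) were calibrated once against the reported spread of
individual preferences — per-participant risky-choice rates running from
the teens to above 90% — by simulating cohorts from the generator alone. Gamma shapes are log-normal around 8
(log-SD 0.3), giving RT coefficients of variation near 0.35. The fitter
treats RTs as untruncated gamma, matching the model equations; the
censoring toggle exists so users can study the (small) bias this induces.

The BOLD generator is deliberately minimal: $Y = X\beta + \varepsilon$ on
a 12×12×12 grid with AR(1) noise (coefficient 0.2) plus the design's own
regressors as ground truth, a constant baseline of 100 for a meaningful
percent-signal-change scale, and two disjoint ≥20-voxel cuboid clusters —
one "deliberation-only" (responds to the RT-scaled control boxcar), one
"conflict-sensitive" (additionally responds to the conflict modulation).
It makes no attempt at fMRI physics (no physiological noise, no spatial
autocorrelation, no anatomy); what passing tests show is that the
*pipeline* recovers what it should under its own assumptions, not that it
is robust to real-scanner artifacts.

# The fMRI pipeline

First-level designs model the deliberation phase with the variable-epoch
method: each trial's boxcar lasts its observed response time, which
controls time-on-task so that a parametric modulator (per-trial $d$,
mean-centered over non-missing trials and zeroed on missing ones) isolates
*intensity* rather than *duration* effects. The fixed-epoch alternative
(uniform 3.5 s boxcars) is retained as a control analysis, as are risk,
reward, and joint modulator sets. Boxcars are built on a 16× oversampled
grid, convolved with the canonical double-gamma HRF (peak 6 s, undershoot
16 s, ratio 6, 32 s support, unit peak — the PSC convention depends on
this normalization and `psc_convert()` is kept consistent with it), and
sampled at scan times. Nuisance terms: an orthonormal DCT high-pass basis
at 0.01 Hz (`floor(2 T f_c)` columns), the six motion parameters demeaned,
detrended and Gram-Schmidt orthogonalized, and one spike regressor per
scrubbed frame (FD > 0.9 mm, radius 50 mm; first four volumes always
dropped). Spike regression rather than row deletion preserves the regular
sampling the DCT basis assumes; the two differ only in how the scrubbed
frames' residuals are counted.

Coefficients are converted to percent signal change —
$100\,\beta\,\mathrm{peak}(X_{task})/\bar Y$ — and passed to a
second-level weighted least-squares model (unit weights by default, i.e.
OLS as the WLS special case; inverse-variance weights optional) with an
F-contrast on the intercept and optional nuisance covariates such as
scanner type. Group inference is permutation-based: the Freedman-Lane
procedure fits the nuisance-only model, transforms its residuals under
the null, adds the nuisance signal back, refits, and records the maximum
TFCE statistic per permutation. One deliberate departure from common
descriptions: for the group-mean (intercept) contrast the residual
transform is *sign-flipping*, not row permutation — permuting rows leaves
a mean effect invariant, so row permutation cannot build a null for the
intercept (its rejection rate would collapse); sign-flipping under the
independent-symmetric-errors assumption restores exact calibration, which
the test suite verifies empirically. Row permutation remains available
for contrasts on exchangeable covariates.

TFCE uses the recommended parameters ($H = 2$, $E = 0.5$, absolute step
0.1) with face (6-)connectivity by default (18/26 selectable); negative
tails are enhanced separately by sign. FWE-corrected p-values use the
add-one estimator $p = (1 + \#\{\max \ge v\})/(1 + n_{perm})$, and
surviving suprathreshold clusters below 20 voxels are discarded. The
surface-based (100 mm²) cluster criterion is out of scope; the pipeline
is volumetric only, and no first-level prewhitening is applied (serial
correlation is handled by the group-level permutation scheme).

# Numerical choices and degenerate inputs

Standardization of reward uses the population-SD convention so the fixed
design is standardized exactly; the sample convention is available.
Degenerate cases are defined rather than fatal where a definition exists:
constant chains give $\hat R = 1$; all-identical draws give a zero-width
HDI; a zero map enhances to zero; zero-baseline voxels are masked in PSC.
Zero-variance rewards, non-positive gamma means, rank-deficient designs
and non-positive WLS weights are errors. HDI ties are broken toward the
lowest lower bound. The gamma likelihood uses the shape-rate
parameterization with rate $k/\mu$ so that $\mu$ is the mean.

# Problem sizes used in the tests

The shipped checks run at what a laptop handles comfortably: the recovery
study uses 20 replicates of 28 participants × 108 trials with four chains
of 1000 steps (half the default schedule); FWE calibration uses 200
global-null replicates at 12³ voxels with 500 permutations; the
epoch-mode dissociation uses one 28-participant synthetic BOLD study with
300 permutations; TFCE is checked against a literal threshold-sum oracle
on 100 random 6³ maps. Full-scale voxelwise reproduction of empirical
peak tables would require the original raw MRI data and preprocessing and
is explicitly out of scope.

# Known limitations

The RT likelihood ignores the response-window truncation; the generator
can censor, so the induced bias is measurable but small at the default
parameters. The BOLD generator's realism limits are listed above. The
non-hierarchical variant shares all parameters across participants — it
is the comparison model, not a per-participant no-pooling fit. WAIC's
trial-level pointwise unit means its absolute scale is comparable across
the three shipped variants but not across models with different
observation units.
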