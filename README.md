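# arcconflict

Model-based analysis of approach-avoidance conflict behavior and its BOLD
correlates, for researchers working with the aversion-reward conflict (ARC)
task or similar risky-choice paradigms.

In the ARC task a participant chooses, 108 times, between a safe option
($0.01, no aversive stimulation) and a risky option ($0.05–$0.95, with a
10/50/90% chance of stimulation). The package implements the full analysis
chain around a joint hierarchical Bayesian model of choices and response
times:

- **Choice model** — the probability of taking the risky option is
  `theta = logistic(b0 + b1*[50% risk] + b2*[90% risk] + b3*reward_z)`,
  with 10% risk as reference level and reward standardized to mean 0, SD 1.
- **Conflict statistic** — `d = 0.25 − (0.5 − theta)²`, the inverse
  distance to the decision boundary: maximal (0.25) when the choice is a
  coin flip, zero when it is certain.
- **RT model** — response times are Gamma(k, k/mu) with
  `mu = alpha0 + alpha1 * d`: conflicted trials are slower, and the joint
  fit lets RTs sharpen the single-trial conflict estimates.
- Participant parameters are partially pooled through group-level normal
  distributions and sampled with the package's Hamiltonian Monte Carlo
  sampler (non-centered hierarchy, compiled in C++). Diagnostics (R-hat,
  ESS), HDIs, WAIC model comparison, posterior predictive checks and modal
  point estimates are built in.
- **Model-based fMRI** — variable-epoch first-level designs (boxcar
  duration = response time) with per-trial `d` as a parametric modulator,
  canonical double-gamma HRF, DCT high-pass at 0.01 Hz, motion nuisance and
  FD-based scrubbing; percent-signal-change conversion; second-level WLS
  with Freedman–Lane permutations, TFCE (H = 2, E = 0.5, step = 0.1),
  voxelwise FWE correction at alpha = 0.05 and a 20-voxel cluster-extent
  filter.
- **Synthetic data** — generators for behavior (the task's exact trial
  structure) and BOLD (known ground-truth voxel sets) make every stage
  testable end to end.

## Worked example

The `analysis/` directory is a numbered workflow; each script is a thin
driver over package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R      # task design + 28-participant cohort
Rscript analysis/02_fit_behavior.R  # HBM + variants, WAIC, diagnostics
Rscript analysis/03_conflict.R      # per-trial conflict series
Rscript analysis/04_bold_glm.R      # synthetic BOLD, variable vs fixed epochs
```

Output of stage 2 on the simulated cohort (group-level posterior, 4 chains
of 2000 steps):

```
 parameter      mean hdi_lower hdi_upper      rhat      ess
   beta1_G -1.953663 -2.636864 -1.244841 1.0008269 431.3015
   beta2_G -4.175981 -5.213257 -3.057009 0.9992909 304.6514
   beta3_G  9.287998  7.958509 10.822789 1.0008261 354.1910
  alpha0_G  1.014315  0.958587  1.066557 0.9989785 132.4119
  alpha1_G  1.754306  1.425846  2.085461 0.9996351 634.5921

WAIC (deviance scale; lower is better):
            model     waic     p_waic
     hierarchical 3264.694 145.431326
 non_hierarchical 4832.646   7.196686
     interactions 3268.572 149.125753

posterior predictive RMSE of risky-choice rates: 0.008
```

Reading this: risk suppresses risky choice (negative `beta1_G`,
`beta2_G`), reward drives it (`beta3_G` ≈ 9.3 logits per SD of reward),
and conflicted trials are slower (`alpha1_G` ≈ 1.75 s per unit `d`, i.e.
about 0.44 s at maximal conflict). The hierarchical model beats the
non-hierarchical one by ~1570 deviance units, and adding risk-by-reward
interactions buys nothing — the main-effects model is preferred. All
generating values sit inside their 95% HDIs.

Stage 4 prints the epoch-mode dissociation on synthetic BOLD:

```
variable epochs: 27 suprathreshold voxels, 1 cluster(s); conflict-voxel sensitivity 1.00; deliberation-only false positives 0
fixed epochs: 54 suprathreshold voxels, 2 cluster(s); conflict-voxel sensitivity 1.00; deliberation-only false positives 27
```

The variable-epoch conflict contrast flags exactly the ground-truth
conflict-sensitive cluster; fixed epochs additionally flag the
deliberation-only cluster — the time-on-task confound the variable-epoch
method exists to remove.

`run_pipeline(default_config())` runs the same chain programmatically from
a single validated config, writing every artifact plus a collated
`summary.json`.

## Layout

- `R/`, `src/` — package code (model core, HMC sampler, fMRI design, GLM
  and permutation inference, synthetic-data generators, pipeline).
- `analysis/` — the numbered workflow drivers.
- `tests/testthat/` — unit, property and end-to-end suites, including
  brute-force oracles for TFCE and WAIC and an rjags cross-check of the
  sampler.
- `vignettes/conflict-modelling.Rmd` — the methods vignette: model,
  priors, scale conventions, generator calibration, numerical choices and
  limitations.
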