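# seqactivate

Sequential analysis of real-time fMRI: voxel-wise truncated sequential
probability ratio tests (SPRT) on general linear model contrasts, with a
global stopping rule that ends stimulus administration as soon as enough
voxels have decided.

## The problem

Conventional fMRI mapping fixes the scan length in advance, fits a voxel-wise
general linear model (GLM) after the fact, and thresholds the resulting
statistics. Because BOLD signal-to-noise ratios vary across subjects, fixed
designs must be conservatively long. When volumes can be analyzed as they are
acquired, a sequential test can instead stop a session the moment the data
support a decision, at pre-specified Type I *and* Type II error levels.

`seqactivate` is written for methodologists studying such adaptive designs:
it implements the streaming estimator, the sequential tests, the stopping
rules, a fixed-design benchmark, a synthetic BOLD generator with ground
truth, and an adaptive (halving) search over task difficulty levels.

## The model and test

Per voxel, the BOLD series follows the GLM

    Y_t = X B + E_t,   E_t ~ N(0, sigma^2 V_t),

with `X` the `t x (P+1)` design matrix of HRF-convolved task regressors plus
intercept, and `V_t` the (known) temporal correlation — identity by default,
or AR(1) with supplied `rho`. After every volume the GLS estimate

    B_hat = (X' V^-1 X)^-1 X' V^-1 Y_t

is updated from streaming sufficient statistics (the whitened cross-products
are accumulated causally; one factorization is shared across all voxels).
For a contrast `c` and one-sided hypotheses `H0: cB = theta0` versus
`Ha: cB >= theta1`, the plug-in log likelihood ratio is

    Lambda_t = [ (cB_hat - theta0)^2 - (cB_hat - theta1)^2 ] / (2 Var(cB_hat)),

with `Var(cB_hat) = sigma2_hat * c (X'V^-1X)^-1 c'` and `sigma2_hat` the
variance MLE (divisor `t`). Two-sided hypotheses `|cB - theta0| >= delta`
use an equal-weight mixture of the two alternatives. Sampling continues
while `B < Lambda_t < A`, where

    A = log((1 - beta_n) / alpha_n),   B = log(beta_n / (1 - alpha_n)),

with Bonferroni-adjusted `alpha_n = alpha/N`, `beta_n = beta/N` over the `N`
simultaneous voxel tests, and a truncation bound `T` at which the sign of
`Lambda_T` decides. Scanning stops globally once at least `G` percent of
in-mask voxels have decided all of their hypotheses.

## Worked example

A synthetic two-task session (48 x 48 slice, three disk-shaped activation
regions decaying from peak amplitude 3, blocks of 4 s task / 20 s rest at
TR 2) analyzed over a 289-voxel ROI:

```r
library(seqactivate)

truth <- preset_activation_map(3)                  # peak b = 3
par   <- make_block_paradigm(c("A", "B"), task_s = 4, rest_s = 20,
                             tr = 2, n_volumes = 360)
ds    <- simulate_dataset(truth, par, noise = noise_spec(sigma = 5),
                          seed = 42)

mask <- matrix(FALSE, 48, 48); mask[5:21, 5:21] <- TRUE
hyp  <- hypothesis(c(0, 1, 0), theta1 = 1, label = "taskA")
b    <- compute_boundaries(0.01, 0.1, n_tests = sum(mask),
                           truncation = 360)
b
#> SPRT boundaries: A = 10.2713, B = -7.96898 (alpha = 0.01, beta = 0.1, N = 289, T = 360)

run <- run_sequential(ds, ds$paradigm, hyp, mask = mask, bounds = b,
                      g_percent = 60)
run
#> voxel-wise SPRT run: stopped at volume 121 (G = 60%)
#>   174 of 289 voxels decided at boundaries (60.2%)
#>   classification codes: 0:3  1:286

detection_accuracy(run$class_map, truth, 1, "A", amplitude_floor = 2.4)
#> [1] 100
scan_savings(run$stop_volume, 360)
#> [1] 66.38889
```

The run stopped at volume 121 — once 60% of the ROI's tests crossed a Wald
boundary — classifying every high-amplitude region-1 voxel correctly and
saving two thirds of the 360-volume fixed scan. Classification codes are
bitwise per hypothesis (0 = none, 1 = task A, 2 = task B, 3 = both).

The adaptive difficulty search streams one ROI series per administered
level through a single-series SPRT and walks a binary tree over levels:

```r
subj <- make_halving_subject(halving_profile(2), sigma = 1, seed = 8)
r <- run_halving(subj)
r$level    # classified minimum activating level
r$blocks   # total 11-s blocks administered (fixed design: 150)
```

Benchmarks: `run_fixed()` (batch GLM + Benjamini–Hochberg FDR) mirrors the
sequential engine's interface, and `simulate_halving_study()` produces the
confusion matrices and scan-time savings of both difficulty-level designs.

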