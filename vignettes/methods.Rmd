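---
title: "Models and methods behind pursuitgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pursuitgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pursuitgeom` analyses how a neural population simultaneously encodes the
positions of several agents — the subject's avatar ("self"), the pursued
and non-pursued prey, optionally a predator, and gaze — during a
continuous prey-pursuit task. This vignette documents the models, the
tunable parameters and their defaults, the synthetic generator's scope,
and the numerical choices the implementation rests on.

## The task simulator

The simulated task replicates the structure of the joystick game: a 1800 x
1000 px field at 60 Hz, an avatar capped at 23 px/frame, square prey of 30
px side, trials ending at capture or after 20 s, and a 400 px minimum
initial avatar-prey separation. Prey move by evaluating 15 candidate
positions equally spaced on the circle of radius `prey_max_speed` and
choosing the cheapest on-screen candidate; the cost field is a quadratic
center bias (`center_bias_strength`, default 0.5, normalized by the field
half-diagonal) plus a sigmoidal repulsion from the avatar (midpoint 200
px, slope 0.02/px, treated as exactly zero below cost 1e-3). The original
task specifies the sigmoid's shape but not its constants; these defaults
make prey flee within roughly the 400 px spawn separation, which is the
behaviour the spawn rule is designed around. The predator follows a single
rule: move toward the avatar at constant speed.

The avatar in the original task is human-controlled. The built-in
`"pursuit"` policy replaces the human with noisy proportional pursuit:
heading toward the target prey (nearest at trial start) plus von Mises
noise (`policy_kappa = 3.5`) and a multiplicative speed jitter in
`[0.75, 1]`, with `prey_max_speed = 17` px/frame. These three values were
calibrated once, jointly, so that the policy captures most but not all
prey (capture fraction ~ 0.55-0.8 across seeds, mean trial duration ~ 10
s), mirroring the spread of human performance; they are configuration,
not fitted quantities. Capture is declared at center distance <= 22.5 px
(avatar radius + prey half-side), a monotone proxy for circle-square
tangency; exact tangency is available via `capture_rule = "tangency"`.

Sessions concatenate independently seeded trials with short invalid gaps
between them; every random stream is a child of one root seed keyed by
(trial, neuron, stage), so adding neurons or trials never perturbs
existing data, and identical seeds give bit-identical sessions.

Gaze is simulated directly in screen coordinates as Markov
target-following (switching at `switch_rate`/s among targets weighted by
`follow_weights`) with isotropic jitter and per-frame dropout; it stands
in for eye-tracker output after calibration, which is out of the
simulator's scope.

## Poisson neurons with plantable geometry

`simulate_spikes` draws counts from
`Poisson(dt * exp(log(baseline) + sum_v w_v[bin_v(t)]))`, with the rate
clipped at a configurable ceiling and frames missing any tuned variable
falling back to baseline. The weight maps `w_v` come from one of two
constructors:

- `plant_tuned_neurons` gives each neuron an explicit tuned-variable set
  with one Gaussian log-rate bump per tuned variable — the natural ground
  truth for encoding-model recovery and false-positive measurement.
- `plant_population` plants *population geometry*: each variable's
  `N x 36` weight matrix is `Q_v A_v`, with `Q_v` an orthonormal
  neuron-space basis at chosen principal angles to the reference
  variable's basis, and `A_v` latent bin patterns with orthogonal
  equal-norm zero-mean rows. Under that construction the population
  covariance of each variable is isotropic on its subspace, so the
  alignment index between two planted variables equals `cos^2(theta)`
  exactly — the oracle used throughout the geometry tests. Optional
  extras: latent coordinates tied by an exact linear map `W_true`, and a
  rank-one left/right component `axis_strength * a_v (x) sign(side)`
  whose neuron-space axis `a_v` is shared, inverted, or orthogonal across
  variables, planting the ground truth for cross-condition decoding.

What the generator does *not* emulate: theta rhythms and other temporal
structure beyond position coupling, slow drift, bursting
(non-Poisson dispersion), realistic gaze saccade dynamics, and behavioural
idiosyncrasies of human play. Passing tests therefore demonstrate that the
*estimators* are correct and calibrated on data obeying the model
assumptions, not that real recordings satisfy those assumptions.

## Rate maps and population matrices

Positions are binned on a 6 x 6 grid (half-open bins, last edge closed,
row-major indices) over trials that ended in capture, matching how
sessions are concatenated for analysis. Per-bin rate = spikes /
(occupancy x dt). Never-visited bins are imputed with a
truncated-Gaussian-weighted average of occupied bins (mask recorded), then
maps are smoothed with a Gaussian of sigma = 0.5 bins. The kernel is
truncated at the field boundary and normalized per *source* bin, making
smoothing exactly mass-preserving and linear; the suite checks it against
a brute-force kernel-sum oracle. The order is smooth, then vectorize,
then z-score rows (n-1 denominator; rows with SD < 1e-12 flagged and
excluded from geometry).

## The LN-GLM and forward selection

The encoding model maximizes
`sum_t [y_t eta_t - dt exp(eta_t)] - sum_v beta_v w_v' L w_v` with `L`
the 4-neighbour graph Laplacian of the grid (first-difference smoothness
in both dimensions, no wraparound) by damped Newton iterations with
analytic gradient and Hessian; backtracking guarantees a non-decreasing
penalized objective, and convergence requires a gradient infinity-norm
below 1e-6. Two small ridges make the optimum unique: 1e-8 on the
intercept and 1e-6 on each block's mean weight. The second is needed
because both the likelihood and the Laplacian penalty are invariant to
trading constants between variable blocks — with two or more variables an
intercept ridge alone leaves flat directions. Both ridges only pin the
constants; penalized rates are unaffected at these magnitudes (the suite
checks equality with the closed-form per-bin MLE at `beta = 0` to 1e-6).

Cross-validation deals contiguous ~10 s chunks round-robin into 10 folds,
so temporally autocorrelated samples stay together while every fold
samples the whole session. Held-out performance is the spike-normalized
log-likelihood increase over a training-mean-rate null, in bits/spike
(base 2, configurable). The regularization grid is `10^(0:3)`, shared
across a model's variables, re-selected for every candidate model during
forward selection. Selection grows supersets of the best single-variable
model, accepting a step only if the paired fold values improve
significantly (one-tailed exact Wilcoxon signed-rank, alpha = 0.05; with
10 folds the exact distribution is used, not the normal approximation),
and finally requires the selected model to beat the null the same way,
else the neuron is untuned. All candidate models are compared on the
complete-case frame set of the full candidate pool, so fold values are
paired across models. Because held-out likelihood punishes overfitting,
the realized false-positive rate on constant-rate neurons sits at or below
the nominal 5% (measured at ~3-4% on 100 neurons; the acceptance script
recomputes this). Prediction quality is the Pearson correlation between
predicted and empirical rates after temporal Gaussian smoothing (SD 250
ms, configurable — the comparison needs a smoothing scale and the
originating method does not state one).

## SPAEF, noise ceilings, and the preference index

SPAEF compares smoothed, unnormalized maps (B needs real coefficients of
variation; z-scoring happens only inside C). C uses 10 equal-width bins
over the union range of the two z-scored maps, normalized by the first
map's total count; with 36 values per map this histogram is coarse, which
is documented as a convention, and the bin count is exposed. B is
`cv(second) / cv(first)` — order-sensitive, matching the source metric's
simulated/observed convention. The permutation null shuffles only the
second map's bins (preserving the first's marginal exactly) with an
add-one-corrected two-sided tail on |SPAEF|. Noise ceilings average SPAEF
over random half-splits of captured trials; they are the attainable upper
bound for cross-variable similarity at the session's noise level.

The agent-preference index uses linear-interpolation percentiles (95th -
5th range) of raw maps, normalized by the population mean per variable.
Bimodality is tested with Hartigan's dip statistic, implemented here by
the greatest-convex-minorant / least-concave-majorant construction on a
shrinking modal interval. The minorant is fitted to pre-jump ecdf values
and the majorant to post-jump values, which makes the two canonical exact
results hold: dip = 1/(2n) for unimodally fittable samples and 1/4 for a
balanced two-point mass (both asserted in the suite). The null is the
classical uniform bootstrap (2000 draws); since the null distribution
depends only on n, draws are cached per sample size.

## Subspace analyses

Two covariance conventions coexist, each dictated by its formula's
dimensions: neuron-space `C = M M' / 35` (N x N) for PCA, alignment and
subspace optimization, and condition-space `C = M' M / (N-1)` (36 x 36)
for the covariance-split correlation.

The alignment-index null draws k-dimensional bases as
`orth(C_comb^{1/2} U)` from the covariance of the variable-concatenated
data and reports the fraction of null AIs *smaller* than observed
(add-one corrected) — the stated direction, so small p means "more
orthogonal than chance". The covariance-split correlation computes, per
iteration, the within floor from the two halves of one random trial split
and the cross value from variable a's first half against variable b's
second half of the *same* split: both quantities then rest on equal data
with independent spike noise, and pairing a variable with itself yields
exact ties (p ~ 0.5 under the randomized tie-break). Computing the cross
from a shared half instead would let shared spike noise inflate it above
the within floor whenever two agents' trajectories correlate — which they
strongly do here (self and chosen prey x-positions correlate ~0.98). The
p-value is the fraction of iterations where cross reaches within: small p
= significantly below the noise ceiling.

Orthogonal subspaces maximize the mean normalized captured variance
`(1/V) sum_v tr(Q_v' C_v Q_v) / sum_i^{d_v} sigma_v(i)` over the joint
Stiefel manifold (equal 1/V weighting generalizes the pairwise 1/2) by
Riemannian gradient ascent: tangent-space projection, QR retraction with
sign correction, adaptive step with backtracking (monotone by
construction), five random starts keeping the best. Convergence is a
gradient norm below 1e-6 or an objective plateau (< 1e-9 relative change
sustained over 20 iterations — needed because collinear variables have a
flat optimum manifold on which the gradient never vanishes numerically).
Subspace dimensionality defaults to d = 4 per variable; an elbow reading
(added dimension gains < 5% captured variance and no LOOCV decoding gain)
supports the same value on planted data.

The cross-subspace linear map is plain OLS over the 36 bin conditions
with the Frobenius R^2, computed in full and under leave-one-bin-out
cross-validation via the exact leverage identity `r_loo = r / (1 - h)`
(the suite checks it against a brute-force 36-fold refit loop to 1e-12;
rank-deficient predictors fall back to the loop with a minimum-norm
solution, flagged). The null permutes entries within each row of the
source coordinates, refit per shuffle. For the cross-projection bootstrap
the resampling unit is the neuron (rows resampled with replacement, bases
fixed), and each cross-capture fraction is compared against the
own-subspace capture — the source description names a bootstrap without
stating its unit or null, so this interpretation is flagged as ours.

## CCGP

Captured-trial frames are cut into 40 s chunks (frame-aligned, remainder
discarded and logged). Per variable, the 12 leftmost-column and 12
rightmost-column bins are candidates; the 6 per side with highest
whole-session occupancy are kept (ties broken by ascending index; a
random-6 rule is available as an option, and the occupancy ranking is
fixed across chunks rather than per chunk, reading the procedure as using
one bin set per variable). Each (chunk, selected bin) cell contributes one
population rate vector. Classification is a linear SVM with margin
penalty 1.0 (the common default; exposed). On each of 50 repetitions the
training design is split 70/30 stratified by class (chunk structure is
not stratified; the residual leakage risk is documented), z-scored by
training-row statistics, and tested on the other context's rows whose
(chunk, side, within-side rank) keys fall in the held-out 30% — the rank
key generalizes bin identity when two variables select different bins.
The shuffle null permutes labels independently within each context and
reruns the full repetition procedure; p is the add-one-corrected tail in
the direction of the deviation from 0.5.

One property of the full simulation deserves emphasis. With mixed
selectivity, a neuron's rate multiplies contributions from *all* agents'
positions, so a context's design rows carry coherent contamination along
the planted left/right axis from the other agents' sides, which persist
within a 40 s chunk. Behavioural correlation makes shared-axis transfer
survive (the avatar tracks the chosen prey), but inverted-axis transfer is
masked at desk-scale session lengths. Direction-recovery tests therefore
use `synthetic_ccgp_design`, which plants contrasts directly at the
design level; the full simulation path is exercised by within-context
decoding, shared transfer, and the shuffle-null calibration. Decoding-axis
angle recovery from SVM weights needs high signal-to-noise: the weight
vector of a hard-margin fit on well-separated data is determined by few
support vectors and is noisy across data draws (~15 degrees at moderate
SNR), converging to the planted axis only as separation dominates; the
recovery test runs in that regime. Classical MDS of the cosine-distance
matrix `D_ij = sqrt(2(1 - cos theta_ij))` embeds 4 axes exactly in <= 3
dimensions; the plotted 2-D coordinates are defined up to rotation and
reflection.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything from code at
fixed seeds: sessions of 10-100 trials (10-40 k analyzable frames),
populations of 30-200 neurons, 10-100 CCGP label shuffles x 10-20
repetitions, 100-1000 permutation/bootstrap draws. These sizes were chosen
so each statistical check has comfortable resolution for its tolerance;
the same functions scale to larger runs by changing the arguments. All
stochastic stages draw from named child streams of a single root seed, and
`run_pipeline` records the seed ledger and output hashes in its manifest,
so any stage can be reproduced in isolation.

## Known limitations

- The simulator's avatar policy is a stand-in for human play; cost-field
  constants are conventions, not reconstructions.
- SPAEF's histogram component is coarse at 36 samples per map.
- Estimated-map geometry between behaviourally correlated agents is
  inflated by conditioning leakage (see the README example); the package
  measures this honestly rather than correcting it, since the correction
  is itself a research question.
- The dip test's bootstrap null uses the uniform calibration; heavy-tailed
  unimodal alternatives can exceed the nominal level slightly (the suite
  bounds the realized level at 0.07 for Gaussian samples).
- Predator analyses are supported by the code but the default synthetic
  sessions disable the predator, mirroring the limited predator data in
  the motivating setting.
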