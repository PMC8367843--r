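---
title: "Rate networks and population geometry for context-dependent integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate networks and population geometry for context-dependent integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the model it implements, the
analyses built on top of it, and the numerical and design choices a user
should know before trusting either.

## The model

The network is a standard continuous-time firing-rate model of `N` fully
connected units,

$$\tau \dot x = -x + W_{rec}\, f(x) + W_{in} u + b + \sqrt{2\tau\sigma_{rec}^2}\,\xi,
\qquad z = W_{out} f(x) + b_{out},$$

with the softplus transfer $f(x) = \log(1 + e^x)$, which keeps rates
non-negative and non-saturating. Euler discretization with
$\alpha = \Delta t / \tau$ gives the update implemented in `rnn_step()`:

$$x_t = (1-\alpha)\,x_{t-1} + \alpha\left(W_{rec} r_{t-1} + W_{in} u_t + b
+ \sqrt{2\alpha^{-1}\sigma_{rec}^2}\,\xi_t\right),\qquad r_t = f(x_t).$$

Defaults: $\tau = \Delta t = 20$ ms (so $\alpha = 1$ and the update is a
one-step map), $\sigma_{rec} = 0.05$, $\sigma_{in} = 0.01$, $N = 256$.
Rates are treated as Hz directly; the 5 Hz activation threshold of the
selectivity analysis applies to these softplus outputs. The initial state
of every trial is $x_0 = 0$ (configurable); nothing in the analyses
depends on this except through the fixation epoch, which gives the
network time to relax before the cue.

Softplus is computed as `log1p(exp(x))` with a pass-through branch for
arguments above 30, so it is exact to machine precision at both tails.

## The task

Each trial walks through fixation (200 ms), context cue (400 ms), delay
(800 ms), sensory stimulus (800 ms), and response (200 ms). The cue and
stimulus durations are task constants; the fixation and response
durations are package defaults, configurable in `trial_spec()`. Six input
channels: two one-hot cue units (color context = unit 1), and two units
per sensory modality carrying the evidence streams
$\gamma_{\cdot,1} = \bar\gamma + c$, $\gamma_{\cdot,2} = \bar\gamma - c$,
where the signed coherence $c$ is drawn from
$\{\pm0.01, \pm0.02, \pm0.04, \pm0.08\}$ and $\bar\gamma \sim U(0.8, 1.2)$
per trial. Both modalities are always presented; the cue alone decides
which one should drive the choice. Input noise is i.i.d. Gaussian with
standard deviation $\sqrt{2}\sigma_{in}$ on every channel and step.

Targets hold all four output units at a 0.2 baseline except during the
response epoch, when the two units of the correct channel (channel 1 for
positive relevant coherence) rise to 1.0. Both amplitudes are package
choices — the task defines only which channel must win — and are
configurable in `build_trial()`. Scoring (`score_choice()`) compares the
two channels' mean response-epoch activity; exact ties are ambiguous and
count as errors.

The canonical condition grid is 2 contexts × 8 relevant coherences.
Condition-averaged activity (`condition_activity()`) marginalizes the
irrelevant modality either by running the full 8 × 8 coherence grid
noise-free (deterministic, the default for geometry) or by averaging
noisy trials with resampled irrelevant coherence.

## Training

`train_rnn()` implements backpropagation through the full trial with
Adam (learning rate 5e-4, $\beta_1 = 0.9$, $\beta_2 = 0.999$), batch 64.
The loss is the mean squared output error over all timesteps, output
units and batch trials; because pre-response targets sit at baseline,
scoring every step doubles as the fixation penalty, with no extra mask
machinery (a mask argument exists in `mse_loss()` and the internal
gradient for restricted scoring).

Recurrent weights initialize with unit diagonal and off-diagonal
Gaussian of standard deviation $0.3/N$; output weights $0.4/N$; input
weights uniform on $[-0.5, 0.5]$. The $1/N$ scaling matters: the unit
diagonal already sits at the edge of stability of the $\alpha = 1$ map,
and a $1/\sqrt N$ off-diagonal scale (spectral radius ≈ 1.3) makes the
120-step forward pass diverge before learning can start. With $1/N$ the
radius is $1 + 0.3/\sqrt N$ and training is stable without gradient
clipping (clipping is available via `grad_clip`).

Convergence is declared when the batch loss falls to `loss_threshold`
and evaluated accuracy reaches `perf_threshold` (defaults 0.01 / 0.95,
matching the unlabeled convergence bands of a typical learning-curve
figure). The recurrent noise puts a floor under the MSE (about 0.002 at
N = 64), so thresholds far below that are unreachable; the shipped
reproduction protocol trains to loss ≤ 0.003 at accuracy ≥ 0.95, i.e.
to the floor, because analyses of asymptotic dynamics (attractors,
below) sharpen with convergence depth.

## Geometric analyses

All geometry runs on condition-averaged rates arranged as
$N \times (C\cdot T)$ matrices (20 ms bins, condition-major columns;
`epoch_matrix()`). PCA (`fit_subspace()`) centers each unit by its mean
over the matrix columns — centering per unit over all columns is also
used when projecting held-out trajectories, so projections and subspaces
share an origin.

The four task axes are first principal components of context-restricted
epoch matrices: cue epoch for the C-cue-/M-cue-axes, stimulus epoch for
the C-choice-/M-choice-axes. Axis signs are fixed by requiring a positive
mean projection of the window's second half, which makes signed angles
reproducible across seeds. Axis–subspace angles are
$\arccos\lVert P_S\,v\rVert$ for a unit axis $v$; below 20° we call the
axis parallel to the plane, above 70° orthogonal, following the field's
convention.

Six standard windows are analyzed: the four single epochs, the combined
cue–delay window (cue onset + 100 ms to delay end − 200 ms — the stated
endpoints span 900 ms; a nominal "1000 ms" reading of the same window
exists and both are expressible via `window_bins()` shifts), and the
combined late-integration window (stimulus onset + 500 ms to the
decision, which this package takes as the end of the response epoch).

The integration subspace deserves a note. In large well-trained networks
the choice axes are parallel to the plane of integ-PC2 and integ-PC3,
with integ-PC1 carrying context. At small $N$ the variance split between
context and choice shifts, so `select_integ_plane()` automates the
plane choice by the criterion that actually defines it: the candidate
PC pair with the minimal mean angle to the two choice axes.

## Sequentiality and rotations

`sequentiality_index()` implements
SI = entropy of the peak-time distribution + mean log ridge-to-background
ratio. Defaults: ridge window 1/8 of the epoch length, one entropy bin
per time bin. Units with zero background are excluded from the ridge
term (logged); all-zero units carry no peak and are dropped. The Monte
Carlo control (`si_monte_carlo()`) draws unit subsamples with
replacement (default 128 units, 10,000 draws) and two networks are
compared by a two-sample KS test on the resulting SI distributions.

`fit_rotation()` fits the delay-epoch dynamics two ways after reducing
to the top 6 PCs of condition-concatenated activity (cross-condition
mean trajectory subtracted first): a least-squares skew-symmetric
generator $M$ of $\dot x = Mx$ (first differences as the derivative;
solved in closed form over the elementary skew basis), and the
orthogonal polar factor $Q$ of the unconstrained one-step map
$A = (X_{t+1}X_t^\top)(X_tX_t^\top)^{-1}$. Rotation planes come from
$M$'s conjugate eigenvector pairs, realified as $v + \bar v$ and
$i(v - \bar v)$ and orthonormalized. Rank-deficient data (motionless
directions) fall back to minimum-norm solutions; a singular
$X_tX_t^\top$ is ridge-regularized with a warning.

## Fixed points and line attractors

The search minimizes $q(x) = \tfrac12\lVert\dot x\rVert^2$ under the
condition's constant stimulus input (cue channels zero, irrelevant
coherence at its set mean of 0, $\bar\gamma = 1$). States with
$q < 10^{-4}$ are fixed points, $q < 10^{-2}$ slow points. The
optimizer is Levenberg–Marquardt on the residual $\dot x(x)$ with the
analytic Jacobian; LM's trust region turned out to converge to exact
roots ($q$ down to machine precision) far more reliably than descent on
$q$ itself, whose gradient vanishes along slow manifolds. Restarts
(default 300 per condition) sample a Gaussian ball (σ = 0.5) around the
trajectory's state at stimulus onset; the slow-point protocol instead
uses i.i.d. standard normal states. Candidates are merged when closer
than 0.1 in state space (keeping the lowest $q$; the merge is
idempotent).

Stability is empirical, matching how an attractor is meant to behave:
10 noise-free probes from radius 0.2 must return to within 0.05 of the
point within 100 steps. The continuous-time Jacobian's spectral abscissa
is attached as a diagnostic. On lightly trained networks the search
finds exact fixed points whose abscissa is slightly positive (order
+1e-3 per ms — instability time constants of seconds, much slower than
any epoch); such points fail the probe test and are reported unstable.
The attractor count is therefore a sharp probe of how fully converged a
network's dynamics are, and the package reports whatever the probes
find. Per condition, the attractor is the stable fixed point nearest the
trajectory's end-of-stimulus state (the selection among multiple stable
candidates is otherwise unspecified); `line_attractor_summary()` then
quantifies collinearity of the per-context attractor sets, the distance
of trajectory endpoints (manifold M) to the fitted line, and whether
each endpoint sits nearer its own context's attractors.

## Perturbation experiments

`scale_weights()` multiplies $W_{rec}$ by a factor globally or only at
delay-epoch timesteps (the latter returns a stage-wise simulator; the
baseline checkpoint is never mutated). `sparsify()` zeroes the
smallest-magnitude off-diagonal weights (the zeroing rule is a package
choice; magnitude ranking is the natural one) and preserves the
diagonal. The default scale sweep {0.80, 0.90, 0.95, 1.0, 1.05, 1.10,
1.20} brackets the identity.
`perturbed_geometry()` projects perturbed trajectories into baseline
subspaces and counts violations of the per-context evidence ordering of
end-of-stimulus states along the fitted evidence direction.

## What the synthetic data does and does not show

Everything here is simulation: the package generates its own training
data from the task definition, and the "fixture" network
(`make_fixture()`, N = 32 trained to ≥ 0.85 accuracy) exists so that
every analysis has a realistic trained substrate in seconds-to-minutes.
Passing tests demonstrate internal consistency of the model, task and
analyses — they say nothing about biological tissue, and small networks
differ quantitatively from large ones: variance concentrates in fewer
dimensions (cumulative explained-variance figures run several points
high at N = 64 versus a full-size N = 256 ensemble), the trained-vs-untrained
sequentiality gap narrows below N ≈ 64, and attractor stability sharpens
with training depth. Problem sizes used by the shipped checks — N = 32
fixture, N = 64 analysis ensemble, 3 seeds — are the package's choice of
desk-scale study conditions; the model itself runs at N = 256 unchanged.

## Known limitations

No Dale's-law sign constraints, no spiking, no biologically plausible
learning rule, no reaction-time variant of the task, no
continuation/bifurcation analysis of the attractor structure, and no
statistical test for rotation significance beyond the fit's $R^2$.
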