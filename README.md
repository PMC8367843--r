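# rnngeom

Rate recurrent networks and population geometry for context-dependent
decision making.

## The problem

How does a neural circuit hold a context rule in working memory across a
delay and then use it to integrate only the relevant stream of sensory
evidence? A standard model system for this question is a firing-rate
recurrent network trained on a delayed context-dependent integration
task: a transient two-unit cue announces whether the color or the motion
modality matters on this trial, a delay follows, then both modalities
stream noisy evidence, and the network must saccade-commit to the choice
supported by the relevant modality alone. `rnngeom` provides both halves
of that research program in R: the model (task, network, training) and
the analysis toolbox that turns trained networks into interpretable
population geometry. It is written for computational neuroscientists who
want a self-contained, seedable substrate for studying context-dependent
computation, and for methodologists who want the geometric analyses
(epoch subspaces, task axes, sequentiality, rotational dynamics, fixed
points) as reusable parts.

## The model and the analyses

The network is the standard rate model
`tau x' = -x + W_rec f(x) + W_in u + b + sqrt(2 tau sigma_rec^2) xi`
with softplus `f(x) = log(1 + exp(x))`, linear readout
`z = W_out f(x) + b_out`, Euler-discretized with `alpha = dt / tau = 1`,
and trained by backpropagation through time with Adam (lr 5e-4) on a
mean-squared output error. Trials run fixation (200 ms) → cue (400 ms) →
delay (800 ms) → stimulus (800 ms) → response (200 ms) at 20-ms steps;
evidence strengths are `gamma_bar ± c` with signed coherence `c` from
`{±0.01, ±0.02, ±0.04, ±0.08}`.

On top of trained networks the package computes:

- **Epoch-wise PCA subspaces** on `N × (C·T)` condition-averaged
  matrices and the four **task axes** (C-cue, M-cue, C-choice, M-choice =
  first PCs of context-restricted epoch matrices), with axis–subspace
  and axis–axis angles (`fit_subspace`, `define_task_axis`,
  `axis_subspace_angle`).
- **Trajectory kinematics**: inter-context distance, velocity
  `dist(P_t, P_{t+n})/n`, and network energy (mean rate of activated
  units).
- **Mixed selectivity**: 5-Hz activation threshold, response-difference
  selectivity per task variable, pure/mixed taxonomy and population
  fractions (`classify_selectivity`, `selectivity_fractions`).
- **Sequentiality**: peak sorting, the sequentiality index
  SI = peak-time entropy + mean log ridge-to-background, Monte Carlo
  subsampling control with KS comparison, and the recurrent-weight
  vs. peak-order-offset profile.
- **Rotational dynamics**: least-squares skew-symmetric generator of
  `x' = Mx` (closed form), and the orthogonal polar factor Q of the
  unconstrained one-step map, with rotation-plane projections
  (`fit_rotation`, `project_rotations`).
- **Fixed points and line attractors**: Levenberg–Marquardt minimization
  of `q(x) = ||x'||²/2` under constant stimulus input, q-thresholded
  fixed/slow classification, empirical stability probes, per-condition
  attractor selection and line-attractor summaries
  (`find_fixed_points`, `condition_attractors`,
  `line_attractor_summary`).
- **Weight perturbation**: global and delay-local recurrent scaling,
  magnitude sparsification, self-connection statistics, and perturbed
  trajectory geometry in baseline subspaces.

## Worked example

```r
library(rnngeom)
set.seed(7)
fx <- make_fixture(seed = 7, N = 32)          # small trained network
fx$performance
#> [1] 0.928
act <- fx$activity                            # 16 condition averages
cue_sub <- fit_subspace(epoch_matrix(act, "cue"), k = 2)
cue_sub
#> subspace: 32 units, k = 2, explained variance 78.4% + 19.8% (cum 98.1%)
c_cue <- define_task_axis(act, "C-cue")
m_cue <- define_task_axis(act, "M-cue")
axis_subspace_angle(c_cue, cue_sub)           # 7.6 degrees
axis_axis_angle(c_cue, m_cue)                 # 77.4 degrees
sequentiality_index(act)
#> seq_stats: SI = 2.096 (entropy 1.895 + mean log ridge 0.201), 32 units
```

Read: the 2-D cue subspace captures 98% of cue-epoch population
variance; the color-context cue axis lies essentially inside it
(7.6° — "parallel" by the <20° convention) while the two context axes
are nearly orthogonal to each other (77.4°), i.e. the two contexts are
encoded in separate directions of one low-dimensional plane. The SI
decomposition says delay-period units tile time (entropy 1.9 of a
possible log(40) ≈ 3.7) with modest ridges.

A full train → simulate → analyze run is scripted in
`inst/cli/rnngeom.R`:

```sh
Rscript inst/cli/rnngeom.R pipeline --seed 1 --out runs/demo
Rscript inst/cli/rnngeom.R perturb --ckpt runs/demo/checkpoint.rds \
    --mode global --scale 1.1 --out runs/demo/perturb.csv
```

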