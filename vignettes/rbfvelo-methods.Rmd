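---
title: "rbfvelo: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rbfvelo: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `rbfvelo`, the
inference procedure, every tunable that matters, the numerical choices that
were genuinely open, and what the simulation-based tests do and do not
establish about real data.

## The model

RNA velocity is the time derivative of spliced mRNA abundance. `rbfvelo`
parameterizes each gene's spliced profile directly as a radial basis
function of a latent time $t \in (0,1)$ shared by all genes of a cell:

$$s_g(t) = h_g\, e^{-a_g (t - \tau_g)^2} + o_g,$$

and derives the expected unspliced abundance through the splicing ODE
$\mathrm{d}s/\mathrm{d}t = \beta u - \gamma s$:

$$u_g(t) = \frac{s_g'(t) + \gamma_g\, s_g(t)}{\beta_g} + i_g .$$

Velocity is the analytic derivative $s_g'(t) = (s_g(t) - o_g)\,(-2 a_g (t -
\tau_g))$. A single Gaussian-kernel family covers the three canonical
expression behaviors through the location of the peak time $\tau_g$ alone:
a peak at or before the start of the axis means the gene only falls
(repressed, $\tau \le 0$), a peak at or beyond the end means it only rises
(induction, $\tau \ge 1$), and an interior peak gives a rise-then-fall
transient ($0 < \tau < 1$). `classify_genes()` applies exactly these
thresholds.

Observed smoothed moments $(u_i, s_i)$ of a gene across cells are modeled
with Gaussian residuals in the $(u, s)$ plane, giving the per-gene negative
log-likelihood

$$\ell(\theta_g) = \pi b_g^2 \sum_i \lVert x_i - \hat x_i(t_i)\rVert^2 -
\log b_g, \qquad b_g = \tfrac{1}{\sqrt{2\pi}\,\sigma_g},$$

which is what the optimizer minimizes; the precision $b_g$ is itself a free
parameter, so the noise level per gene is learned.

Two formulation details were open and are worth recording:

* **Offset in the velocity.** The derivative of $s_g(t)$ kills the constant
  $o_g$, so the default velocity is $(s - o)\cdot(-2a(t-\tau))$. The looser
  algebraic form $s\cdot(-2a(t-\tau))$, which multiplies the full spliced
  value including the offset, is sometimes written instead; both are
  implemented (`rbf_velocity(..., form = "printed")`) and agree whenever
  $o = 0$. We follow the calculus by default.
* **Shared vs per-dimension precision.** The likelihood above shares one
  $b_g$ between the unspliced and spliced residual dimensions. A variant
  with separate precisions (`rbf_nll(..., b_u = )`) is provided; the shared
  form is the default because the combined likelihood treats the residual as
  one vector in the phase plane.

## Inference

Two parameter sets are estimated: the gene-wise $\theta_g = (h, a, \tau,
\gamma, \beta, b, o, i)$ and the cell times. `fit_velocity()` alternates:

1. **Gradient phase** (most iterations): Adam updates of all $\theta_g$
   against the summed loss with times fixed. Positivity of $(h, a, \gamma,
   \beta, b)$ is enforced by optimizing their logarithms; unconstrained
   gradient steps on the raw scale would otherwise cross zero. Gradients
   are analytic and evaluated in compiled code.
2. **Assignment phase** (every `reassign_every` iterations): with
   $\theta_g$ frozen, each cell-gene pair is re-projected onto the updated
   phase trajectory by grid search over `grid_size` equally spaced
   candidates in $[0, 1]$, minimizing the squared $(u, s)$ distance. Ties
   go to the smallest candidate time (a fixed, order-independent rule).
3. **Unification** (unified mode only): per-gene times are mapped onto a
   common scale by the fractional-rank transform $Q[t_{ng}] = (\mathrm{rank}
   - 0.5)/N$ (ties averaged), optionally denoised by a truncated SVD of the
   rank matrix, averaged across genes, and min-max rescaled to $[0, 1]$.
   The rank transform is our reading of "re-ordering cells by relative
   position": it aligns genes that agree on the ordering while discarding
   incomparable raw time values.

The fit stops when the proportional change of the total loss stays below
`conv_tol` through an entire re-assignment cycle (gradient steps *and* the
re-assignment itself), or at `max_iters`. The optimizer state is carried
across re-assignments rather than reset; re-assignment changes the loss
surface only through the data term, and preserving momentum avoids a cold
restart every few iterations.

### Defaults and their rationale

| parameter | default | meaning |
|---|---|---|
| `max_iters` | 12000 | iteration cap; convergence typically stops fits at a few hundred to a few thousand iterations |
| `reassign_every` | 10 | gradient iterations per assignment; frequent enough that times track the trajectories, rare enough that Adam makes progress |
| `grid_size` | 100 | time resolution 1/99; the rank transform removes the quantization in unified mode |
| `learning_rate` | 0.01 | Adam step size on the (log-)parameter scale |
| `conv_tol` | 1e-4 | proportional loss-change threshold |
| `denoise_dims` | 50 | SVD rank for unification, applied only when more than 100 genes are fitted (below that the average over genes is already stable) |
| `min_cells` | 20 | joint unspliced+spliced detection filter |
| `n_top` (HVGs) | 2000 | binned-dispersion highly variable genes |
| `n_pcs`, `n_neighbors` | 30, 30 | PCA rank and KNN neighborhood for moment smoothing |
| `min_gamma`, `min_r2` | 0.01, 0.01 | steady-state slope and fit filters for velocity genes |
| `sigma_lo`, `sigma_hi` | 0.03, 3 | admissible sd(u)/sd(s) range |

### Initialization

Peak times start at the non-informative $\tau_g = 0.5$ (every gene assumed
to traverse induction and repression). Amplitudes and offsets come from
data ranges ($h \approx \max - \min$ of the smoothed spliced layer, $o$ and
$i$ the layer minima), rates start at 1, and $b$ at its closed-form optimum
given the initial residuals (the loss is analytically minimized in $b$ at
fixed residuals, so starting anywhere else only adds burn-in). The initial
cell time is the fractional rank of each cell's total smoothed spliced
signal — a deliberately crude monotone proxy; the first few re-assignment
cycles replace it. Initialization is deterministic, and the only stochastic
ingredients of a fit (SVD initialization inside the truncated
decompositions) are governed by the single `seed` in `fit_config()` through
a private RNG stream.

### The two modes, and choosing between them

Unified mode pools ordering evidence across the transcriptome; it is the
default and the right choice for most single-lineage datasets, where many
genes change monotonically and per-gene phase portraits are
under-determined. Independent mode keeps a per-gene time matrix, pins
$(\tau, o, i)$ at $(0.5, 0, 0)$ — forcing a full induction+repression
portrait anchored at the origin — and skips unification; it suits data
whose structure breaks a single global ordering, such as cell-cycle-driven
or fragmented (sparse-cluster) datasets. `choose_mode()` recommends
independent mode when either trigger fires: more than half of the S-phase
or G2M-phase marker list is highly variable, or strictly more than 2
clusters have mean same-cluster KNN purity above 95%. The thresholds are
user-adjustable and the recommendation is only a recommendation; the mode
remains a user hyper-parameter. Cluster purity is aggregated as the mean
over member cells of each cell's same-cluster neighbor fraction — the
per-cell fractions are the primitive quantity, and averaging them weights
every cell equally.

## Preprocessing choices

Counts are size-normalized per layer (each cell scaled to the median total
of that layer), genes must be jointly detected in both layers in at least
`min_cells` cells, and HVGs are ranked by mean-binned normalized dispersion
(variance/mean z-scored within 20 quantile bins of the mean). PCA is
computed on the log1p of the normalized spliced layer over HVGs, and the
KNN neighborhood of size `n_neighbors` *includes the cell itself* plus its
nearest neighbors — self-inclusion keeps small neighborhoods stable and
makes the smoothing operator a proper averaging (a cell identical to its
neighbors is a fixed point). The steady-state velocity-gene regression is
zero-intercept least squares of smoothed unspliced on smoothed spliced,
the classical $\gamma$ estimator that the 0.01 slope threshold was
formulated for; its $R^2$ is computed against the centered total sum of
squares, so anticorrelated genes score negative and are excluded. The
sd-ratio filter runs on the smoothed layers, consistent with everything
downstream. One ordering question — HVG selection before or after the
detection filter — is resolved as filter-first, which matches the listed
order of operations and only ever removes genes the HVG ranking would
waste slots on.

When a unified cell time exists, `amplify_velocity_genes()` can re-admit
HVGs that failed the steady-state filters but whose spliced profile is well
explained by a linear regression on cell time ($R^2$ above the `AGENES_R2`
configuration value). The pipeline runs it after a first converged fit and
refits when genes were added.

## Evaluation

Per-gene goodness of fit is $R^2 = 1 - \mathrm{MSE}/\mathrm{Var}$ of the
fitted spliced mean at assigned times (spliced only; negative values flag
genes the time function does not explain). For direction metrics the
gene-space velocity is projected onto the embedding: cosine similarities
between a cell's velocity and the expression displacement to each KNN
neighbor are softmax-weighted, the uniform baseline $1/k$ is subtracted
(so zero velocity maps to the zero vector and pure density gradients
cancel), and the weighted sum of embedding displacements is normalized to
a unit direction. The softmax temperature is adaptive — the cell's mean
absolute cosine — so weak but consistent signals are sharpened comparably
to strong ones; with a fixed temperature, cells with small cosines would
receive near-uniform weights exactly where discrimination matters most.
Any standard variant of this projection is acceptable for the metrics; the
adaptive choice is validated by the synthetic-direction test (velocities
point from early to late clusters for >90% of cells).

Cross-boundary direction correctness (CBDir) scores, for a ground-truth
transition $A \to B$, the mean cosine between a boundary cell's projected
velocity and the displacements toward its target-cluster neighbors,
averaged over boundary cells of the source cluster; both the unweighted
mean over pairs and the boundary-cell-count weighted mean are reported,
since the aggregation convention is not fixed. In-cluster coherence
(ICCoh) is the mean cosine among same-cluster neighbors; it measures
smoothness only and is exactly invariant to global negation of the
velocity field — a reversed but coherent field scores identically, which
is why the two metrics must be read together.

## The simulator

`simulate_dataset()` forward-simulates the generative model: true times
(uniform by default), per-gene parameters drawn per class — repressed
$\tau \sim U(-0.5, -0.05)$, induction $\tau \sim U(1.05, 1.5)$ (kernel
width $a \sim U(1.5, 4)$ so the visible window captures a meaningful rise
or fall), transient $\tau \sim U(0.3, 0.7)$ with $a \sim U(5, 15)$ (peaks
visibly inside the window) — amplitudes $h \sim U(1, 3)$, rates $\gamma
\sim U(1, 4)$, $\beta \sim U(0.8, 2)$, offsets $o \sim U(0, 0.3)$, $i \sim
U(0, 0.2)$. Gaussian noise with per-gene sd equal to `noise_sd` × $h_g$ is
added to both layers and truncated at zero, respecting the nonnegativity
of normalized counts (the truncation is our addition for count realism;
the likelihood's residual model is plain Gaussian). Cluster labels are
ordered time bins with ground-truth transitions bin$_k \to$ bin$_{k+1}$,
and the embedding places cells on a half-circle arc parameterized by true
time with jitter sd 0.05 — a smooth 1-D manifold in 2-D, the geometry the
direction metrics assume.

The default conditions — 500 cells × 200 genes, `noise_sd = 0.1`, class
mix 40% induction / 30% repression / 30% transient, 5 bins — are the
package's reference experiment. The mild excess of induction over
repression reflects that differentiation datasets typically activate
somewhat more programs than they shut down; it also gives the monotone
genes a common majority direction, which is what makes *signed* time
recovery possible at all (see below). Layers are generated on the
normalized scale the likelihood operates on, so pipelines on simulated
data use `normalize_and_filter(size_normalize = FALSE)`: re-scaling each
cell to the median total would distort per-gene trajectories, because the
true per-cell totals legitimately vary along the trajectory.

What the simulator does **not** emulate: count noise (Poisson/negative
binomial capture), dropout structure, library-size variation, batch
effects, doublets, branching topologies, or genes violating the
single-kernel assumption (an optional late-time amplitude boost,
`murk_frac`, provides a controlled multiple-rate-kinetics stressor).
Passing the recovery tests therefore demonstrates correctness of the
estimator under its own generative assumptions — identifiability,
optimization, aggregation — not robustness to everything real data does.

## Identifiability and orientation

The model is invariant under time reversal $t \mapsto 1 - t$ combined with
$\tau_g \mapsto 1 - \tau_g$ (and the induced relabeling repressed ↔
induction): both orientations have identical likelihood. The unified
aggregation breaks the tie only through the data — when a majority of
monotone genes share a direction, the initialization (rank of total
spliced signal) and the pooled ordering settle on one orientation, but
which one is not guaranteed. Recovery is therefore assessed
orientation-aware: latent-time agreement by $|\rho|$, and class labels and
velocity signs after orienting the fit by the sign of its correlation with
the reference ordering. On real data the same degree of freedom appears as
the choice of which trajectory end is "early"; it is resolved by biology
(known progenitor states), not by the likelihood.

## Numerical details

* Grid-search ties take the smallest candidate time; assignment is exactly
  reproducible and independent of gene order.
* Log-parameters are clamped to $[-18, 18]$ and $\tau$ to $[-5, 6]$ after
  each Adam step; the clamps are far outside any plausible optimum and
  only guard against transient overshoot early in optimization.
* A loss increase beyond 10× the initial loss aborts with a diagnostic
  (runaway learning rate); non-finite gradients abort naming the gene.
* Constant genes (zero spliced range) get their amplitude floored at 1e-6
  and are flagged in the initialization rather than silently fitted.
* The SVD denoise uses a truncated decomposition (exact SVD for small
  problems); its random initialization is the one seeded ingredient of a
  fit.
* Held-out cells are placed on the training time scale by per-gene
  quantile mapping against the training assignments (midpoint convention
  for ties), so a held-out cell identical to a training cell reproduces
  that cell's unified time exactly when denoising is off.

## Problem sizes used by the test-suite experiments

The reference recovery experiment fits 500 cells × 200 genes (about 80
velocity genes after filtering) and converges in a few hundred iterations;
the down-sampling experiment simulates 5,000 cells × 100 genes, fits the
full data and a stratified 50% subset, and compares held-out predicted
times with the full fit. Oracle checks (finite differences, brute-force
grid search, brute-force CBDir/ICCoh) run on problems small enough to
enumerate. These sizes were chosen as the smallest at which the studied
effects — aggregation gain, class separation, down-sampling stability —
are clearly expressed.

## Known limitations

* One global latent time: branching trajectories are out of scope; on
  branched data the unified ordering interleaves branches.
* The RBF family enforces a single expression peak per gene; genes with
  multiple kinetic regimes are mis-fit unless treated in independent mode
  (or excluded by the $R^2$ report).
* CBDir requires user-supplied ground-truth transitions and a meaningful
  low-dimensional embedding; ICCoh rewards smoothness even when the
  direction is globally wrong.
* The h5ad/loom readers cover the layer/obs/obsm subset this tool needs,
  not the full AnnData/loom specifications; results are written to a
  plain-text MTX container.
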