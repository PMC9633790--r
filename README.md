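# rbfvelo

RNA velocity estimation with radial-basis-function dynamics and a unified
latent time, for single-cell transcriptomics.

## The problem

RNA velocity infers the direction and speed of cellular differentiation from
the balance between unspliced (nascent) and spliced (mature) mRNA in
single-cell RNA-seq data. Classical estimators work bottom-up: they posit a
step-function transcription rate, derive unspliced/spliced profiles from the
splicing ODE, and fit each gene's phase portrait independently. That per-gene
flexibility makes them fragile on the many genes that change monotonically
(quasi-steady-state) along a trajectory, where the induction/repression
assignment has weak directional signal.

`rbfvelo` takes the top-down route: the **spliced** profile of each gene is
modeled directly as a radial basis function of latent time,

```
s_g(t) = h_g · exp(−a_g (t − τ_g)²) + o_g
u_g(t) = ( s_g′(t) + γ_g s_g(t) ) / β_g + i_g
velocity_g(t) = s_g′(t) = (s_g(t) − o_g) · (−2 a_g (t − τ_g))
```

where `h` is the amplitude, `a` the kernel width, `τ` the peak time, `o`/`i`
offsets, and `γ`, `β` the degradation and splicing rates linking the two
layers through the splicing ODE `ds/dt = β u − γ s`. Velocity is the analytic
derivative of the fitted spliced mean — no steady-state deviation needed.
The peak time classifies each gene's behavior on the trajectory: repressed
(`τ ≤ 0`), induction (`τ ≥ 1`), or transient (`0 < τ < 1`).

Parameters are estimated per gene by minimizing the negative log-likelihood

```
l(θ_g) = π b_g² Σ_i |x_i − x̂_i(t)|² − log b_g
```

(joint residuals in the (u, s) plane, precision `b = 1/(√(2π)σ)`) with Adam
gradient descent, alternated with periodic grid-search re-assignment of cell
times to the updated phase trajectories. In the default **unified-time
mode**, per-gene time assignments are aggregated across the transcriptome by
a quantile (rank) transform and averaged — one shared latent time per cell —
which pools directional evidence from stably, monotonically changing genes.
An **independent mode** (per-gene times, `(τ, o, i)` pinned at
`(0.5, 0, 0)`) is available for cycling or fragmented datasets, with a
heuristic (`choose_mode()`) that recommends it when cell-cycle genes are
enriched among HVGs or when many clusters are detached from the manifold.

## Worked example

Simulate a differentiation trajectory from the generative model, preprocess,
fit, and evaluate against the known bin-to-bin transitions:

```r
library(rbfvelo)

sce <- simulate_dataset(sim_spec(n_cells = 400, n_genes = 150, seed = 3))
sce <- normalize_and_filter(sce, size_normalize = FALSE)  # already depth-normalized
sce <- select_hvg(sce, n_top = 2000)
sce <- knn_moments(sce)                  # 30 PCs, 30-cell neighborhoods
sce <- select_velocity_genes(sce)        # γ > 0.01, R² > 0.01, σ-ratio ∈ [0.03, 3]

fit <- fit_velocity(sce, fit_config(seed = 1))
fit
#> velocity_fit: 58 genes x 400 cells, mode=unified
#>   iterations: 1350 (converged), final loss 97.9947
#>   gene classes: repressed=30 transient=4 induction=24

truth <- S4Vectors::metadata(sce)$truth
evaluate_velocity(sce, fit, truth$transitions)
#> eval_report: CBDir mean 0.647 (weighted 0.621), ICCoh mean 0.988
#> bin1->bin2 bin2->bin3 bin3->bin4 bin4->bin5
#>      0.740      0.844      0.306      0.696

cor(fit$time, truth$time, method = "spearman")
#> [1] 0.9993676
```

The fit recovers the latent ordering of cells almost exactly (Spearman ρ =
0.999); the cross-boundary direction correctness (CBDir, cosine agreement
between projected velocities and displacements toward the next cluster) is
positive for every transition, and the in-cluster coherence (ICCoh) shows a
smooth velocity field. `fit$velocity` holds the cells × genes velocity
matrix, `fit$time` the unified latent time in [0, 1], `fit$gene_class` the
τ-based classification, and `fit$gene_r2` the per-gene goodness of fit.

The same analysis runs from the shell on any container with
`spliced`/`unspliced` layers (MTX directory, `.h5ad`, or `.loom`):

```sh
rbfvelo run --input data.h5ad --mode auto --transitions truth.tsv --out results/
```

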