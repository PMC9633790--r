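#' Specification of a simulated velocity dataset
#'
#' Defines the generative conditions for forward-simulating spliced and
#' unspliced layers from the RBF dynamics. Gene classes control the peak
#' time: repressed genes peak before the trajectory (`tau < 0`, monotone
#' decline), induction genes after it (`tau > 1`, monotone rise), transient
#' genes inside it (`tau` in (0.3, 0.7), rise then fall). Gaussian noise
#' proportional to each gene's amplitude is added per layer and truncated at
#' zero so the layers remain nonnegative like normalized counts. Cluster
#' labels are ordered time bins, with ground-truth transitions bin k ->
#' bin k+1, and the embedding places cells along a noisy 2-D arc.
#'
#' @param n_cells,n_genes dataset size (defaults 500 x 200).
#' @param frac_induction,frac_repression,frac_transient gene-class mix,
#'   summing to 1 (defaults 0.4/0.3/0.3).
#' @param noise_sd noise standard deviation as a fraction of each gene's
#'   amplitude `h` (default 0.1).
#' @param time_dist distribution of true cell times: `"uniform"` or `"beta"`
#'   (mildly front-loaded, shape (2, 3)).
#' @param n_clusters number of ordered time-bin clusters (default 5).
#' @param murk_frac fraction of genes with a late-time amplitude boost
#'   (multiple-rate-kinetics stressor; default 0 = off).
#' @param seed RNG seed; the simulation is bit-reproducible given the spec.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_cells = 500, n_genes = 200, frac_induction = 0.4,
                     frac_repression = 0.3, frac_transient = 0.3,
                     noise_sd = 0.1, time_dist = c("uniform", "beta"),
                     n_clusters = 5, murk_frac = 0, seed = 1L) {
  time_dist <- match.arg(time_dist)
  .assert(n_cells >= 2 && n_genes >= 1, "need at least 2 cells and 1 gene")
  .assert(abs(frac_induction + frac_repression + frac_transient - 1) < 1e-8,
          "class fractions must sum to 1")
  .assert(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 frac_induction = frac_induction,
                 frac_repression = frac_repression,
                 frac_transient = frac_transient, noise_sd = noise_sd,
                 time_dist = time_dist, n_clusters = as.integer(n_clusters),
                 murk_frac = murk_frac, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Forward-simulate a velocity dataset from the RBF model
#'
#' Draws true cell times and per-gene parameters, evaluates the noiseless
#' spliced/unspliced means through the model equations, adds truncated
#' Gaussian noise, and packages everything as a dataset ready for the
#' pipeline. All ground truth (times, parameters, classes, noiseless
#' velocity, bin transitions) is stored in `metadata(sce)$truth`.
#'
#' Layers are generated directly on the normalized-expression scale the
#' model operates on; run [normalize_and_filter()] with
#' `size_normalize = FALSE` on these data.
#'
#' @param spec a [sim_spec()].
#' @return A `SingleCellExperiment` with assays `spliced`/`unspliced`,
#'   ordered `clusters`, an `"embedding"` reducedDim, and ground truth in
#'   the metadata.
#' @export
simulate_dataset <- function(spec) {
  .assert(inherits(spec, "sim_spec"), "spec must come from sim_spec()")
  with_local_seed(spec$seed, {
    n <- spec$n_cells; G <- spec$n_genes
    t_true <- switch(spec$time_dist,
                     uniform = runif(n),
                     beta = rbeta(n, 2, 3))
    n_ind <- round(spec$frac_induction * G)
    n_rep <- round(spec$frac_repression * G)
    n_tra <- G - n_ind - n_rep
    cls <- rep(c("induction", "repressed", "transient"),
               c(n_ind, n_rep, n_tra))
    tau <- c(runif(n_ind, 1.05, 1.5), runif(n_rep, -0.5, -0.05),
             runif(n_tra, 0.3, 0.7))
    a <- ifelse(cls == "transient", runif(G, 5, 15), runif(G, 1.5, 4))
    params <- rbf_params(h = runif(G, 1, 3), a = a, tau = tau,
                         gamma = runif(G, 1, 4), beta = runif(G, 0.8, 2),
                         b = rep(1, G), o = runif(G, 0, 0.3),
                         i = runif(G, 0, 0.2),
                         gene = sprintf("gene%d", seq_len(G)))
    s_mean <- rbf_spliced(params, t_true)
    u_mean <- rbf_unspliced(params, t_true)
    if (spec$murk_frac > 0) {
      boosted <- seq_len(G) <= ceiling(spec$murk_frac * G) & cls != "repressed"
      boost <- 1 + 1.5 * pmax(0, t_true - 0.7) / 0.3
      s_mean[, boosted] <- s_mean[, boosted] * boost
      u_mean[, boosted] <- u_mean[, boosted] * boost
    }
    sdm <- matrix(spec$noise_sd * params$h, n, G, byrow = TRUE)
    s_obs <- pmax(s_mean + rnorm(n * G) * sdm, 0)
    u_obs <- pmax(u_mean + rnorm(n * G) * sdm, 0)
    bins <- cut(t_true, breaks = seq(0, 1, length.out = spec$n_clusters + 1),
                include.lowest = TRUE,
                labels = sprintf("bin%d", seq_len(spec$n_clusters)))
    theta <- pi * (1 - t_true)
    emb <- cbind(cos(theta), sin(theta)) + matrix(rnorm(2 * n, sd = 0.05), n, 2)
    sce <- velocity_dataset(t(s_obs), t(u_obs), clusters = bins,
                            embedding = emb)
    S4Vectors::metadata(sce)$truth <- list(
      time = t_true, params = params,
      class = factor(cls, levels = c("repressed", "transient", "induction")),
      velocity = rbf_velocity(params, t_true),
      s_mean = s_mean, u_mean = u_mean,
      transitions = data.frame(
        source = sprintf("bin%d", seq_len(spec$n_clusters - 1)),
        target = sprintf("bin%d", 2:spec$n_clusters)),
      spec = spec)
    sce
  })
}
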