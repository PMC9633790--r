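#' Cluster-stratified down-sampling
#'
#' Samples cells for training per cluster: each cluster keeps
#' `max(min_per_cluster, frac * size)` cells (capped at the cluster size),
#' so rare populations are never lost. Sampling is without replacement and
#' deterministic under `seed`.
#'
#' @param sce dataset with `clusters`.
#' @param frac sampling fraction in (0, 1].
#' @param min_per_cluster minimum cells to keep per cluster (default 50).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `heldout`.
#' @export
stratified_downsample <- function(sce, frac, min_per_cluster = 50, seed = 1L) {
  .assert(is.numeric(frac) && frac > 0 && frac <= 1, "frac must be in (0, 1]")
  cl <- sce$clusters
  .assert(!is.null(cl), "cluster labels required for stratified down-sampling")
  train <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(ncol(sce)), cl), function(idx) {
      target <- min(length(idx), max(min_per_cluster, ceiling(frac * length(idx))))
      sort(sample(idx, target))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, heldout = setdiff(seq_len(ncol(sce)), train))
}

#' Predict latent time and velocity for held-out cells
#'
#' Held-out cells are projected onto the frozen fitted phase trajectories by
#' the same grid search used during training. In unified mode the per-gene
#' assignments are mapped onto the training time scale by per-gene quantile
#' mapping against the training assignments, averaged across genes, and
#' rescaled with the training min-max bounds; in independent mode the
#' per-gene matrix is returned directly. Velocities are the model derivative
#' at the predicted times. Deterministic given the fit.
#'
#' @param fit a `velocity_fit` trained on a subset of cells.
#' @param sce the full preprocessed dataset (moments available for all
#'   cells).
#' @param heldout integer or character index of held-out cells.
#' @return List with `time` (vector or matrix) and `velocity`
#'   (cells x genes) for the held-out cells; empty inputs give empty
#'   outputs.
#' @export
predict_heldout <- function(fit, sce, heldout) {
  genes <- fit$genes
  missing <- setdiff(genes, rownames(sce))
  .assert(length(missing) == 0,
          "fitted genes absent from the dataset: %s",
          paste(head(missing, 5), collapse = ", "))
  if (length(heldout) == 0)
    return(list(time = numeric(0),
                velocity = matrix(0, 0, length(genes),
                                  dimnames = list(NULL, genes))))
  sub <- sce[, heldout]
  mm <- moment_matrices(sub, genes)
  Tng <- assign_time(fit$params, mm$Mu, mm$Ms, fit$config$grid_size)
  if (fit$mode == "independent") {
    vel <- rbf_velocity(fit$params, Tng)
    dimnames(vel) <- dimnames(Tng)
    return(list(time = Tng, velocity = vel))
  }
  # quantile-map each gene's held-out times against the training assignments
  n_tr <- nrow(fit$time_ng)
  Q <- matrix(0, nrow(Tng), ncol(Tng))
  for (g in seq_along(genes)) {
    tr <- sort(fit$time_ng[, g])
    lo <- findInterval(Tng[, g], tr, left.open = TRUE)   # strictly below
    hi <- findInterval(Tng[, g], tr)                      # below or equal
    # midpoint of the tied block: reproduces the training fractional rank
    # exactly when a held-out cell coincides with a training cell
    Q[, g] <- (lo + (hi - lo) / 2) / n_tr
  }
  m <- rowMeans(Q)
  rng <- fit$unify_range
  t_out <- if (!is.null(rng) && diff(rng) > 0)
    pmin(pmax((m - rng[1]) / diff(rng), 0), 1) else m
  names(t_out) <- colnames(sub)
  vel <- rbf_velocity(fit$params, matrix(t_out, length(t_out), length(genes)))
  dimnames(vel) <- list(colnames(sub), genes)
  list(time = t_out, velocity = vel)
}
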