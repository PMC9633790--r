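#' Build a velocity dataset container
#'
#' Wraps spliced/unspliced count layers, cluster labels and an optional
#' embedding in a [SingleCellExperiment::SingleCellExperiment] (genes as
#' rows, cells as columns), the container all downstream steps operate on.
#'
#' @param spliced,unspliced gene x cell matrices (dense or sparse),
#'   nonnegative, same dimensions.
#' @param clusters optional per-cell labels (factor/character, length = cells).
#' @param embedding optional cell x d matrix of low-dimensional coordinates.
#' @return A `SingleCellExperiment` with assays `"spliced"` and `"unspliced"`.
#' @export
velocity_dataset <- function(spliced, unspliced, clusters = NULL,
                             embedding = NULL) {
  .assert(all(dim(spliced) == dim(unspliced)),
          "spliced and unspliced layers must share dimensions")
  .assert(min(spliced) >= 0 && min(unspliced) >= 0,
          "count layers must be nonnegative")
  if (is.null(rownames(spliced)))
    rownames(spliced) <- rownames(unspliced) <-
      sprintf("gene%d", seq_len(nrow(spliced)))
  if (is.null(colnames(spliced)))
    colnames(spliced) <- colnames(unspliced) <-
      sprintf("cell%d", seq_len(ncol(spliced)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(spliced = spliced, unspliced = unspliced))
  if (!is.null(clusters)) {
    .assert(length(clusters) == ncol(sce), "clusters must have one label per cell")
    sce$clusters <- factor(clusters)
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    .assert(nrow(embedding) == ncol(sce), "embedding must have one row per cell")
    SingleCellExperiment::reducedDim(sce, "embedding") <- embedding
  }
  sce
}

#' Filter lowly covered genes and size-normalize
#'
#' Removes genes detected (both layers simultaneously positive) in fewer than
#' `min_cells` cells, then scales each cell of each layer so its total
#' matches the median per-cell total of that layer. Set
#' `size_normalize = FALSE` when the input layers are already
#' depth-normalized (e.g. simulated on the normalized scale); the normalized
#' assays are then plain copies.
#'
#' @param sce a dataset from [velocity_dataset()].
#' @param min_cells minimum number of cells with joint u/s detection
#'   (default 20).
#' @param size_normalize logical; perform median-total scaling.
#' @return The dataset with assays `spliced_norm` and `unspliced_norm` added
#'   and low-coverage genes dropped.
#' @export
normalize_and_filter <- function(sce, min_cells = 20, size_normalize = TRUE) {
  s <- SummarizedExperiment::assay(sce, "spliced")
  u <- SummarizedExperiment::assay(sce, "unspliced")
  detected <- Matrix::rowSums((s > 0) & (u > 0))
  keep <- detected >= min_cells
  .assert(any(keep),
          "no gene is jointly detected in >= %d cells; lower min_cells", min_cells)
  sce <- sce[keep, ]
  s <- as.matrix(SummarizedExperiment::assay(sce, "spliced"))
  u <- as.matrix(SummarizedExperiment::assay(sce, "unspliced"))
  if (size_normalize) {
    norm1 <- function(x) {
      tot <- colSums(x)
      .assert(all(tot > 0), "a cell has zero total counts after filtering")
      sweep(x, 2, median(tot) / tot, "*")
    }
    s <- norm1(s); u <- norm1(u)
  }
  SummarizedExperiment::assay(sce, "spliced_norm") <- s
  SummarizedExperiment::assay(sce, "unspliced_norm") <- u
  sce
}

#' Select highly variable genes by binned dispersion
#'
#' Ranks genes by their normalized dispersion: dispersion = variance/mean of
#' the normalized spliced layer, z-scored within 20 quantile bins of the mean
#' so that highly expressed genes do not dominate. The classic
#' mean-binned-dispersion HVG criterion.
#'
#' @param sce dataset with a `spliced_norm` assay.
#' @param n_top number of genes to keep (default 2000).
#' @return The dataset with a logical `hvg` column in `rowData`.
#' @export
select_hvg <- function(sce, n_top = 2000) {
  s <- as.matrix(SummarizedExperiment::assay(sce, "spliced_norm"))
  mu <- rowMeans(s)
  v <- apply(s, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (n_top >= nrow(sce)) {
    warning("n_top >= number of genes; keeping all genes as HVGs")
    SummarizedExperiment::rowData(sce)$hvg <- rep(TRUE, nrow(sce))
    return(sce)
  }
  nb <- min(20L, max(1L, floor(nrow(sce) / 2)))
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  zs <- stats::ave(disp, bin, FUN = function(x) {
    s0 <- sd(x)
    if (!is.finite(s0) || s0 == 0) rep(0, length(x)) else (x - mean(x)) / s0
  })
  ord <- order(zs, disp, decreasing = TRUE)
  hvg <- logical(nrow(sce))
  hvg[ord[seq_len(n_top)]] <- TRUE
  SummarizedExperiment::rowData(sce)$hvg <- hvg
  sce
}

#' Compute KNN-smoothed first moments of the count layers
#'
#' PCA (on the log1p normalized spliced layer, HVGs only) followed by a
#' k-nearest-neighbor graph in PC space. `Mu` and `Ms` replace each cell's
#' unspliced/spliced value by the average over its neighborhood, stabilizing
#' the variance before model fitting. The neighborhood of size `n_neighbors`
#' includes the cell itself plus its `n_neighbors - 1` nearest neighbors, so
#' the graph is defined consistently for all downstream users (moments,
#' cluster-sparsity heuristic, velocity projection).
#'
#' @param sce dataset with normalized assays and an `hvg` mask.
#' @param n_pcs number of principal components (default 30).
#' @param n_neighbors neighborhood size including self (default 30).
#' @return Dataset with assays `Mu`, `Ms`, a `"PCA"` reducedDim and the
#'   neighbor index matrix in `metadata(sce)$knn` (first column = self).
#' @export
knn_moments <- function(sce, n_pcs = 30, n_neighbors = 30) {
  .assert(!is.null(SummarizedExperiment::rowData(sce)$hvg),
          "run select_hvg() before knn_moments()")
  n <- ncol(sce)
  if (n_neighbors > n) {
    warning(sprintf("n_neighbors (%d) exceeds cell count (%d); reducing",
                    n_neighbors, n))
    n_neighbors <- n
  }
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  X <- t(log1p(as.matrix(
    SummarizedExperiment::assay(sce, "spliced_norm")[hvg, , drop = FALSE])))
  k_pc <- min(n_pcs, ncol(X) - 1L, nrow(X) - 1L)
  pcs <- if (k_pc >= min(dim(X)) - 1L || min(dim(X)) < 100) {
    stats::prcomp(X, rank. = k_pc, center = TRUE, scale. = FALSE)$x
  } else {
    with_local_seed(0L,
      irlba::prcomp_irlba(X, n = k_pc, center = TRUE, scale. = FALSE)$x)
  }
  nb <- if (n_neighbors > 1) {
    BiocNeighbors::findKNN(pcs, k = n_neighbors - 1L)$index
  } else {
    matrix(integer(0), nrow = n, ncol = 0)
  }
  knn <- cbind(seq_len(n), nb)
  # sparse cell x cell averaging operator: column c holds 1/k on c's neighborhood
  W <- Matrix::sparseMatrix(i = as.vector(knn),
                            j = rep(seq_len(n), times = ncol(knn)),
                            x = 1 / ncol(knn), dims = c(n, n))
  Ms <- as.matrix(SummarizedExperiment::assay(sce, "spliced_norm") %*% W)
  Mu <- as.matrix(SummarizedExperiment::assay(sce, "unspliced_norm") %*% W)
  dimnames(Ms) <- dimnames(Mu) <- dimnames(sce)
  SummarizedExperiment::assay(sce, "Ms") <- Ms
  SummarizedExperiment::assay(sce, "Mu") <- Mu
  SingleCellExperiment::reducedDim(sce, "PCA") <- pcs
  S4Vectors::metadata(sce)$knn <- knn
  sce
}

#' Select genes informative for velocity fitting
#'
#' For each HVG, fits the zero-intercept steady-state regression of smoothed
#' unspliced on smoothed spliced values. Genes are kept when the slope
#' (the steady-state degradation ratio) exceeds `min_gamma`, the regression
#' R-squared exceeds `min_r2`, and the ratio of unspliced to spliced standard
#' deviations lies within `[sigma_lo, sigma_hi]` (guarding against capture
#' artifacts). Zero-variance genes are excluded.
#'
#' @param sce dataset with `Mu`/`Ms` assays.
#' @param min_gamma minimum regression slope (default 0.01).
#' @param min_r2 minimum coefficient of determination (default 0.01).
#' @param sigma_lo,sigma_hi admissible range of sd(u)/sd(s) (defaults 0.03, 3).
#' @return Dataset with `velocity_genes`, `gamma_ss`, `r2_ss`, `sigma_ratio`
#'   columns in `rowData`.
#' @export
select_velocity_genes <- function(sce, min_gamma = 0.01, min_r2 = 0.01,
                                  sigma_lo = 0.03, sigma_hi = 3) {
  rd <- SummarizedExperiment::rowData(sce)
  .assert(!is.null(rd$hvg), "run select_hvg() first")
  Ms <- as.matrix(SummarizedExperiment::assay(sce, "Ms"))
  Mu <- as.matrix(SummarizedExperiment::assay(sce, "Mu"))
  G <- nrow(sce)
  gam <- r2 <- ratio <- rep(NA_real_, G)
  for (g in which(rd$hvg)) {
    x <- Ms[g, ]; y <- Mu[g, ]
    sx <- sd(x); sy <- sd(y)
    if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) next
    sxx <- sum(x^2)
    if (sxx == 0) next
    gam[g] <- sum(x * y) / sxx
    sst <- sum((y - mean(y))^2)
    r2[g] <- if (sst > 0) 1 - sum((y - gam[g] * x)^2) / sst else NA_real_
    ratio[g] <- sy / sx
  }
  keep <- !is.na(gam) & !is.na(r2) & gam > min_gamma & r2 > min_r2 &
    ratio >= sigma_lo & ratio <= sigma_hi
  rd$velocity_genes <- keep
  rd$gamma_ss <- gam; rd$r2_ss <- r2; rd$sigma_ratio <- ratio
  SummarizedExperiment::rowData(sce) <- rd
  sce
}

#' Expand the velocity-gene set using an interim cell time
#'
#' Once a unified cell time is available, HVGs that were excluded by the
#' steady-state filters but whose smoothed spliced expression is well
#' explained by a linear regression on cell time (R-squared above
#' `r2_threshold`, the `AGENES_R2` configuration value) are added back to the
#' velocity-gene set.
#'
#' @param sce dataset with `velocity_genes` computed.
#' @param cell_time per-cell unified latent time (numeric vector). Passing a
#'   per-gene time matrix (independent mode) is a no-op with a warning.
#' @param r2_threshold minimum time-regression R-squared for inclusion.
#' @return Dataset with an expanded `velocity_genes` mask.
#' @export
amplify_velocity_genes <- function(sce, cell_time, r2_threshold) {
  if (is.matrix(cell_time)) {
    warning("unified cell time undefined in independent mode; gene set unchanged")
    return(sce)
  }
  .assert(length(cell_time) == ncol(sce), "cell_time must have one entry per cell")
  rd <- SummarizedExperiment::rowData(sce)
  .assert(!is.null(rd$velocity_genes), "run select_velocity_genes() first")
  Ms <- as.matrix(SummarizedExperiment::assay(sce, "Ms"))
  cand <- which(rd$hvg & !rd$velocity_genes)
  tc <- cell_time - mean(cell_time)
  stt <- sum(tc^2)
  added <- logical(length(cand))
  for (k in seq_along(cand)) {
    y <- Ms[cand[k], ]
    sst <- sum((y - mean(y))^2)
    if (sst == 0 || stt == 0) next
    beta <- sum(tc * (y - mean(y))) / stt
    r2 <- 1 - sum((y - mean(y) - beta * tc)^2) / sst
    added[k] <- r2 > r2_threshold
  }
  rd$velocity_genes[cand[added]] <- TRUE
  SummarizedExperiment::rowData(sce) <- rd
  sce
}
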