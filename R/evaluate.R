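#' Per-gene goodness of fit on the spliced layer
#'
#' Coefficient of determination of the fitted spliced mean at the assigned
#' times: `R^2 = 1 - MSE / Var(Ms)`, per gene. Focuses on spliced RNA only;
#' may be negative for poor fits. Zero-variance genes yield `NA`.
#'
#' @param params an [rbf_params].
#' @param t assigned times (vector or cells x genes matrix).
#' @param s_obs cells x genes matrix of smoothed spliced observations.
#' @return Named numeric vector of per-gene R-squared values.
#' @export
gene_r2 <- function(params, t, s_obs) {
  G <- nrow(params)
  s_obs <- time_matrix(s_obs, G)
  shat <- time_matrix(rbf_spliced(params, t), G)
  sse <- colSums((shat - s_obs)^2)
  sst <- colSums(sweep(s_obs, 2, colMeans(s_obs))^2)
  setNames(ifelse(sst > 0, 1 - sse / sst, NA_real_), rownames(params))
}

# cosine similarity rows of A against vector b (zero-safe)
.cos_rows <- function(A, b) {
  nb <- sqrt(sum(b^2))
  na <- sqrt(rowSums(A^2))
  d <- as.vector(A %*% b)
  out <- ifelse(na > 0 & nb > 0, d / (na * nb), 0)
  out
}

#' Project gene-space velocities onto the embedding
#'
#' For each cell, cosine similarities between its gene-space velocity and
#' the expression-difference vectors to its KNN neighbors are turned into
#' transition weights by an adaptive softmax (temperature = the cell's mean
#' absolute cosine, so weak signals are sharpened comparably to strong
#' ones). The uniform baseline is subtracted so that a zero velocity maps to
#' a zero embedding vector, and the weighted sum of embedding displacements
#' is returned as a unit direction per cell.
#'
#' @param sce dataset with `Ms`, a KNN graph and an `"embedding"` reducedDim.
#' @param fit a `velocity_fit` (or a cells x genes velocity matrix over
#'   `genes`).
#' @param genes genes to use; defaults to the fit's genes.
#' @return Cells x d matrix of unit velocity directions in the embedding
#'   (zero rows for cells with no velocity signal).
#' @export
project_velocity <- function(sce, fit, genes = NULL) {
  vel <- if (inherits(fit, "velocity_fit")) fit$velocity else fit
  if (is.null(genes))
    genes <- if (inherits(fit, "velocity_fit")) fit$genes else colnames(vel)
  emb <- SingleCellExperiment::reducedDim(sce, "embedding")
  knn <- S4Vectors::metadata(sce)$knn
  .assert(!is.null(knn), "no KNN graph; run knn_moments() first")
  Ms <- t(as.matrix(SummarizedExperiment::assay(sce, "Ms")[genes, , drop = FALSE]))
  n <- nrow(Ms)
  V <- matrix(0, n, ncol(emb), dimnames = list(colnames(sce), NULL))
  for (c in seq_len(n)) {
    nbs <- knn[c, -1]
    if (length(nbs) == 0) next
    dX <- Ms[nbs, , drop = FALSE] -
      matrix(Ms[c, ], length(nbs), ncol(Ms), byrow = TRUE)
    cosim <- .cos_rows(dX, vel[c, ])
    temp <- mean(abs(cosim))
    w <- if (temp > 0) exp(cosim / temp) else rep(1, length(cosim))
    w <- w / sum(w)
    dE <- emb[nbs, , drop = FALSE] -
      matrix(emb[c, ], length(nbs), ncol(emb), byrow = TRUE)
    v <- colSums((w - 1 / length(w)) * dE)
    nv <- sqrt(sum(v^2))
    if (nv > 0) V[c, ] <- v / nv
  }
  V
}

#' Cross-boundary direction correctness (CBDir)
#'
#' For a ground-truth transition A -> B, boundary cells are cells of the
#' source cluster A having KNN neighbors in the target cluster B. Each
#' boundary cell scores the mean cosine between its embedding velocity and
#' the displacement vectors toward its target-cluster neighbors; the pair
#' score averages over boundary cells. Scores lie in `[-1, 1]`; pairs
#' without boundary cells are reported as `NA`.
#'
#' @param v cells x d embedding velocity matrix (from [project_velocity()]).
#' @param x cells x d embedding coordinates.
#' @param clusters per-cell labels.
#' @param transitions data frame with columns `source`, `target`.
#' @param knn neighbor index matrix (first column self).
#' @return List: `per_pair` (named scores), `per_cell` (boundary-cell
#'   scores), `n_boundary` (cells per pair), `mean` (unweighted pair mean),
#'   `mean_weighted` (boundary-cell-count weighted mean).
#' @export
cbdir <- function(v, x, clusters, transitions, knn) {
  clusters <- as.factor(clusters)
  per_pair <- numeric(nrow(transitions))
  nb_count <- integer(nrow(transitions))
  cell_scores <- list()
  for (p in seq_len(nrow(transitions))) {
    src <- as.character(transitions$source[p])
    tgt <- as.character(transitions$target[p])
    cand <- which(clusters == src)
    scores <- c()
    for (c in cand) {
      nbs <- knn[c, -1]
      tnb <- nbs[clusters[nbs] == tgt]
      if (length(tnb) == 0) next
      dX <- x[tnb, , drop = FALSE] -
        matrix(x[c, ], length(tnb), ncol(x), byrow = TRUE)
      scores <- c(scores, mean(.cos_rows(dX, v[c, ])))
    }
    per_pair[p] <- if (length(scores)) mean(scores) else NA_real_
    nb_count[p] <- length(scores)
    cell_scores[[p]] <- scores
  }
  names(per_pair) <- paste(transitions$source, transitions$target, sep = "->")
  ok <- !is.na(per_pair)
  list(per_pair = per_pair, per_cell = cell_scores, n_boundary = nb_count,
       mean = mean(per_pair[ok]),
       mean_weighted = if (any(ok))
         sum(per_pair[ok] * nb_count[ok]) / sum(nb_count[ok]) else NA_real_)
}

#' In-cluster velocity coherence (ICCoh)
#'
#' Mean cosine similarity of each cell's embedding velocity with those of
#' its same-cluster neighbors; high values indicate a smooth field within
#' clusters. Note the metric is direction-blind in aggregate: globally
#' negating all velocities leaves it unchanged. Cells with zero-norm
#' velocity are skipped.
#'
#' @inheritParams cbdir
#' @return List: `per_cell`, `per_cluster` (means), `mean`.
#' @export
iccoh <- function(v, clusters, knn) {
  clusters <- as.factor(clusters)
  n <- nrow(v)
  per_cell <- rep(NA_real_, n)
  vn <- sqrt(rowSums(v^2))
  for (c in seq_len(n)) {
    if (vn[c] == 0) next
    nbs <- knn[c, -1]
    nbs <- nbs[clusters[nbs] == clusters[c] & vn[nbs] > 0]
    if (length(nbs) == 0) next
    per_cell[c] <- mean(.cos_rows(v[nbs, , drop = FALSE], v[c, ]))
  }
  per_cluster <- tapply(per_cell, clusters, mean, na.rm = TRUE)
  list(per_cell = per_cell, per_cluster = per_cluster,
       mean = mean(per_cell, na.rm = TRUE))
}

#' Full evaluation report
#'
#' Projects velocities onto the embedding and computes the per-gene fit
#' R-squared, CBDir against the supplied ground-truth transitions, and
#' ICCoh.
#'
#' @param sce preprocessed dataset with embedding and KNN graph.
#' @param fit a `velocity_fit`.
#' @param transitions data frame (`source`, `target`) of ground-truth
#'   cluster transitions, or path to a two-column TSV/JSON file.
#' @return A list of class `eval_report`.
#' @export
evaluate_velocity <- function(sce, fit, transitions) {
  if (is.character(transitions)) transitions <- read_transitions(transitions)
  v <- project_velocity(sce, fit)
  x <- SingleCellExperiment::reducedDim(sce, "embedding")
  knn <- S4Vectors::metadata(sce)$knn
  cb <- cbdir(v, x, sce$clusters, transitions, knn)
  ic <- iccoh(v, sce$clusters, knn)
  structure(list(gene_r2 = fit$gene_r2, cbdir = cb, iccoh = ic,
                 transitions = transitions, v_embedding = v),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: CBDir mean %.3f (weighted %.3f), ICCoh mean %.3f\n",
              x$cbdir$mean, x$cbdir$mean_weighted, x$iccoh$mean))
  print(round(x$cbdir$per_pair, 3))
  invisible(x)
}

#' Read ground-truth transitions from TSV or JSON
#' @param path two-column TSV (source, target; header optional) or a JSON
#'   array of `{source, target}` objects.
#' @return Data frame with columns `source`, `target`.
#' @export
read_transitions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(df[1, 1])), "source")) df <- df[-1, ]
    colnames(df)[1:2] <- c("source", "target")
  }
  .assert(all(c("source", "target") %in% colnames(df)),
          "transitions file needs 'source' and 'target' columns")
  df[, c("source", "target")]
}
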