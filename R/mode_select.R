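#' Bundled cell-cycle gene lists
#'
#' Returns the packaged S-phase and G2M-phase marker symbol lists (one symbol
#' per line, human gene symbols; widely used for cycle scoring). Users can
#' point to their own files to override.
#'
#' @param s_file,g2m_file optional paths to replacement lists.
#' @return List with character vectors `s` and `g2m`.
#' @export
cycle_gene_lists <- function(s_file = NULL, g2m_file = NULL) {
  if (is.null(s_file))
    s_file <- system.file("extdata", "s_genes.txt", package = "rbfvelo")
  if (is.null(g2m_file))
    g2m_file <- system.file("extdata", "g2m_genes.txt", package = "rbfvelo")
  list(s = readLines(s_file), g2m = readLines(g2m_file))
}

#' Count cell-cycle genes among the highly variable genes
#'
#' Cycle-driven datasets are flagged by an excess of S/G2M marker genes among
#' the HVGs, evaluated after HVG selection. Matching is case-insensitive on
#' gene symbols.
#'
#' @param sce dataset with an `hvg` mask.
#' @param s_genes,g2m_genes character vectors of marker symbols.
#' @return List with `count_s` and `count_g2m`.
#' @export
count_cycle_hvgs <- function(sce, s_genes, g2m_genes) {
  .assert(length(s_genes) > 0 && length(g2m_genes) > 0,
          "empty cycle gene list; cannot assess cycle content")
  hvg <- SummarizedExperiment::rowData(sce)$hvg
  .assert(!is.null(hvg), "run select_hvg() first")
  hv <- toupper(rownames(sce)[hvg])
  list(count_s = sum(toupper(s_genes) %in% hv),
       count_g2m = sum(toupper(g2m_genes) %in% hv))
}

#' Detect sparse (self-contained) clusters
#'
#' A cluster is sparse when, averaged over its member cells, the fraction of
#' KNN neighbors sharing the cell's cluster label exceeds `purity`, i.e. the
#' cluster sits detached from the rest of the manifold.
#'
#' @param sce dataset with a KNN graph (from [knn_moments()]) and `clusters`.
#' @param purity neighborhood-purity threshold (default 0.95).
#' @return Character vector of sparse cluster labels (possibly empty).
#' @export
detect_sparse_clusters <- function(sce, purity = 0.95) {
  knn <- S4Vectors::metadata(sce)$knn
  .assert(!is.null(knn), "no KNN graph; run knn_moments() first")
  cl <- sce$clusters
  .assert(!is.null(cl), "no cluster labels in the dataset")
  if (nlevels(cl) < 2) return(character(0))
  nb <- knn[, -1, drop = FALSE]  # exclude self
  same <- matrix(as.integer(cl)[nb] == rep(as.integer(cl), times = ncol(nb)),
                 nrow = nrow(nb))
  frac <- rowMeans(same)
  per_cluster <- tapply(frac, cl, mean)
  names(per_cluster)[!is.na(per_cluster) & per_cluster > purity]
}

#' Recommend unified vs independent fitting mode
#'
#' Independent mode is suggested when either trigger fires: (i) the number of
#' S-phase or G2M-phase marker genes among the HVGs exceeds `cycle_frac` of
#' the respective list (cell-cycle signal present), or (ii) strictly more
#' than `n_clusters_min` clusters are sparse at the given neighborhood
#' purity. Otherwise the default unified-time mode is recommended. The mode
#' remains a user hyper-parameter; this is a heuristic aid.
#'
#' @param sce dataset with HVGs, KNN graph and cluster labels.
#' @param s_genes,g2m_genes cycle marker lists; defaults to the packaged
#'   lists.
#' @param cycle_frac fraction of a list that must be highly variable to
#'   trigger (default 0.5).
#' @param n_clusters_min sparse-cluster count that must be exceeded to
#'   trigger (default 2).
#' @param purity neighborhood purity defining sparse clusters (default 0.95).
#' @return A list of class `mode_recommendation`.
#' @export
choose_mode <- function(sce, s_genes = NULL, g2m_genes = NULL,
                        cycle_frac = 0.5, n_clusters_min = 2, purity = 0.95) {
  if (is.null(s_genes) || is.null(g2m_genes)) {
    lists <- cycle_gene_lists()
    if (is.null(s_genes)) s_genes <- lists$s
    if (is.null(g2m_genes)) g2m_genes <- lists$g2m
  }
  counts <- count_cycle_hvgs(sce, s_genes, g2m_genes)
  cycle_trigger <- counts$count_s > cycle_frac * length(s_genes) ||
    counts$count_g2m > cycle_frac * length(g2m_genes)
  sparse <- if (!is.null(sce$clusters) &&
                !is.null(S4Vectors::metadata(sce)$knn))
    detect_sparse_clusters(sce, purity) else character(0)
  sparse_trigger <- length(sparse) > n_clusters_min
  structure(list(mode = if (cycle_trigger || sparse_trigger) "independent"
                        else "unified",
                 n_cycle_hvgs_S = counts$count_s,
                 n_cycle_hvgs_G2M = counts$count_g2m,
                 cycle_trigger = cycle_trigger,
                 sparse_clusters = sparse,
                 sparse_trigger = sparse_trigger,
                 thresholds = list(cycle_frac = cycle_frac,
                                   n_clusters_min = n_clusters_min,
                                   purity = purity)),
            class = "mode_recommendation")
}

#' @export
print.mode_recommendation <- function(x, ...) {
  cat(sprintf("recommended mode: %s\n", x$mode))
  cat(sprintf("  cycle HVGs: S=%d G2M=%d (trigger: %s)\n", x$n_cycle_hvgs_S,
              x$n_cycle_hvgs_G2M, x$cycle_trigger))
  cat(sprintf("  sparse clusters: %s (trigger: %s)\n",
              if (length(x$sparse_clusters)) paste(x$sparse_clusters,
                                                   collapse = ", ") else "none",
              x$sparse_trigger))
  invisible(x)
}
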