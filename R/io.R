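# Container reading/writing. The native on-disk container is a plain-text
# directory of MatrixMarket triplets plus TSV sidecars; h5ad and loom files
# with spliced/unspliced layers are read via rhdf5.

#' Read a velocity dataset from disk
#'
#' Dispatches on the input: a directory is read as an MTX-triplet container
#' (`spliced.mtx`, `unspliced.mtx`, `genes.tsv`, `cells.tsv`, optional
#' `embedding.tsv`), a `.h5ad` file as an AnnData container with
#' `layers/spliced` and `layers/unspliced`, a `.loom` file as a loom
#' container with the same layer names.
#'
#' @param path input directory or file.
#' @param cluster_col name of the cell metadata column holding cluster
#'   labels (default `"clusters"`).
#' @param embedding_key for h5ad, the `obsm` key of the embedding; the first
#'   available of `X_umap`, `X_tsne`, `X_embedding` by default.
#' @return A `SingleCellExperiment` as built by [velocity_dataset()].
#' @export
read_velocity_dataset <- function(path, cluster_col = "clusters",
                                  embedding_key = NULL) {
  if (dir.exists(path)) return(read_mtx_dataset(path, cluster_col))
  .assert(file.exists(path), "input '%s' does not exist", path)
  if (grepl("\\.h5ad$", path, ignore.case = TRUE))
    return(read_h5ad_dataset(path, cluster_col, embedding_key))
  if (grepl("\\.loom$", path, ignore.case = TRUE))
    return(read_loom_dataset(path, cluster_col))
  stop("unrecognized container: expected a directory, .h5ad or .loom", call. = FALSE)
}

# full-precision MatrixMarket writer (triplet, general real)
write_mtx <- function(m, path) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)), con)
  if (length(m@x))
    writeLines(sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, m@x), con)
  invisible(path)
}

read_mtx_dataset <- function(dir, cluster_col = "clusters") {
  need <- file.path(dir, c("spliced.mtx", "unspliced.mtx", "genes.tsv",
                           "cells.tsv"))
  missing <- need[!file.exists(need)]
  .assert(length(missing) == 0, "missing container files: %s",
          paste(basename(missing), collapse = ", "))
  s <- as.matrix(Matrix::readMM(need[1]))
  u <- as.matrix(Matrix::readMM(need[2]))
  genes <- read.delim(need[3], stringsAsFactors = FALSE)
  cells <- read.delim(need[4], stringsAsFactors = FALSE)
  rownames(s) <- rownames(u) <- genes[[1]]
  colnames(s) <- colnames(u) <- cells[[1]]
  emb <- NULL
  ef <- file.path(dir, "embedding.tsv")
  if (file.exists(ef)) emb <- as.matrix(read.delim(ef, row.names = 1))
  cl <- if (cluster_col %in% colnames(cells)) cells[[cluster_col]] else NULL
  sce <- velocity_dataset(s, u, clusters = cl, embedding = emb)
  for (col in setdiff(colnames(cells), c(colnames(cells)[1], cluster_col)))
    SummarizedExperiment::colData(sce)[[col]] <- cells[[col]]
  sce
}

#' Write a velocity dataset (and fit results) as an MTX container
#'
#' Writes `spliced.mtx`/`unspliced.mtx` at full precision, gene and cell
#' tables as TSV, the embedding if present, and — when a fit is supplied —
#' the velocity layer, per-cell latent time (cells.tsv column), per-gene
#' peak time/class/R-squared (genes.tsv columns) and a JSON run manifest.
#'
#' @param sce the dataset.
#' @param dir output directory (created if needed).
#' @param fit optional `velocity_fit` to serialize alongside.
#' @param manifest optional list written as `manifest.json`.
#' @return The output directory, invisibly.
#' @export
write_velocity_dataset <- function(sce, dir, fit = NULL, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx(SummarizedExperiment::assay(sce, "spliced"),
            file.path(dir, "spliced.mtx"))
  write_mtx(SummarizedExperiment::assay(sce, "unspliced"),
            file.path(dir, "unspliced.mtx"))
  genes <- data.frame(gene = rownames(sce))
  rd <- SummarizedExperiment::rowData(sce)
  for (col in c("hvg", "velocity_genes", "gamma_ss", "r2_ss", "sigma_ratio"))
    if (!is.null(rd[[col]])) genes[[col]] <- rd[[col]]
  cells <- data.frame(cell = colnames(sce))
  if (!is.null(sce$clusters)) cells$clusters <- as.character(sce$clusters)
  if (!is.null(fit)) {
    idx <- match(genes$gene, fit$genes)
    genes$fit_tau <- fit$params$tau[idx]
    genes$fit_class <- as.character(fit$gene_class)[idx]
    genes$fit_r2 <- fit$gene_r2[idx]
    if (fit$mode == "unified") {
      cells$latent_time <- fit$time[match(cells$cell, names(fit$time))]
    } else {
      write_mtx(t(fit$time), file.path(dir, "latent_time_by_gene.mtx"))
    }
    vel <- matrix(NA_real_, nrow(sce), ncol(sce),
                  dimnames = dimnames(sce))
    vel[fit$genes, fit$cells] <- t(fit$velocity)
    vel[is.na(vel)] <- 0
    write_mtx(vel, file.path(dir, "velocity.mtx"))
  }
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if ("embedding" %in% SingleCellExperiment::reducedDimNames(sce)) {
    emb <- SingleCellExperiment::reducedDim(sce, "embedding")
    emb_chr <- apply(emb, 2, function(x) sprintf("%.17g", x))
    write.table(data.frame(cell = colnames(sce), emb_chr),
                file.path(dir, "embedding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(manifest))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# --- h5ad ------------------------------------------------------------------

# read a (possibly sparse-encoded) h5ad matrix as genes x cells
read_h5ad_matrix <- function(file, name, n_obs, n_var) {
  attrs <- tryCatch(rhdf5::h5readAttributes(file, name), error = function(e) list())
  enc <- attrs[["encoding-type"]]
  if (!is.null(enc) && enc %in% c("csr_matrix", "csc_matrix")) {
    data <- as.numeric(rhdf5::h5read(file, paste0(name, "/data")))
    indices <- as.integer(rhdf5::h5read(file, paste0(name, "/indices")))
    indptr <- as.integer(rhdf5::h5read(file, paste0(name, "/indptr")))
    shape <- as.integer(attrs[["shape"]])  # (n_obs, n_var)
    if (enc == "csr_matrix") {
      # CSR over obs x var == CSC over var x obs: genes x cells directly
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[2], shape[1]))
    } else {
      m <- Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                          x = data,
                                          dims = c(shape[1], shape[2])))
    }
    return(as.matrix(m))
  }
  x <- rhdf5::h5read(file, name)
  # dense (n_obs, n_var) datasets arrive transposed in R: var x obs
  if (nrow(x) == n_var && ncol(x) == n_obs) x
  else if (nrow(x) == n_obs && ncol(x) == n_var) t(x)
  else stop(sprintf("layer '%s' has unexpected shape %d x %d", name,
                    nrow(x), ncol(x)), call. = FALSE)
}

# decode an h5ad obs/var column (plain array or categorical group)
read_h5ad_column <- function(file, name) {
  attrs <- tryCatch(rhdf5::h5readAttributes(file, name), error = function(e) list())
  if (identical(attrs[["encoding-type"]], "categorical")) {
    codes <- as.integer(rhdf5::h5read(file, paste0(name, "/codes")))
    cats <- as.character(rhdf5::h5read(file, paste0(name, "/categories")))
    out <- rep(NA_character_, length(codes))
    out[codes >= 0] <- cats[codes[codes >= 0] + 1L]
    return(out)
  }
  as.vector(rhdf5::h5read(file, name))
}

read_h5ad_dataset <- function(path, cluster_col = "clusters",
                              embedding_key = NULL) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  paths <- paste(sub("^/$", "", ls$group), ls$name, sep = "/")
  .assert(all(c("/layers/spliced", "/layers/unspliced") %in% paths),
          "h5ad file lacks layers/spliced and layers/unspliced")
  obs_attr <- rhdf5::h5readAttributes(path, "obs")
  var_attr <- rhdf5::h5readAttributes(path, "var")
  obs_index <- as.character(rhdf5::h5read(
    path, paste0("obs/", obs_attr[["_index"]] %||% "_index")))
  var_index <- as.character(rhdf5::h5read(
    path, paste0("var/", var_attr[["_index"]] %||% "_index")))
  n_obs <- length(obs_index); n_var <- length(var_index)
  s <- read_h5ad_matrix(path, "/layers/spliced", n_obs, n_var)
  u <- read_h5ad_matrix(path, "/layers/unspliced", n_obs, n_var)
  rownames(s) <- rownames(u) <- var_index
  colnames(s) <- colnames(u) <- obs_index
  cl <- if (paste0("/obs/", cluster_col) %in% paths)
    read_h5ad_column(path, paste0("obs/", cluster_col)) else NULL
  emb <- NULL
  keys <- if (is.null(embedding_key))
    c("X_umap", "X_tsne", "X_embedding") else embedding_key
  for (k in keys) {
    if (paste0("/obsm/", k) %in% paths) {
      emb <- t(rhdf5::h5read(path, paste0("obsm/", k)))
      break
    }
  }
  velocity_dataset(s, u, clusters = cl, embedding = emb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- loom ------------------------------------------------------------------

read_loom_dataset <- function(path, cluster_col = "clusters") {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  paths <- paste(sub("^/$", "", ls$group), ls$name, sep = "/")
  .assert(all(c("/layers/spliced", "/layers/unspliced") %in% paths),
          "loom file lacks layers/spliced and layers/unspliced")
  # loom stores (genes, cells) row-major; rhdf5 returns cells x genes
  s <- t(rhdf5::h5read(path, "layers/spliced"))
  u <- t(rhdf5::h5read(path, "layers/unspliced"))
  gene_key <- intersect(c("/row_attrs/Gene", "/row_attrs/var_names"), paths)
  cell_key <- intersect(c("/col_attrs/CellID", "/col_attrs/obs_names"), paths)
  if (length(gene_key))
    rownames(s) <- rownames(u) <- as.character(rhdf5::h5read(path, gene_key[1]))
  if (length(cell_key))
    colnames(s) <- colnames(u) <- as.character(rhdf5::h5read(path, cell_key[1]))
  cl <- if (paste0("/col_attrs/", cluster_col) %in% paths)
    as.character(rhdf5::h5read(path, paste0("col_attrs/", cluster_col))) else NULL
  velocity_dataset(s, u, clusters = cl)
}
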