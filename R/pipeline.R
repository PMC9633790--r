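#' Run the full velocity pipeline
#'
#' Reads (or accepts) a dataset, preprocesses it, optionally recommends a
#' fitting mode, fits the RBF model, optionally expands the velocity-gene
#' set with the interim cell time, predicts held-out cells when
#' down-sampling is requested, evaluates trajectory direction when
#' ground-truth transitions are given, and writes an output container plus
#' run manifest.
#'
#' @param input path to a container (MTX directory / h5ad / loom) or a
#'   `SingleCellExperiment` from [velocity_dataset()] / [simulate_dataset()].
#' @param output_dir optional output directory for the result container.
#' @param mode `"auto"` (use [choose_mode()] when labels allow, else
#'   unified), `"unified"` or `"independent"`.
#' @param min_cells,n_top_genes,n_neighbors,n_pcs preprocessing parameters.
#' @param size_normalize set `FALSE` for layers already depth-normalized.
#' @param agenes_r2 optional R-squared threshold for mid-fit velocity-gene
#'   expansion (the `AGENES_R2` configuration value); `NULL` disables.
#' @param downsample_frac optional (0, 1] fraction for stratified
#'   down-sampling; held-out cells get predicted times/velocities.
#' @param min_per_cluster minimum cells per cluster kept when down-sampling.
#' @param transitions optional ground-truth transitions (data frame or file
#'   path) enabling evaluation.
#' @param config optional [fit_config()]; built from `conv_tol`, `mode` and
#'   `seed` otherwise.
#' @param conv_tol convergence tolerance when `config` is `NULL`.
#' @param max_iters iteration cap when `config` is `NULL`.
#' @param seed seed for all stochastic steps.
#' @param verbose print progress lines.
#' @return List of class `velocity_run`: `sce` (with velocity assay,
#'   latent time and gene annotations attached), `fit`, `mode_rec`,
#'   `eval`, `heldout`, `manifest`.
#' @export
run_pipeline <- function(input, output_dir = NULL, mode = c("auto", "unified",
                                                            "independent"),
                         min_cells = 20, n_top_genes = 2000, n_neighbors = 30,
                         n_pcs = 30, size_normalize = TRUE, agenes_r2 = NULL,
                         downsample_frac = NULL, min_per_cluster = 50,
                         transitions = NULL, config = NULL, conv_tol = 1e-4,
                         max_iters = 12000, seed = 1L, verbose = TRUE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  sce <- if (is.character(input)) read_velocity_dataset(input) else input
  .assert(all(c("spliced", "unspliced") %in%
                SummarizedExperiment::assayNames(sce)),
          "input must carry 'spliced' and 'unspliced' assays")

  say("preprocess: %d genes x %d cells", nrow(sce), ncol(sce))
  sce <- normalize_and_filter(sce, min_cells = min_cells,
                              size_normalize = size_normalize)
  sce <- select_hvg(sce, n_top = n_top_genes)
  sce <- knn_moments(sce, n_pcs = n_pcs, n_neighbors = n_neighbors)
  sce <- select_velocity_genes(sce)
  say("velocity genes: %d of %d HVGs",
      sum(SummarizedExperiment::rowData(sce)$velocity_genes),
      sum(SummarizedExperiment::rowData(sce)$hvg))

  mode_rec <- NULL
  if (mode == "auto") {
    mode_rec <- tryCatch(choose_mode(sce), error = function(e) NULL)
    mode <- if (is.null(mode_rec)) "unified" else mode_rec$mode
    say("mode: %s (%s)", mode,
        if (is.null(mode_rec)) "heuristic unavailable, default" else "heuristic")
  }
  if (is.null(config))
    config <- fit_config(mode = mode, conv_tol = conv_tol,
                         max_iters = max_iters, seed = seed)

  train <- seq_len(ncol(sce)); heldout_idx <- integer(0)
  if (!is.null(downsample_frac) && downsample_frac < 1) {
    split <- stratified_downsample(sce, downsample_frac,
                                   min_per_cluster = min_per_cluster,
                                   seed = seed)
    train <- split$train; heldout_idx <- split$heldout
    say("down-sampling: %d train / %d held-out cells", length(train),
        length(heldout_idx))
  }

  fit <- fit_velocity(sce[, train], config)
  say("fit: %d iterations (%s)", fit$iterations,
      if (fit$converged) "converged" else "max_iters")

  if (!is.null(agenes_r2) && config$mode == "unified") {
    before <- sum(SummarizedExperiment::rowData(sce)$velocity_genes)
    tt <- setNames(rep(NA_real_, ncol(sce)), colnames(sce))
    tt[train] <- fit$time
    sce2 <- amplify_velocity_genes(sce[, train], fit$time, agenes_r2)
    added <- setdiff(
      rownames(sce2)[SummarizedExperiment::rowData(sce2)$velocity_genes],
      fit$genes)
    if (length(added) > 0) {
      rd <- SummarizedExperiment::rowData(sce)
      rd$velocity_genes[rownames(sce) %in% added] <- TRUE
      SummarizedExperiment::rowData(sce) <- rd
      say("gene expansion: +%d genes (AGENES_R2 = %g); refitting", length(added),
          agenes_r2)
      fit <- fit_velocity(sce[, train], config)
    } else say("gene expansion: no genes added (AGENES_R2 = %g)", agenes_r2)
  }

  heldout <- NULL
  if (length(heldout_idx) > 0) {
    heldout <- predict_heldout(fit, sce, heldout_idx)
    say("held-out prediction: %d cells", length(heldout_idx))
  }

  # attach results to the container
  vel <- matrix(0, nrow(sce), ncol(sce), dimnames = dimnames(sce))
  vel[fit$genes, fit$cells] <- t(fit$velocity)
  if (!is.null(heldout) && fit$mode == "unified")
    vel[fit$genes, heldout_idx] <- t(heldout$velocity)
  SummarizedExperiment::assay(sce, "velocity") <- vel
  if (fit$mode == "unified") {
    lt <- rep(NA_real_, ncol(sce))
    lt[train] <- fit$time
    if (!is.null(heldout)) lt[heldout_idx] <- heldout$time
    sce$latent_time <- lt
  }
  rd <- SummarizedExperiment::rowData(sce)
  idx <- match(rownames(sce), fit$genes)
  rd$fit_tau <- fit$params$tau[idx]
  rd$fit_class <- as.character(fit$gene_class)[idx]
  rd$fit_r2 <- fit$gene_r2[idx]
  SummarizedExperiment::rowData(sce) <- rd

  eval <- NULL
  if (!is.null(transitions) &&
      "embedding" %in% SingleCellExperiment::reducedDimNames(sce)) {
    eval <- evaluate_velocity(sce[, train], fit, transitions)
    say("evaluation: CBDir mean %.3f, ICCoh mean %.3f", eval$cbdir$mean,
        eval$iccoh$mean)
  }

  manifest <- list(
    package = "rbfvelo",
    version = as.character(utils::packageVersion("rbfvelo")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed, mode = config$mode,
    n_cells = ncol(sce), n_genes = nrow(sce),
    n_velocity_genes = length(fit$genes),
    parameters = list(min_cells = min_cells, n_top_genes = n_top_genes,
                      n_neighbors = n_neighbors, n_pcs = n_pcs,
                      size_normalize = size_normalize,
                      agenes_r2 = agenes_r2,
                      downsample_frac = downsample_frac,
                      min_per_cluster = min_per_cluster,
                      conv_tol = config$conv_tol,
                      max_iters = config$max_iters,
                      grid_size = config$grid_size,
                      reassign_every = config$reassign_every,
                      learning_rate = config$learning_rate,
                      denoise_dims = config$denoise_dims),
    iterations = fit$iterations, converged = fit$converged)

  if (!is.null(output_dir)) {
    write_velocity_dataset(sce, output_dir, fit = fit, manifest = manifest)
    if (!is.null(eval)) {
      jsonlite::write_json(
        list(cbdir_per_pair = as.list(eval$cbdir$per_pair),
             cbdir_mean = eval$cbdir$mean,
             cbdir_mean_weighted = eval$cbdir$mean_weighted,
             iccoh_mean = eval$iccoh$mean,
             iccoh_per_cluster = as.list(eval$iccoh$per_cluster)),
        file.path(output_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA)
    }
    say("wrote results to %s", output_dir)
  }

  structure(list(sce = sce, fit = fit, mode_rec = mode_rec, eval = eval,
                 heldout = heldout, manifest = manifest),
            class = "velocity_run")
}

#' Load a pipeline configuration file
#'
#' YAML (or JSON) file whose keys mirror the [run_pipeline()] arguments;
#' values given on the command line take precedence over the file, which
#' takes precedence over built-in defaults.
#'
#' @param path YAML/JSON config file.
#' @return Named list of arguments.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  .assert(is.list(cfg), "config file must parse to a key-value mapping")
  cfg
}
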