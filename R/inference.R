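#' Configuration of the alternating fit
#'
#' @param max_iters maximum number of gradient iterations (default 12000;
#'   convergence usually stops the fit much earlier).
#' @param reassign_every gradient iterations between grid-search time
#'   re-assignments (default 10).
#' @param grid_size number of candidate time points in `[0, 1]` for the
#'   re-assignment grid search (default 100).
#' @param learning_rate Adam step size (default 0.01).
#' @param conv_tol convergence threshold on the proportional change of the
#'   total loss (default 1e-4).
#' @param mode `"unified"` (one shared latent time per cell, the default) or
#'   `"independent"` (per-gene cell times with `(tau, o, i)` fixed at
#'   `(0.5, 0, 0)`).
#' @param denoise_dims rank of the SVD denoising of the per-gene time matrix
#'   before averaging (default 50; 0 disables; only applied when the number
#'   of fitted genes exceeds 100).
#' @param seed integer governing all stochastic components of a fit.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iters = 12000, reassign_every = 10, grid_size = 100,
                       learning_rate = 0.01, conv_tol = 1e-4,
                       mode = c("unified", "independent"), denoise_dims = 50,
                       seed = 1L) {
  mode <- match.arg(mode)
  .assert(conv_tol > 0, "conv_tol must be > 0")
  .assert(grid_size >= 2, "grid_size must be >= 2")
  .assert(reassign_every >= 1, "reassign_every must be >= 1")
  structure(list(max_iters = as.integer(max_iters),
                 reassign_every = as.integer(reassign_every),
                 grid_size = as.integer(grid_size),
                 learning_rate = learning_rate, conv_tol = conv_tol,
                 mode = mode, denoise_dims = as.integer(denoise_dims),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# internal theta layout: rows lh, la, tau, lgamma, lbeta, lb, o, i
params_to_theta <- function(p) {
  rbind(log(p$h), log(p$a), p$tau, log(p$gamma), log(p$beta), log(p$b),
        p$o, p$i)
}

theta_to_params <- function(th, genes = NULL) {
  rbf_params(h = exp(th[1, ]), a = exp(th[2, ]), tau = th[3, ],
             gamma = exp(th[4, ]), beta = exp(th[5, ]), b = exp(th[6, ]),
             o = th[7, ], i = th[8, ], gene = genes)
}

# Pull cells x genes smoothed moment matrices for the fitted genes.
moment_matrices <- function(sce, genes) {
  list(Mu = t(as.matrix(SummarizedExperiment::assay(sce, "Mu")[genes, , drop = FALSE])),
       Ms = t(as.matrix(SummarizedExperiment::assay(sce, "Ms")[genes, , drop = FALSE])))
}

#' Initialize gene parameters and cell times
#'
#' Peak times start at the non-informative value `tau = 0.5` (every gene
#' assumed to traverse induction and repression), amplitudes and offsets come
#' from per-gene data ranges (`h ~ max - min` of smoothed spliced, `o`, `i`
#' the layer minima), rates start at 1, and the residual precision `b` at its
#' closed-form optimum given the initial residuals. The initial cell time is
#' the fractional rank of each cell's total smoothed spliced signal, a cheap
#' monotone proxy the periodic re-assignment then corrects. In independent
#' mode `(tau, o, i)` start (and stay) at `(0.5, 0, 0)`.
#'
#' @param sce preprocessed dataset with velocity genes selected.
#' @param mode `"unified"` or `"independent"`.
#' @param genes optional character/logical/integer gene selection; defaults
#'   to the `velocity_genes` mask.
#' @return List with `params` (an [rbf_params]) and `time` (per-cell vector).
#' @export
init_params <- function(sce, mode = c("unified", "independent"), genes = NULL) {
  mode <- match.arg(mode)
  if (is.null(genes)) {
    vg <- SummarizedExperiment::rowData(sce)$velocity_genes
    .assert(!is.null(vg), "no velocity_genes mask; run select_velocity_genes()")
    genes <- rownames(sce)[vg]
  }
  .assert(length(genes) > 0, "empty gene selection")
  mm <- moment_matrices(sce, genes)
  n <- nrow(mm$Ms)
  h <- pmax(apply(mm$Ms, 2, max) - apply(mm$Ms, 2, min), 1e-6)
  constant <- h <= 1e-6
  o <- apply(mm$Ms, 2, min)
  i <- apply(mm$Mu, 2, min)
  if (mode == "independent") { o[] <- 0; i[] <- 0 }
  tt <- frac_rank(rowSums(mm$Ms))
  p <- rbf_params(h = h, a = rep(1, length(genes)), tau = rep(0.5, length(genes)),
                  gamma = rep(1, length(genes)), beta = rep(1, length(genes)),
                  b = rep(1, length(genes)), o = o, i = i, gene = genes)
  D <- colSums((rbf_unspliced(p, tt) - mm$Mu)^2) +
       colSums((rbf_spliced(p, tt) - mm$Ms)^2)
  p$b <- pmin(pmax(sqrt(1 / (2 * pi * pmax(D, 1e-12))), 1e-6), 1e6)
  attr(p, "constant_genes") <- genes[constant]
  list(params = p, time = tt)
}

#' One or more Adam updates of the gene parameters
#'
#' Runs `n_steps` Adam iterations of all gene parameters against the summed
#' negative log-likelihood with the cell times held fixed. Positivity of
#' `(h, a, gamma, beta, b)` is maintained by optimizing on the log scale.
#' The optimizer state is carried in/out so alternating schedules preserve
#' momentum across time re-assignments.
#'
#' @param params an [rbf_params].
#' @param u_obs,s_obs cells x genes observation matrices.
#' @param t cell times (vector or matrix).
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @param learning_rate,n_steps Adam step size and number of updates.
#' @param fix_toi freeze `(tau, o, i)` (independent mode).
#' @return List with updated `params`, `state`, and the per-step `loss` trace
#'   (loss evaluated before each update).
#' @export
gradient_step <- function(params, u_obs, s_obs, t, state = NULL,
                          learning_rate = 0.01, n_steps = 1, fix_toi = FALSE) {
  G <- nrow(params)
  u_obs <- time_matrix(u_obs, G); s_obs <- time_matrix(s_obs, G)
  tm <- time_matrix(t, G)
  th <- params_to_theta(params)
  if (is.null(state))
    state <- list(m = matrix(0, 8, G), v = matrix(0, 8, G), step = 0L)
  res <- cpp_adam_steps(u_obs, s_obs, tm, th, state$m, state$v, state$step,
                        as.integer(n_steps), learning_rate, 0.9, 0.999, 1e-8,
                        fix_toi)
  list(params = theta_to_params(res$theta, rownames(params)),
       state = list(m = res$m, v = res$v, step = res$step),
       loss = res$trace)
}

#' Grid-search assignment of cell times
#'
#' For each cell and gene, picks the candidate time on a uniform grid over
#' `[0, 1]` minimizing the squared distance between the smoothed observation
#' and the parametric (u, s) trajectory. Ties go to the smallest candidate.
#'
#' @param params an [rbf_params].
#' @param u_obs,s_obs cells x genes observation matrices.
#' @param grid_size number of equally spaced candidates (default 100).
#' @return Cells x genes matrix of assigned times.
#' @export
assign_time <- function(params, u_obs, s_obs, grid_size = 100) {
  G <- nrow(params)
  u_obs <- time_matrix(u_obs, G); s_obs <- time_matrix(s_obs, G)
  grid <- seq(0, 1, length.out = grid_size)
  T <- cpp_assign_time(u_obs, s_obs, params_to_theta(params), grid)
  dimnames(T) <- list(rownames(u_obs), rownames(params))
  T
}

#' Aggregate per-gene cell times into a unified time
#'
#' Each gene's time vector is first mapped onto a common `[0, 1]` scale by
#' the fractional-rank (quantile) transform, aligning genes that agree on
#' the cell ordering but differ in raw time values. The per-gene quantiles
#' are optionally denoised by a truncated SVD before averaging across genes;
#' the average is then min-max rescaled to `[0, 1]`.
#'
#' @param t_ng cells x genes matrix of per-gene assigned times.
#' @param denoise_dims SVD rank for denoising (0 disables; values >= the
#'   number of genes also disable it).
#' @return Per-cell unified time in `[0, 1]`, with the pre-rescale range in
#'   `attr(, "raw_range")` (used when mapping held-out cells onto the scale).
#' @export
unify_time <- function(t_ng, denoise_dims = 0) {
  t_ng <- as.matrix(t_ng)
  Q <- apply(t_ng, 2, frac_rank)
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = nrow(t_ng))
  if (denoise_dims > 0 && denoise_dims < ncol(Q) && nrow(Q) > 2) {
    k <- min(denoise_dims, nrow(Q) - 1L)
    sv <- if (k < min(dim(Q)) / 3 && min(dim(Q)) > 50) {
      with_local_seed(0L, irlba::irlba(Q, nv = k))
    } else {
      s0 <- svd(Q, nu = k, nv = k)
      list(u = s0$u, d = s0$d[seq_len(k)], v = s0$v)
    }
    Q <- sv$u %*% (sv$d * t(sv$v))
  }
  m <- rowMeans(Q)
  rng <- range(m)
  t_n <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else rep(0.5, length(m))
  names(t_n) <- rownames(t_ng)
  attr(t_n, "raw_range") <- rng
  t_n
}

#' Fit the RBF velocity model
#'
#' Alternates Adam gradient descent on the gene parameters with periodic
#' grid-search re-assignment of cell times (followed, in unified mode, by
#' quantile aggregation of the per-gene times into one shared time per
#' cell). Stops when the proportional change of the total loss stays below
#' `conv_tol` through a full re-assignment cycle, or at `max_iters`.
#'
#' @param sce preprocessed dataset (normalized, moments, velocity genes).
#' @param config a [fit_config()].
#' @param genes optional gene selection overriding the `velocity_genes` mask.
#' @return An object of class `velocity_fit`: `params` (converged
#'   [rbf_params]), `time` (per-cell vector in unified mode, cells x genes
#'   matrix in independent mode), `time_ng` (final per-gene assignments),
#'   `velocity` (cells x genes ds/dt at the final times), `gene_r2`,
#'   `gene_class`, `loss_trace`, `iterations`, `converged`, `mode`.
#' @export
fit_velocity <- function(sce, config = fit_config(), genes = NULL) {
  .assert(inherits(config, "fit_config"), "config must come from fit_config()")
  ini <- init_params(sce, mode = config$mode, genes = genes)
  p <- ini$params
  genes <- rownames(p)
  mm <- moment_matrices(sce, genes)
  n <- nrow(mm$Ms); G <- length(genes)
  .assert(all(is.finite(mm$Mu)) && all(is.finite(mm$Ms)),
          "non-finite values in the smoothed moment layers")
  dd <- if (G > 100) min(config$denoise_dims, G - 1L) else 0L

  th <- params_to_theta(p)
  st <- list(m = matrix(0, 8, G), v = matrix(0, 8, G), step = 0L)
  fix_toi <- config$mode == "independent"
  Tmat <- matrix(ini$time, n, G)
  t_unified <- ini$time
  grid <- seq(0, 1, length.out = config$grid_size)

  loss_trace <- numeric(0)
  init_loss <- NA_real_
  converged <- FALSE
  iters <- 0L

  with_local_seed(config$seed, {
    while (iters < config$max_iters) {
      n_steps <- min(config$reassign_every, config$max_iters - iters)
      res <- cpp_adam_steps(mm$Mu, mm$Ms, Tmat, th, st$m, st$v, st$step,
                            n_steps, config$learning_rate, 0.9, 0.999, 1e-8,
                            fix_toi)
      th <- res$theta; st <- list(m = res$m, v = res$v, step = res$step)
      iters <- iters + n_steps
      loss_trace <- c(loss_trace, res$trace)
      if (is.na(init_loss)) init_loss <- res$trace[1]
      last_loss <- cpp_loss(mm$Mu, mm$Ms, Tmat, th)$total
      .assert(is.finite(last_loss) &&
                last_loss < 10 * abs(init_loss) + abs(init_loss),
              "loss diverged (%.3g vs initial %.3g); lower the learning rate",
              last_loss, init_loss)

      # time re-assignment with parameters held fixed
      Tng <- cpp_assign_time(mm$Mu, mm$Ms, th, grid)
      if (config$mode == "unified") {
        t_unified <- unify_time(Tng, dd)
        Tmat <- matrix(t_unified, n, G)
      } else {
        Tmat <- Tng
      }
      re_loss <- cpp_loss(mm$Mu, mm$Ms, Tmat, th)$total

      cyc <- c(res$trace, last_loss, re_loss)
      rel <- abs(diff(cyc)) / pmax(abs(cyc[-length(cyc)]), 1e-12)
      if (all(rel < config$conv_tol)) { converged <- TRUE; break }
    }
  })

  p <- theta_to_params(th, genes)
  Tng <- cpp_assign_time(mm$Mu, mm$Ms, th, grid)
  dimnames(Tng) <- list(rownames(mm$Ms), genes)
  time_out <- if (config$mode == "unified") {
    setNames(as.numeric(t_unified), rownames(mm$Ms))
  } else Tng
  Tfinal <- if (config$mode == "unified") matrix(time_out, n, G) else Tng
  vel <- rbf_velocity(p, Tfinal)
  dimnames(vel) <- list(rownames(mm$Ms), genes)
  shat <- rbf_spliced(p, Tfinal)
  sse <- colSums((shat - mm$Ms)^2)
  sst <- colSums(sweep(mm$Ms, 2, colMeans(mm$Ms))^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, NA_real_)

  structure(list(params = p, time = time_out, time_ng = Tng, velocity = vel,
                 gene_r2 = setNames(r2, genes),
                 gene_class = setNames(classify_genes(p), genes),
                 loss_trace = loss_trace, iterations = iters,
                 converged = converged, mode = config$mode,
                 unify_range = attr(t_unified, "raw_range"),
                 genes = genes, cells = rownames(mm$Ms), config = config),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("velocity_fit: %d genes x %d cells, mode=%s\n",
              length(x$genes), length(x$cells), x$mode))
  cat(sprintf("  iterations: %d (%s), final loss %.4f\n", x$iterations,
              if (x$converged) "converged" else "max_iters reached",
              utils::tail(x$loss_trace, 1)))
  cat("  gene classes:", paste(sprintf("%s=%d", levels(x$gene_class),
                                       table(x$gene_class)), collapse = " "),
      "\n")
  invisible(x)
}
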