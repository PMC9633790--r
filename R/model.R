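#' Per-gene parameters of the RBF velocity model
#'
#' Bundles the eight gene-specific parameters of the radial-basis-function
#' expression model. The spliced mean along latent time `t` is
#' \deqn{s_g(t) = h_g e^{-a_g (t - \tau_g)^2} + o_g,}
#' the unspliced mean is derived from the splicing ODE
#' \eqn{ds/dt = \beta u - \gamma s} as
#' \deqn{u_g(t) = (s_g'(t) + \gamma_g s_g(t)) / \beta_g + i_g,}
#' and the RNA velocity is the analytic derivative \eqn{s_g'(t)}.
#'
#' @param h expression amplitude (normalized counts, > 0).
#' @param a RBF width/scale parameter (1/time^2, > 0); larger values give
#'   narrower expression peaks.
#' @param tau peak time of the gene; may lie outside `[0, 1]`, which is what
#'   classifies monotone (induction/repressed) genes.
#' @param gamma degradation rate (1/time, > 0).
#' @param beta splicing rate (1/time, > 0).
#' @param b residual precision, \eqn{b = 1/(\sqrt{2\pi}\sigma)} (> 0).
#' @param o spliced offset (normalized counts).
#' @param i unspliced offset (normalized counts).
#' @param gene optional gene identifiers used as row names.
#'
#' @return A data frame of class `rbf_params` with one row per gene.
#' @examples
#' p <- rbf_params(h = 2, a = 1, tau = 0.5, gamma = 1, beta = 1, o = 0.1)
#' rbf_spliced(p, 0.5)  # peak value h + o
#' @export
rbf_params <- function(h, a, tau, gamma, beta, b = 1, o = 0, i = 0,
                       gene = NULL) {
  df <- data.frame(h = h, a = a, tau = tau, gamma = gamma, beta = beta,
                   b = b, o = o, i = i)
  if (!is.null(gene)) rownames(df) <- gene
  validate_rbf_params(df)
  class(df) <- c("rbf_params", "data.frame")
  df
}

validate_rbf_params <- function(p) {
  .assert(all(c("h", "a", "tau", "gamma", "beta", "b", "o", "i") %in%
                colnames(p)), "rbf_params needs columns h,a,tau,gamma,beta,b,o,i")
  pos <- c("h", "a", "gamma", "beta", "b")
  for (col in pos)
    .assert(all(is.finite(p[[col]])) && all(p[[col]] > 0),
            "parameter '%s' must be strictly positive and finite", col)
  .assert(all(is.finite(p$tau)) && all(is.finite(p$o)) && all(is.finite(p$i)),
          "tau, o, i must be finite")
  invisible(p)
}

# Broadcast a time argument against G genes: returns an n x G matrix.
time_matrix <- function(t, G) {
  if (is.matrix(t)) {
    .assert(ncol(t) == G, "time matrix has %d columns but %d genes", ncol(t), G)
    t
  } else {
    matrix(t, nrow = length(t), ncol = G)
  }
}

# Collapse n x 1 results back to vectors when the input time was a vector.
maybe_drop <- function(m, t, G)
  if (G == 1L && !is.matrix(t)) unname(drop(m)) else m

#' Spliced, unspliced and velocity mean functions
#'
#' Evaluate the parametric phase trajectory at given latent times. `t` can be
#' a vector (shared across genes, e.g. the unified cell time) or an
#' `n x G` matrix of per-cell per-gene times.
#'
#' `rbf_velocity()` returns the time derivative of the spliced mean. The
#' constant offset `o` vanishes under differentiation, so the default
#' (`form = "derivative"`) computes `(s(t) - o) * (-2a(t - tau))`. The
#' alternative `form = "printed"` multiplies the full `s(t)` including the
#' offset, matching the algebraically looser form in which the velocity
#' formula is sometimes written; the two agree whenever `o = 0`.
#'
#' @param params an [rbf_params] data frame with G rows.
#' @param t numeric vector of length n, or an `n x G` matrix.
#' @param form for `rbf_velocity`, `"derivative"` (default) or `"printed"`.
#' @return An `n x G` matrix (a vector if G = 1 and `t` is a vector).
#' @examples
#' p <- rbf_params(h = 1, a = 4, tau = 0, gamma = 1, beta = 1)
#' rbf_spliced(p, 0.5)   # exp(-1)
#' rbf_velocity(p, 0)    # zero at the peak
#' @export
rbf_spliced <- function(params, t) {
  G <- nrow(params)
  tm <- time_matrix(t, G)
  d <- sweep(tm, 2, params$tau, "-")
  E <- exp(-sweep(d^2, 2, params$a, "*"))
  s <- sweep(sweep(E, 2, params$h, "*"), 2, params$o, "+")
  dimnames(s) <- list(rownames(tm), rownames(params))
  maybe_drop(s, t, G)
}

#' @rdname rbf_spliced
#' @export
rbf_unspliced <- function(params, t) {
  G <- nrow(params)
  tm <- time_matrix(t, G)
  d <- sweep(tm, 2, params$tau, "-")
  E <- exp(-sweep(d^2, 2, params$a, "*"))
  hE <- sweep(E, 2, params$h, "*")
  s <- sweep(hE, 2, params$o, "+")
  sp <- hE * sweep(d, 2, -2 * params$a, "*")
  u <- sweep(sp + sweep(s, 2, params$gamma, "*"), 2, params$beta, "/")
  u <- sweep(u, 2, params$i, "+")
  dimnames(u) <- list(rownames(tm), rownames(params))
  maybe_drop(u, t, G)
}

#' @rdname rbf_spliced
#' @export
rbf_velocity <- function(params, t, form = c("derivative", "printed")) {
  form <- match.arg(form)
  G <- nrow(params)
  tm <- time_matrix(t, G)
  d <- sweep(tm, 2, params$tau, "-")
  E <- exp(-sweep(d^2, 2, params$a, "*"))
  core <- sweep(E, 2, params$h, "*")
  if (form == "printed") core <- sweep(core, 2, params$o, "+")
  v <- core * sweep(d, 2, -2 * params$a, "*")
  dimnames(v) <- list(rownames(tm), rownames(params))
  maybe_drop(v, t, G)
}

#' Negative log-likelihood of observed phase points
#'
#' Per-gene loss \eqn{\pi b^2 \sum_i |x_i - \hat x_i(t)|^2 - \log b}, where
#' the residual is the joint Euclidean distance in the (unspliced, spliced)
#' plane. A single precision `b` per gene is shared between the two
#' dimensions by default; supplying `b_u` switches to a per-dimension
#' precision variant in which `params$b` applies to the spliced residuals and
#' `b_u` to the unspliced ones.
#'
#' @param params an [rbf_params] with G rows.
#' @param u_obs,s_obs `n x G` matrices (or length-n vectors when G = 1) of
#'   observed unspliced/spliced values (typically KNN-smoothed moments).
#' @param t latent times, vector or `n x G` matrix.
#' @param b_u optional per-gene unspliced precision (length G), enabling the
#'   per-dimension variant.
#' @return Numeric vector of per-gene losses (lower is better).
#' @examples
#' p <- rbf_params(h = 1, a = 1, tau = 0.5, gamma = 1, beta = 1, b = 2)
#' s <- rbf_spliced(p, c(0.2, 0.8)); u <- rbf_unspliced(p, c(0.2, 0.8))
#' rbf_nll(p, u, s, c(0.2, 0.8))  # perfect fit: -log(2)
#' @export
rbf_nll <- function(params, u_obs, s_obs, t, b_u = NULL) {
  G <- nrow(params)
  u_obs <- time_matrix(u_obs, G); s_obs <- time_matrix(s_obs, G)
  .assert(all(is.finite(u_obs)) && all(is.finite(s_obs)),
          "non-finite observations passed to the likelihood")
  eu <- rbf_unspliced(params, t) - u_obs
  es <- rbf_spliced(params, t) - s_obs
  eu <- time_matrix(eu, G); es <- time_matrix(es, G)
  if (is.null(b_u)) {
    D <- colSums(eu^2) + colSums(es^2)
    unname(pi * params$b^2 * D - log(params$b))
  } else {
    .assert(length(b_u) == G && all(b_u > 0), "b_u must be positive, length G")
    unname(pi * b_u^2 * colSums(eu^2) - log(b_u) +
           pi * params$b^2 * colSums(es^2) - log(params$b))
  }
}

#' Classify genes by their fitted peak time
#'
#' A gene whose expression peak lies at or before the start of the latent
#' time axis is falling throughout the trajectory (repressed); a peak at or
#' beyond the end means the gene is still rising (induction); a peak strictly
#' inside (0, 1) yields a rise-then-fall transient.
#'
#' @param params an [rbf_params].
#' @return Factor with levels `repressed`, `transient`, `induction`.
#' @examples
#' p <- rbf_params(h = 1, a = 1, tau = c(-0.2, 0.5, 1.3), gamma = 1, beta = 1)
#' classify_genes(p)
#' @export
classify_genes <- function(params) {
  lab <- ifelse(params$tau <= 0, "repressed",
                ifelse(params$tau >= 1, "induction", "transient"))
  factor(lab, levels = c("repressed", "transient", "induction"))
}
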