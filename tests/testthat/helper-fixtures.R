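suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

# Preprocess a simulated dataset up to velocity-gene selection.
preprocess_sim <- function(sce, n_neighbors = 30) {
  sce <- normalize_and_filter(sce, size_normalize = FALSE)
  sce <- suppressWarnings(select_hvg(sce, 2000))
  sce <- knn_moments(sce, n_neighbors = n_neighbors)
  select_velocity_genes(sce)
}

# Cache expensive shared fixtures (one simulation + one unified fit) so
# several test files can reuse them.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    sce <- simulate_dataset(sim_spec(seed = 7))
    .fixture_env$sim <- preprocess_sim(sce)
  }
  .fixture_env$sim
}

fit_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- fit_velocity(sim_fixture(),
                                     fit_config(max_iters = 3000, seed = 1))
  }
  .fixture_env$fit
}

toy_dataset <- function() {
  # 3 genes x 5 cells; gene3 has unspliced signal in a single cell
  s <- matrix(c(4, 3, 5, 2, 6,
                1, 2, 1, 3, 1,
                2, 2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  u <- matrix(c(2, 1, 2, 1, 3,
                1, 1, 2, 1, 1,
                0, 0, 1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = dimnames(s))
  velocity_dataset(s, u)
}

# 8-gene dataset in which each steady-state filter can be checked by hand;
# the moment layers are injected directly so expected statistics are exact.
eight_gene_dataset <- function() {
  set.seed(42)
  n <- 50
  s_base <- seq(1, 5, length.out = n)
  Ms <- rbind(
    lin      = s_base,                 # u = 0.5 s: kept
    wide_u   = s_base,                 # sd(u)/sd(s) = 5: excluded
    neg      = s_base,                 # negative slope: excluded
    tiny_gam = s_base,                 # slope 0.005 < 0.01: excluded
    noise    = s_base,                 # u unrelated to s, poor R2: excluded
    narrow_u = s_base,                 # sd ratio 0.01 < 0.03: excluded
    kept2    = s_base,                 # u = 2 s: kept
    flat     = rep(3, n))              # zero variance: excluded
  Mu <- rbind(
    lin      = 0.5 * s_base,
    wide_u   = 5 * (s_base - mean(s_base)) + 5.2 * mean(s_base),
    neg      = -0.5 * s_base + 6,
    tiny_gam = 0.005 * s_base,
    noise    = rnorm(n, mean = 3, sd = 1),
    narrow_u = 0.01 * (s_base - mean(s_base)) + mean(s_base) * 0.5,
    kept2    = 2 * s_base,
    flat     = 0.5 * s_base)
  Mu <- pmax(Mu, 0)
  sce <- velocity_dataset(Ms, Mu)
  sce <- normalize_and_filter(sce, min_cells = 1, size_normalize = FALSE)
  sce <- suppressWarnings(select_hvg(sce, 100))
  dimnames(Ms) <- dimnames(Mu) <- dimnames(sce)
  SummarizedExperiment::assay(sce, "Ms") <- Ms
  SummarizedExperiment::assay(sce, "Mu") <- Mu
  sce
}

with_seed_runif <- function(n, seed, ...) {
  set.seed(seed)
  runif(n, ...)
}

random_params <- function(G, seed = 1, o_zero = FALSE, i_zero = FALSE) {
  set.seed(seed)
  rbf_params(gene = sprintf("g%d", seq_len(G)),
             h = runif(G, 0.5, 3), a = runif(G, 0.5, 6),
             tau = runif(G, -0.5, 1.5), gamma = runif(G, 0.5, 3),
             beta = runif(G, 0.5, 3), b = runif(G, 0.5, 2),
             o = if (o_zero) rep(0, G) else runif(G, 0, 0.5),
             i = if (i_zero) rep(0, G) else runif(G, 0, 0.3))
}

# brute-force time assignment: exhaustive argmin over a candidate vector
brute_assign <- function(params, u_obs, s_obs, candidates) {
  n <- nrow(s_obs); G <- nrow(params)
  out <- matrix(0, n, G)
  for (g in seq_len(G)) {
    p1 <- params[g, , drop = FALSE]
    class(p1) <- c("rbf_params", "data.frame")
    sg <- rbf_spliced(p1, candidates)
    ug <- rbf_unspliced(p1, candidates)
    for (c in seq_len(n)) {
      d <- (sg - s_obs[c, g])^2 + (ug - u_obs[c, g])^2
      out[c, g] <- candidates[which.min(d)]
    }
  }
  out
}

# brute-force CBDir for one source->target pair, straight from its definition
brute_cbdir_pair <- function(v, x, clusters, src, tgt, knn) {
  scores <- c()
  for (c in which(as.character(clusters) == src)) {
    nbs <- knn[c, -1]
    tnb <- nbs[as.character(clusters[nbs]) == tgt]
    if (!length(tnb)) next
    cs <- sapply(tnb, function(cc) {
      d <- x[cc, ] - x[c, ]
      sum(d * v[c, ]) / (sqrt(sum(d^2)) * sqrt(sum(v[c, ]^2)))
    })
    scores <- c(scores, sum(cs) / length(tnb))
  }
  if (length(scores)) mean(scores) else NA_real_
}

brute_iccoh_cell <- function(v, clusters, knn, c) {
  nbs <- knn[c, -1]
  nbs <- nbs[as.character(clusters[nbs]) == as.character(clusters[c])]
  nbs <- nbs[sqrt(rowSums(v[nbs, , drop = FALSE]^2)) > 0]
  if (!length(nbs) || sqrt(sum(v[c, ]^2)) == 0) return(NA_real_)
  mean(sapply(nbs, function(cc)
    sum(v[c, ] * v[cc, ]) / (sqrt(sum(v[c, ]^2)) * sqrt(sum(v[cc, ]^2)))))
}
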