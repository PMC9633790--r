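test_that("fit R-squared matches its definition", {
  p <- random_params(3, seed = 1)
  set.seed(2)
  t <- runif(40)
  s <- rbf_spliced(p, t)
  expect_equal(unname(gene_r2(p, t, s)), rep(1, 3))   # perfect fit
  # hand-computed 4-cell example
  p1 <- rbf_params(h = 1, a = 1, tau = 0.5, gamma = 1, beta = 1)
  t4 <- c(0.1, 0.4, 0.6, 0.9)
  obs <- rbf_spliced(p1, t4) + c(0.1, -0.1, 0.2, -0.2)
  expected <- 1 - sum((rbf_spliced(p1, t4) - obs)^2) /
    sum((obs - mean(obs))^2)
  expect_equal(unname(gene_r2(p1, t4, matrix(obs))), expected)
  # predicting the per-gene mean scores zero
  pred_mean <- matrix(mean(obs), 4, 1)
  sse <- sum((pred_mean - obs)^2); sst <- sum((obs - mean(obs))^2)
  expect_equal(1 - sse / sst, 0)
  # zero-variance gene is undefined
  expect_true(is.na(gene_r2(p1, t4, matrix(rep(2, 4)))))
})

test_that("zero velocity projects to a zero embedding vector", {
  sce <- sim_fixture()
  fit <- fit_fixture()
  v0 <- project_velocity(sce, matrix(0, ncol(sce), length(fit$genes),
                                     dimnames = list(colnames(sce), fit$genes)),
                         genes = fit$genes)
  expect_true(all(v0 == 0))
})

test_that("projected velocities point from early to late clusters", {
  sce <- sim_fixture()
  fit <- fit_fixture()
  v <- project_velocity(sce, fit)
  truth <- S4Vectors::metadata(sce)$truth
  # for each cell, does the projected vector align with the local time
  # direction of the embedding arc?
  emb <- reducedDim(sce, "embedding")
  knn <- S4Vectors::metadata(sce)$knn
  t_true <- truth$time
  ok <- 0; tot <- 0
  for (c in seq_len(ncol(sce))) {
    if (all(v[c, ] == 0)) next
    nbs <- knn[c, -1]
    later <- nbs[t_true[nbs] > t_true[c]]
    if (!length(later)) next
    d <- colMeans(emb[later, , drop = FALSE]) - emb[c, ]
    tot <- tot + 1
    if (sum(d * v[c, ]) > 0) ok <- ok + 1
  }
  expect_gt(ok / tot, 0.9)
})

test_that("CBDir matches a brute-force evaluation and its symmetries", {
  # 5-cell hand-worked configuration in 2-D
  x <- rbind(c(0, 0), c(1, 0), c(1.2, 0.3), c(0.2, -0.1), c(2, 0))
  v <- rbind(c(1, 0), c(1, 0.2), c(0, 1), c(-1, 0), c(0.5, 0.5))
  clusters <- factor(c("A", "A", "B", "A", "B"))
  knn <- cbind(1:5, rbind(c(2, 4), c(3, 5), c(2, 5), c(1, 3), c(3, 2)))
  tr <- data.frame(source = "A", target = "B")
  res <- cbdir(v, x, clusters, tr, knn)
  expect_equal(unname(res$per_pair[1]),
               brute_cbdir_pair(v, x, clusters, "A", "B", knn))
  # cells 2 and 4 of the source cluster touch the target; cell 1 does not
  expect_equal(res$n_boundary[1], 2L)
  # parallel velocities score exactly 1, antiparallel -1
  v_par <- t(apply(x, 1, function(z) c(1, 0)))
  x_line <- cbind(seq_len(5), 0)
  knn_line <- cbind(1:5, rbind(2, 3, 4, 5, 4))
  cl_line <- factor(c("A", "A", "B", "B", "B"))
  res_par <- cbdir(v_par, x_line, cl_line, tr, knn_line)
  expect_equal(unname(res_par$per_pair[1]), 1)
  res_anti <- cbdir(-v_par, x_line, cl_line, tr, knn_line)
  expect_equal(unname(res_anti$per_pair[1]), -1)
  # positive rescaling leaves the metric unchanged; negation flips its sign
  expect_equal(cbdir(7.3 * v, x, clusters, tr, knn)$per_pair, res$per_pair)
  expect_equal(cbdir(-v, x, clusters, tr, knn)$per_pair, -res$per_pair)
  # missing pair reported as NA, not zero
  tr2 <- data.frame(source = "B", target = "C")
  expect_true(is.na(cbdir(v, x, clusters, tr2, knn)$per_pair[1]))
})

test_that("ICCoh matches brute force and ignores global direction", {
  set.seed(4)
  n <- 40
  x <- matrix(rnorm(2 * n), n, 2)
  v <- matrix(rnorm(2 * n), n, 2)
  clusters <- factor(rep(c("A", "B"), each = n / 2))
  knn <- cbind(seq_len(n), t(sapply(seq_len(n), function(c)
    order(colSums((t(x) - x[c, ])^2))[2:6])))
  res <- iccoh(v, clusters, knn)
  for (c in c(1, 7, 25))
    expect_equal(res$per_cell[c], brute_iccoh_cell(v, clusters, knn, c))
  # identical velocities: perfect coherence
  v_same <- matrix(rep(c(1, 2), each = n), n, 2)
  expect_equal(iccoh(v_same, clusters, knn)$mean, 1)
  # global negation leaves ICCoh exactly unchanged
  expect_equal(iccoh(-v, clusters, knn)$per_cell, res$per_cell)
  # positive rescaling invariance
  expect_equal(iccoh(3.7 * v, clusters, knn)$per_cell, res$per_cell)
  # random velocities: near-zero mean coherence
  set.seed(5)
  nbig <- 1000
  xb <- matrix(rnorm(2 * nbig), nbig, 2)
  vb <- matrix(rnorm(2 * nbig), nbig, 2)
  clb <- factor(rep("A", nbig))
  knnb <- BiocNeighbors::findKNN(xb, k = 10)$index
  res_rand <- iccoh(vb, clb, cbind(seq_len(nbig), knnb))
  expect_lt(abs(res_rand$mean), 0.05)
})

test_that("transition files round-trip through TSV and JSON", {
  tr <- data.frame(source = c("bin1", "bin2"), target = c("bin2", "bin3"))
  tsv <- tempfile(fileext = ".tsv")
  write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_transitions(tsv), tr, ignore_attr = TRUE)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(tr, js)
  expect_equal(read_transitions(js), tr, ignore_attr = TRUE)
})
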