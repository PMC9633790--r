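test_that("the pipeline runs end to end on simulated data", {
  sce <- simulate_dataset(sim_spec(n_cells = 150, n_genes = 60, seed = 31))
  truth <- S4Vectors::metadata(sce)$truth
  out_dir <- file.path(tempfile("run"), "out")
  res <- suppressWarnings(run_pipeline(sce, output_dir = out_dir, mode = "unified",
                      size_normalize = FALSE, max_iters = 600, seed = 2,
                      transitions = truth$transitions, verbose = FALSE))
  expect_s3_class(res, "velocity_run")
  expect_true(all(res$sce$latent_time >= 0 & res$sce$latent_time <= 1))
  expect_true("velocity" %in% assayNames(res$sce))
  expect_false(is.null(res$eval))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "evaluation.json")))
  # identical rerun under the same seed/config
  res2 <- suppressWarnings(run_pipeline(sce, mode = "unified",
                       size_normalize = FALSE,
                       max_iters = 600, seed = 2, verbose = FALSE))
  expect_identical(assay(res$sce, "velocity"), assay(res2$sce, "velocity"))
  # forcing independent mode overrides any heuristic
  res_i <- suppressWarnings(run_pipeline(sce, mode = "independent",
                        size_normalize = FALSE,
                        max_iters = 200, seed = 2, verbose = FALSE))
  expect_true(all(res_i$fit$params$tau == 0.5))
  # missing layers produce a schema error naming the expectation
  bad <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = matrix(1, 2, 2)))
  expect_error(run_pipeline(bad, verbose = FALSE), "spliced")
})

test_that("the MTX container round-trips layers bitwise", {
  set.seed(32)
  s <- matrix(as.numeric(rpois(200, 5)), 10, 20,
              dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:20)))
  u <- matrix(as.numeric(rpois(200, 2)), 10, 20, dimnames = dimnames(s))
  emb <- matrix(rnorm(40), 20, 2)
  sce <- velocity_dataset(s, u, clusters = rep(c("A", "B"), 10),
                          embedding = emb)
  dir <- tempfile("mtx")
  write_velocity_dataset(sce, dir)
  back <- read_velocity_dataset(dir)
  expect_identical(as.matrix(assay(back, "spliced")), s)
  expect_identical(as.matrix(assay(back, "unspliced")), u)
  expect_equal(as.character(back$clusters), rep(c("A", "B"), 10))
  expect_equal(unname(reducedDim(back, "embedding")), emb, tolerance = 1e-15)
  # real-valued layers survive at full double precision
  sr <- s * pi
  scer <- velocity_dataset(sr, u)
  dir2 <- tempfile("mtx")
  write_velocity_dataset(scer, dir2)
  expect_identical(as.matrix(assay(read_velocity_dataset(dir2), "spliced")),
                   sr)
  # a missing file yields a clear container error
  file.remove(file.path(dir2, "unspliced.mtx"))
  expect_error(read_velocity_dataset(dir2), "unspliced.mtx")
})

test_that("h5ad and loom containers written by Python tools are readable", {
  scratch <- tempfile("h5")
  dir.create(scratch)
  h5ad <- file.path(scratch, "t.h5ad")
  loom <- file.path(scratch, "t.loom")
  script <- c(
    "import numpy as np, pandas as pd, h5py, scipy.sparse as sp",
    "import anndata as ad",
    "rng = np.random.default_rng(0)",
    "n, g = 25, 8",
    "S = rng.poisson(5, size=(n, g)).astype(float)",
    "U = rng.poisson(2, size=(n, g)).astype(float)",
    "labels = ['A', 'B'] * 12 + ['A']",
    "obs = pd.DataFrame({'clusters': pd.Categorical(labels)},",
    "                   index=['c%d' % i for i in range(n)])",
    "var = pd.DataFrame(index=['g%d' % j for j in range(g)])",
    "A = ad.AnnData(X=S, obs=obs, var=var,",
    "               layers={'spliced': sp.csr_matrix(S), 'unspliced': U},",
    "               obsm={'X_umap': rng.normal(size=(n, 2))})",
    sprintf("A.write_h5ad('%s')", h5ad),
    sprintf("with h5py.File('%s', 'w') as f:", loom),
    "    f.create_dataset('matrix', data=S.T)",
    "    f.create_dataset('layers/spliced', data=S.T)",
    "    f.create_dataset('layers/unspliced', data=U.T)",
    "    f.create_dataset('row_attrs/Gene', data=np.array(['g%d' % j for j in range(g)], dtype='S'))",
    "    f.create_dataset('col_attrs/CellID', data=np.array(['c%d' % i for i in range(n)], dtype='S'))",
    "    f.create_dataset('col_attrs/clusters', data=np.array(labels, dtype='S'))",
    sprintf("np.savetxt('%s', S)", file.path(scratch, "S.txt")),
    sprintf("np.savetxt('%s', U)", file.path(scratch, "U.txt")))
  system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(h5ad))
  S <- as.matrix(read.table(file.path(scratch, "S.txt")))
  U <- as.matrix(read.table(file.path(scratch, "U.txt")))
  h <- read_velocity_dataset(h5ad)
  expect_equal(unname(t(as.matrix(assay(h, "spliced")))), unname(S))
  expect_equal(unname(t(as.matrix(assay(h, "unspliced")))), unname(U))
  expect_equal(levels(h$clusters), c("A", "B"))
  expect_equal(dim(reducedDim(h, "embedding")), c(25L, 2L))
  l <- read_velocity_dataset(loom)
  expect_equal(unname(t(as.matrix(assay(l, "spliced")))), unname(S))
  expect_equal(as.character(l$clusters), c(rep(c("A", "B"), 12), "A"))
})

test_that("configuration files merge with explicit arguments", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c("mode: unified", "min_cells: 5", "seed: 9"), cfg_file)
  cfg <- read_pipeline_config(cfg_file)
  expect_equal(cfg$min_cells, 5)
  expect_equal(cfg$mode, "unified")
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 4), js, auto_unbox = TRUE)
  expect_equal(read_pipeline_config(js)$seed, 4)
})
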