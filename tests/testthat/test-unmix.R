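test_that("trivial pixel cases follow from the objective", {
  ax <- wn_axis(seq(2850, 2890, length.out = 5))
  s <- rep(1 / sqrt(5), 5)
  lib <- ref_library(matrix(s, 1), ax, names = "s")
  # zero spectrum -> zero abundances at any lambda
  for (lam in c(0, 0.01, 0.5))
    expect_equal(unname(lasso_unmix_pixel(rep(0, 5), lib,
                                          unmix_params(lam = lam))), 0)
  # lam = 0, y = 2s -> exact least squares c = 2
  expect_equal(unname(lasso_unmix_pixel(2 * s, lib, unmix_params(lam = 0))), 2,
               tolerance = 1e-10)
  expect_error(lasso_unmix_pixel(rep(1, 4), lib, unmix_params()), "channels")
})

test_that("coordinate descent matches the exhaustive active-set oracle", {
  set.seed(101)
  for (i in 1:40) {
    K <- sample(2:5, 1); M <- sample((K + 1):10, 1)
    A <- matrix(runif(K * M, 0.05, 1), K, M)
    A <- A / sqrt(rowSums(A^2))
    lib <- ref_library(A, wn_axis(seq(2850, 2850 + M - 1)), normalize = FALSE)
    y <- as.numeric(t(A) %*% runif(K, 0, 2)) + rnorm(M, sd = 0.05)
    y <- pmax(y, 0)
    for (lam in c(0, 0.01, 0.1)) for (nn in c(TRUE, FALSE)) {
      cc <- lasso_unmix_pixel(y, lib, unmix_params(lam = lam, nonneg = nn, max_iters = 100000,
                                                   tol = 1e-12))
      co <- active_set_lasso_oracle(A, y, lam, nonneg = nn)
      expect_lt(abs(lasso_objective(A, y, cc, lam) -
                      lasso_objective(A, y, co, lam)), 1e-6)
    }
  }
})

test_that("orthonormal libraries give the soft-threshold closed form", {
  M <- 6
  A <- diag(1, 4, M)  # orthonormal rows
  lib <- ref_library(A, wn_axis(seq(2850, 2855)), normalize = FALSE)
  set.seed(5)
  for (i in 1:10) {
    y <- runif(M)
    lam <- sample(c(0, 0.02, 0.2), 1)
    cc <- lasso_unmix_pixel(y, lib, unmix_params(lam = lam, tol = 1e-12))
    expect_equal(unname(cc), pmax(as.numeric(A %*% y) - lam / 2, 0),
                 tolerance = 1e-10)
  }
})

test_that("lambda = 0 with nonnegativity reduces to NNLS", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (i in 1:10) {
    K <- sample(2:5, 1); M <- sample(K:9, 1)
    A <- matrix(runif(K * M), K, M); A <- A / sqrt(rowSums(A^2))
    lib <- ref_library(A, wn_axis(seq(2850, 2850 + M - 1)), normalize = FALSE)
    y <- runif(M)
    cc <- lasso_unmix_pixel(y, lib, unmix_params(lam = 0, tol = 1e-13,
                                                 max_iters = 50000))
    co <- pracma::lsqnonneg(t(A), y)$x
    expect_lt(max(abs(unname(cc) - co)), 1e-8)
  }
})

test_that("sparsity is monotone non-increasing in lambda", {
  set.seed(31)
  lib <- make_default_library(default_axis())
  for (i in 1:5) {
    y <- as.numeric(t(lib$spectra) %*% runif(5, 0, 1)) + rnorm(45, sd = 0.02)
    y <- pmax(y, 0)
    nnz <- vapply(c(0, 0.005, 0.01, 0.05, 0.1, 0.5, 1),
                  function(l) sum(lasso_unmix_pixel(y, lib,
                                                    unmix_params(lam = l)) > 1e-10),
                  numeric(1))
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("unmix_cube is the per-pixel solver applied everywhere", {
  ph <- generate_phantom(phantom_spec(height = 1, width = 1, noise_sd = 0.02,
                                      seed = 2))
  m <- unmix_cube(ph$cube, ph$library, unmix_params())
  p <- lasso_unmix_pixel(as.numeric(ph$cube$data[1, 1, ]), ph$library,
                         unmix_params())
  expect_equal(as.numeric(m$data[1, 1, ]), unname(p))
  expect_equal(m$provenance$lam, 0.01)

  cube_wrong <- hyper_cube(ph$cube$data,
                           wn_axis(as.numeric(ph$cube$axis) + 5))
  expect_error(unmix_cube(cube_wrong, ph$library, unmix_params()),
               "different axes")
})

test_that("noiseless recovery error stays within the lambda-bias bound", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  m <- unmix_cube(ph$cube, ph$library, unmix_params(lam = 0.01))
  N <- prod(dim(ph$truth$data)[1:2])
  Tr <- matrix(ph$truth$data, nrow = N)
  # oracle bias: exact solve on each distinct ground-truth mixture
  uniq <- unique(Tr)
  bias <- 0
  for (r in seq_len(nrow(uniq))) {
    y <- as.numeric(t(ph$library$spectra) %*% uniq[r, ])
    co <- active_set_lasso_oracle(ph$library$spectra, y, 0.01)
    bias <- max(bias, max(abs(co - uniq[r, ])))
  }
  expect_lt(max(abs(matrix(m$data, nrow = N) - Tr)), bias + 1e-4)
  # and with lam = 0 recovery is essentially exact
  m0 <- unmix_cube(ph$cube, ph$library, unmix_params(lam = 0))
  expect_lt(max(abs(m0$data - ph$truth$data)), 1e-6)
})

test_that("abundance RMSE grows with noise", {
  rmse <- vapply(c(0, 0.01, 0.05), function(ns) {
    ph <- generate_phantom(phantom_spec(noise_sd = ns, seed = 4))
    m <- unmix_cube(ph$cube, ph$library, unmix_params())
    sqrt(mean((m$data - ph$truth$data)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("protein reference derivation removes the lipid contribution", {
  ax <- default_axis()
  models <- default_band_models()
  protein <- eval_band_model(models$cellular_protein, ax)
  lipid <- eval_band_model(models$unsaturated_lipid, ax)

  # identical inputs leave an all-zero residual
  expect_error(derive_protein_reference(lipid, lipid, ax), "degenerate")

  # disjoint support: alpha ~ 0, cell returned renormalized
  cellA <- c(rep(1, 20), rep(0, 25))
  lipB <- c(rep(0, 25), rep(1, 20))
  out <- derive_protein_reference(cellA, lipB, ax)
  expect_equal(out, cellA / sqrt(sum(cellA^2)), tolerance = 1e-12)

  # 0.7 protein + 0.3 lipid mixture: recovered spectrum ~ protein
  cell <- 0.7 * protein / sqrt(sum(protein^2)) +
    0.3 * lipid / sqrt(sum(lipid^2))
  rec <- derive_protein_reference(cell, lipid, ax)
  pn <- protein / sqrt(sum(protein^2))
  expect_gt(sum(rec * pn), 0.99)  # cosine similarity (both unit norm)
})
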