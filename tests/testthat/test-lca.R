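test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(0.5, 1.0), 0)
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  u <- withr::with_seed(1, array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  ref <- u
  for (i in seq_along(u)) {
    ref[i] <- sign(u[i]) * max(abs(u[i]) - 0.3, 0)
  }
  expect_equal(soft_threshold(u, 0.3), ref)
  expect_error(soft_threshold(u, -0.1), "non-negative")
})

test_that("reconstruction is the impulse response of the dictionary", {
  # degenerate non-convolutional geometry: kernel = image = stride, pad 0
  dict <- withr::with_seed(2, normalize_dictionary(
    sc_dictionary(array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2)), stride = 8)))
  maps <- array(0, c(1, 1, 2))
  zero <- histosparse:::new_sparse_code(maps, NA_real_, 0L, c(8, 8, 3), 8L, 0L)
  expect_true(all(reconstruct(dict, zero) == 0))
  maps[1, 1, 2] <- 1
  one <- histosparse:::new_sparse_code(maps, NA_real_, 0L, c(8, 8, 3), 8L, 0L)
  expect_equal(reconstruct(dict, one), dict$kernels[, , , 2],
               ignore_attr = TRUE)
})

test_that("reconstruction equals the explicit dense convolution matrix", {
  inst <- random_instance(3)
  maps <- withr::with_seed(4, {
    m <- array(0, c(8, 8, 8))
    at <- sample(length(m), 20)
    m[at] <- rnorm(20)
    m
  })
  code <- histosparse:::new_sparse_code(maps, NA_real_, 0L, c(32, 32, 3), 4L, 2L)
  D <- dense_conv_matrix(inst$dict$kernels, c(32, 32, 3), 4)
  expect_equal(as.vector(reconstruct(inst$dict, code)),
               as.vector(D %*% as.vector(maps)))
})

test_that("the energy splits into its two terms", {
  inst <- random_instance(5)
  maps <- array(0, c(8, 8, 8))
  zero <- histosparse:::new_sparse_code(maps, 0.2, 0L, c(32, 32, 3), 4L, 2L)
  expect_equal(energy(inst$img, inst$dict, zero), 0.5 * sum(inst$img^2))
  maps[c(3, 100, 300)] <- c(1, -2, 0.5)
  code <- histosparse:::new_sparse_code(maps, 0.2, 0L, c(32, 32, 3), 4L, 2L)
  resid <- inst$img - reconstruct(inst$dict, code)
  expect_equal(energy(inst$img, inst$dict, code),
               0.5 * sum(resid^2) + 0.2 * sum(abs(maps)))
  expect_error(energy(array(0, c(16, 16, 3)), inst$dict, code), "dimensions")
})

test_that("a threshold above every correlation yields the all-zero code", {
  inst <- random_instance(6)
  drive <- histosparse:::cs_correlate(
    inst$img, matrix(inst$dict$kernels, 192, 8), 8L, 4L, 2L)
  lam <- max(abs(drive)) * 1.05
  cd <- encode(inst$img, inst$dict, lca_config(lambda = lam, n_iterations = 50),
               center = FALSE)
  expect_true(all(cd$maps == 0))
})

test_that("the degenerate one-atom case solves the scalar LASSO", {
  # kernel = image size = stride: a single coefficient
  dict <- withr::with_seed(7, normalize_dictionary(
    sc_dictionary(array(rnorm(8 * 8 * 3), c(8, 8, 3, 1)), stride = 8)))
  img <- withr::with_seed(8, array(rnorm(8 * 8 * 3, sd = 0.5), c(8, 8, 3)))
  lam <- 0.2
  cd <- encode(img, dict, lca_config(lambda = lam, n_iterations = 2000,
                                     tolerance = 1e-12), center = FALSE)
  inner <- sum(dict$kernels[, , , 1] * img)
  expect_equal(as.numeric(cd$maps), sign(inner) * max(abs(inner) - lam, 0),
               tolerance = 1e-3)
})

test_that("LCA reaches the FISTA optimum of the convolutional LASSO", {
  for (seed in 1:3) {
    inst <- random_instance(seed)
    cd <- encode(inst$img, inst$dict,
                 lca_config(lambda = 0.1, n_iterations = 2000,
                            tolerance = 1e-9), center = FALSE)
    e_lca <- tail(attr(cd, "lca_state")$energy_trace, 1)
    D <- dense_conv_matrix(inst$dict$kernels, c(32, 32, 3), 4)
    e_fista <- fista_lasso(D, as.vector(inst$img), 0.1)$energy
    expect_lt(abs(e_lca - e_fista) / e_fista, 0.01)
  }
})

test_that("energy is non-increasing along LCA iterations after burn-in", {
  ds <- generate_tile_dataset(2, tile = 64, seed = 19)
  dict <- init_dictionary(train_config(n_features = 16, kernel = 8, stride = 4,
                                       seed = 1))
  for (img in ds$tiles[1:2]) {
    st <- attr(encode(img, dict, lca_config(lambda = 0.2, dt_over_tau = 0.1,
                                            n_iterations = 150)), "lca_state")
    expect_true(all(diff(st$energy_trace[-(1:5)]) <= 1e-9))
  }
})

test_that("active coefficients satisfy the LASSO stationarity conditions", {
  inst <- random_instance(10)
  lam <- 0.1
  cd <- encode(inst$img, inst$dict,
               lca_config(lambda = lam, n_iterations = 3000, tolerance = 1e-12),
               center = FALSE)
  resid <- inst$img - reconstruct(inst$dict, cd)
  corr <- histosparse:::cs_correlate(resid, matrix(inst$dict$kernels, 192, 8),
                                     8L, 4L, 2L)
  active <- which(cd$maps != 0)
  expect_gt(length(active), 0)
  expect_equal(as.numeric(corr[active]),
               as.numeric(lam * sign(cd$maps[active])), tolerance = 0.05)
})

test_that("codes sparsify as lambda grows", {
  ds <- generate_tile_dataset(2, tile = 64, seed = 29)
  dict <- init_dictionary(train_config(n_features = 16, kernel = 8, stride = 4,
                                       seed = 2))
  frac <- vapply(c(0.05, 0.1, 0.2, 0.4), function(lam) {
    mean(vapply(ds$tiles[1:3], function(img) {
      mean(encode(img, dict, lca_config(lambda = lam, dt_over_tau = 0.1,
                                        n_iterations = 120))$maps != 0)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("sparsity statistics count nonzeros per feature", {
  maps <- array(0, c(4, 4, 3))
  zero <- histosparse:::new_sparse_code(maps, 0.1, 1L, c(16, 16, 3), 4L, 0L)
  st <- sparsity_stats(list(zero))
  expect_equal(st$pct_nonzero, rep(0, 3))
  maps[1, 2, 1] <- 0.7
  one <- histosparse:::new_sparse_code(maps, 0.1, 1L, c(16, 16, 3), 4L, 0L)
  st1 <- sparsity_stats(list(one))
  expect_equal(st1$pct_nonzero, c(6.25, 0, 0))
  # brute-force count over random codes
  codes <- lapply(1:3, function(s) {
    m <- withr::with_seed(s, array(rnorm(4 * 4 * 3) * (runif(48) < 0.3),
                                   c(4, 4, 3)))
    histosparse:::new_sparse_code(m, 0.1, 1L, c(16, 16, 3), 4L, 0L)
  })
  st3 <- sparsity_stats(codes)
  for (f in 1:3) {
    cnt <- sum(vapply(codes, function(cd) sum(cd$maps[, , f] != 0), numeric(1)))
    expect_equal(st3$pct_nonzero[f], 100 * cnt / (16 * 3))
  }
  expect_equal(attr(st3, "overall_fraction"),
               sum(st3$pct_nonzero / 100 * 16 * 3) / (48 * 3))
  expect_error(sparsity_stats(list()), "at least one")
})

test_that("sparse codes round-trip through the coordinate-list format", {
  inst <- random_instance(12)
  cd <- encode(inst$img, inst$dict, lca_config(lambda = 0.1, n_iterations = 200),
               center = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sparse_code(cd, path)
  back <- read_sparse_code(path)
  expect_equal(back$maps, cd$maps)
  expect_equal(back$geometry, cd$geometry)
  expect_equal(back$lambda, cd$lambda)
})

test_that("encoding rejects unnormalized dictionaries", {
  dict <- sc_dictionary(array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2)), stride = 4)
  img <- array(0.5, c(32, 32, 3))
  expect_error(encode(img, dict, lca_config()), "normalized")
})
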