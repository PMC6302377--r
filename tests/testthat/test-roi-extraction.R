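test_that("Otsu separates a symmetric bimodal image exactly", {
  gray <- matrix(rep(c(0.1, 0.9), each = 32), 8, 8)
  res <- binarize_otsu(gray)
  expect_gt(res$threshold, 0.1)
  expect_lt(res$threshold, 0.9)
  expect_identical(res$mask, gray == 0.1)
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  for (seed in 1:5) {
    gray <- withr::with_seed(seed, matrix(runif(64 * 64), 64, 64))
    res <- binarize_otsu(gray)
    expect_equal(res$threshold, otsu_bruteforce(gray))
  }
  # independent library cross-check; overlapping modes so the
  # between-class-variance argmax is unique (a gap would leave a plateau
  # of equivalent thresholds and make the comparison ill-posed)
  gray <- withr::with_seed(2, matrix(pmin(pmax(
    c(rnorm(2000, 0.3, 0.1), rnorm(2096, 0.7, 0.1)), 0), 1), 64, 64))
  expect_lt(abs(binarize_otsu(gray)$threshold -
                EBImage::otsu(gray, range = c(0, 1))), 0.02)
})

test_that("constant images raise a degenerate-histogram error", {
  expect_error(binarize_otsu(matrix(0.5, 10, 10)), "degenerate histogram")
})

test_that("8-bit input is handled on the same scale as [0,1] input", {
  gray01 <- withr::with_seed(3, matrix(runif(32 * 32), 32, 32))
  gray8 <- round(gray01 * 255)
  res <- binarize_otsu(gray8)
  expect_equal(res$threshold, binarize_otsu(gray8 / 255)$threshold)
})

test_that("FFT window density saturates on constant masks", {
  m1 <- matrix(TRUE, 40, 50)
  expect_true(all(window_density_fft(m1, 8) == 1))
  expect_equal(dim(window_density_fft(m1, 8)), c(33, 43))
  m0 <- matrix(FALSE, 40, 40)
  expect_true(all(window_density_fft(m0, 8) == 0))
  expect_error(window_density_fft(m0, 41), "between")
})

test_that("FFT window density equals direct sliding-window summation", {
  mask <- withr::with_seed(4, matrix(runif(128 * 128) < 0.4, 128, 128))
  fftd <- window_density_fft(mask, 32)
  expect_lt(max(abs(fftd - density_bruteforce(mask, 32))), 1e-9)
})

test_that("greedy ROI selection matches the brute-force reference", {
  for (seed in 1:3) {
    d <- withr::with_seed(seed, matrix(runif(64 * 64), 64, 64))
    sel <- select_rois(d, n = 3, window = 16)
    ref <- greedy_bruteforce(d, 3, 16)
    expect_equal(nrow(sel), nrow(ref))
    expect_equal(sel$level_x, unname(ref[, "x"]))
    expect_equal(sel$level_y, unname(ref[, "y"]))
    expect_equal(sel$density, unname(ref[, "density"]), tolerance = 1e-12)
  }
})

test_that("selected windows are pairwise disjoint with non-increasing density", {
  d <- withr::with_seed(6, matrix(runif(80 * 80), 80, 80))
  sel <- select_rois(d, n = 4, window = 20)
  expect_true(all(diff(sel$density) <= 0))
  if (nrow(sel) > 1) {
    pairs <- utils::combn(nrow(sel), 2)
    for (q in seq_len(ncol(pairs))) {
      a <- sel[pairs[1, q], ]; b <- sel[pairs[2, q], ]
      overlap <- abs(a$level_x - b$level_x) < 20 &&
        abs(a$level_y - b$level_y) < 20
      expect_false(overlap)
    }
  }
})

test_that("a map with one dense spot yields exactly one ROI", {
  d <- matrix(0, 32, 32)
  d[10, 17] <- 0.5
  sel <- select_rois(d, n = 4, window = 8)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$level_x, 16)
  expect_equal(sel$level_y, 9)
})

test_that("lift_and_extract is an identity crop at matched power and size", {
  img <- withr::with_seed(8, array(runif(512 * 512 * 3), c(512, 512, 3)))
  sl <- slide_image(list(img), 1, objective_power = 20)
  roi <- tibble::tibble(level_x = 32, level_y = 64, level_window = 128,
                        density = 1, rank = 1)
  tile <- lift_and_extract(sl, roi, level = 1, target = 128, target_power = 20)
  expect_equal(as.vector(tile), as.vector(img[65:192, 33:160, ]))
})

test_that("40X slides are area-averaged 2x down to the 20X equivalent", {
  img <- withr::with_seed(9, array(runif(1024 * 1024 * 3), c(1024, 1024, 3)))
  sl <- slide_image(list(img), 1, objective_power = 40)
  roi <- tibble::tibble(level_x = 100, level_y = 100, level_window = 512,
                        density = 1, rank = 1)
  tile <- lift_and_extract(sl, roi, level = 1, target = 256, target_power = 20)
  expect_equal(dim(tile), c(256, 256, 3))
  expect_equal(attr(tile, "full_window"), 512)
  crop <- img[101:612, 101:612, ]
  expect_lt(abs(mean(tile) - mean(crop)) / mean(crop), 0.01)
})

test_that("an all-white slide fails with the slide ID in the message", {
  white <- array(1, c(256, 256, 3))
  sl <- slide_image(list(white), 1, objective_power = 20)
  expect_error(extract_slide_rois(sl, slide_id = "blank01"),
               "degenerate histogram.*blank01")
})

test_that("Otsu tissue mask agrees with the ground-truth blob mask", {
  sl <- generate_slide(synth_config(canvas_size = 1024, n_blobs = 4, seed = 17))
  thumb <- sl$levels[[2]]
  otsu_mask <- binarize_otsu(luminance_of(thumb))$mask
  truth <- block_mean_of(sl$blob_mask * 1, 4) >= 0.5
  jac <- sum(otsu_mask & truth) / sum(otsu_mask | truth)
  expect_gt(jac, 0.8)
})

test_that("extracted ROIs cover planted tissue preferentially", {
  sl <- generate_slide(synth_config(canvas_size = 1024, n_blobs = 3, seed = 23))
  rs <- extract_slide_rois(sl, n = 4, tile = 128, slide_id = "s23")
  expect_lte(nrow(rs$manifest), 4)
  expect_gt(nrow(rs$manifest), 0)
  expect_true(all(diff(rs$manifest$density) <= 0))
  global_frac <- mean(sl$blob_mask)
  roi_frac <- vapply(seq_len(nrow(rs$manifest)), function(i) {
    m <- rs$manifest[i, ]
    rows <- (m$full_y + 1):(m$full_y + m$full_window)
    cols <- (m$full_x + 1):(m$full_x + m$full_window)
    mean(sl$blob_mask[rows, cols])
  }, numeric(1))
  expect_true(all(roi_frac > 0.5))
  expect_gt(mean(roi_frac), global_frac)
})
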