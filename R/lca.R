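#' Sparse code container
#'
#' Feature maps for one image: an `[mh, mw, n_features]` array of
#' coefficients, mostly zero, plus the geometry that ties map positions to
#' image pixels (`mh = ceiling(H / stride)`; zero-padded "same"-style
#' placement, so a 2048-px tile at stride 4 yields 512 x 512 maps).
#'
#' @name sparse_code
NULL

new_sparse_code <- function(maps, lambda, n_iterations, image_dim, stride, pad) {
  structure(
    list(maps = maps, lambda = lambda, n_iterations = as.integer(n_iterations),
         geometry = list(image_dim = as.integer(image_dim),
                         stride = as.integer(stride), pad = as.integer(pad))),
    class = "sparse_code"
  )
}

#' @export
print.sparse_code <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<sparse_code: %d maps %dx%d, %.2f%% nonzero, lambda %s>\n",
              d[3], d[1], d[2], 100 * mean(x$maps != 0),
              format(x$lambda)), sep = "")
  invisible(x)
}

check_geometry <- function(dict, code) {
  g <- code$geometry
  if (g$stride != dict$stride) abort("code/dictionary stride mismatch.")
  d <- dim(code$maps)
  if (d[3] != n_features(dict)) abort("code/dictionary feature count mismatch.")
  if (d[1] != map_side(g$image_dim[1], g$stride) ||
      d[2] != map_side(g$image_dim[2], g$stride)) {
    abort("map dimensions inconsistent with image size and stride.")
  }
  invisible(TRUE)
}

#' LCA solver configuration
#'
#' @param lambda L1 sparsity tradeoff (>= 0); larger values give sparser
#'   codes at the cost of reconstruction error. Default 0.15 for inputs in
#'   `[0, 1]` with per-tile mean subtraction.
#' @param dt_over_tau integration step of the LCA dynamics, in `(0, 1]`.
#' @param n_iterations maximum iterations.
#' @param tolerance early-stop threshold on the relative energy change.
#' @param threshold_type only `"soft"` (the proximal operator of the L1
#'   penalty) is supported.
#' @return A list of class `lca_config`.
#' @export
lca_config <- function(lambda = 0.15, dt_over_tau = 0.05, n_iterations = 400,
                       tolerance = 1e-4, threshold_type = "soft") {
  if (lambda < 0) abort("`lambda` must be non-negative.")
  if (dt_over_tau <= 0 || dt_over_tau > 1) abort("`dt_over_tau` must be in (0, 1].")
  if (!is_count(n_iterations)) abort("`n_iterations` must be >= 1.")
  threshold_type <- match.arg(threshold_type, "soft")
  structure(
    list(lambda = lambda, dt_over_tau = dt_over_tau,
         n_iterations = as.integer(n_iterations), tolerance = tolerance,
         threshold_type = threshold_type),
    class = "lca_config"
  )
}

#' Soft-thresholding (shrinkage) operator
#'
#' Elementwise `sign(u) * max(|u| - lambda, 0)` — the proximal operator of
#' the L1 penalty, mapping LCA membrane potentials to activations.
#'
#' @param u numeric vector, matrix or array.
#' @param lambda threshold (>= 0).
#' @return Object shaped like `u`.
#' @export
soft_threshold <- function(u, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    abort("`lambda` must be a single non-negative number.")
  }
  sign(u) * pmax(abs(u) - lambda, 0)
}

#' Linear reconstruction from a sparse code
#'
#' Transposed-convolution superposition: each nonzero coefficient adds its
#' kernel, scaled by the coefficient, at its stride-mapped image location.
#'
#' @param dict an [sc_dictionary()].
#' @param code a `sparse_code`.
#' @return Numeric array with the code's image dimensions.
#' @export
reconstruct <- function(dict, code) {
  stopifnot(inherits(dict, "sc_dictionary"), inherits(code, "sparse_code"))
  check_geometry(dict, code)
  g <- code$geometry
  cs_reconstruct(code$maps, kernel_matrix(dict),
                 g$image_dim[1], g$image_dim[2], g$image_dim[3],
                 kernel_side(dict), g$stride, g$pad)
}

#' Sparse-coding energy
#'
#' The objective minimized by inference:
#' `0.5 * ||image - reconstruction||^2 + lambda * sum(|a|)`.
#'
#' @param image numeric array matching the code's image dimensions.
#' @param dict an [sc_dictionary()].
#' @param code a `sparse_code`.
#' @param lambda L1 tradeoff; defaults to the lambda stored in the code.
#' @return A single number.
#' @export
energy <- function(image, dict, code, lambda = code$lambda) {
  if (!all(dim(image) == code$geometry$image_dim)) {
    abort("image dimensions do not match the code geometry.")
  }
  resid <- image - reconstruct(dict, code)
  0.5 * sum(resid^2) + lambda * sum(abs(code$maps))
}

#' Infer a sparse code with the Locally Competitive Algorithm
#'
#' Minimizes the convolutional LASSO energy by integrating the LCA
#' dynamics in residual form: membrane potentials `u` are driven by the
#' stride-matched correlation of the reconstruction residual with each
#' kernel, `u <- u + dt*(Phi'(I - Phi a) + a - u)`, with activations
#' `a = soft_threshold(u, lambda)`. Iteration stops at `n_iterations` or
#' when the relative energy change falls below `tolerance`.
#'
#' @param image `H x W x C` numeric array. By default the per-channel mean
#'   is subtracted before encoding (`center = TRUE`); reconstruction adds
#'   no mean back.
#' @param dict a normalized [sc_dictionary()].
#' @param cfg an [lca_config()].
#' @param center subtract the per-channel image mean before encoding.
#' @return A `sparse_code` with an `lca_state` attribute carrying the
#'   membrane potentials, iteration count and energy trace.
#' @export
encode <- function(image, dict, cfg = lca_config(), center = TRUE) {
  stopifnot(inherits(dict, "sc_dictionary"), inherits(cfg, "lca_config"))
  if (!dict$normalized) abort("dictionary must be normalized before encoding.")
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (d[3] != kernel_channels(dict)) abort("image/dictionary channel mismatch.")
  if (center) {
    mu <- colMeans(matrix(image, ncol = d[3]))
    image <- sweep(image, 3, mu, `-`)
  }
  k <- kernel_side(dict)
  p <- lca_padding(k, dict$stride)
  fit <- cs_lca(image, kernel_matrix(dict), k, dict$stride, p,
                cfg$lambda, cfg$dt_over_tau, cfg$n_iterations, cfg$tolerance)
  code <- new_sparse_code(fit$maps, cfg$lambda, fit$iterations,
                          image_dim = d, stride = dict$stride, pad = p)
  attr(code, "lca_state") <- structure(
    list(potentials = fit$potentials, iteration = fit$iterations,
         energy_trace = as.numeric(fit$energy)),
    class = "lca_state"
  )
  code
}

#' Per-feature activation statistics over a set of codes
#'
#' For each feature, the percentage of map positions (across all codes)
#' with a nonzero coefficient — the sparsity histogram of the feature maps.
#'
#' @param codes a list of `sparse_code` objects with identical geometry.
#' @return A tibble of class `sc_sparsity` with columns `feature` and
#'   `pct_nonzero`, and attribute `overall_fraction` (fraction of nonzero
#'   coefficients over everything).
#' @export
sparsity_stats <- function(codes) {
  if (inherits(codes, "sparse_code")) codes <- list(codes)
  if (length(codes) == 0) abort("`codes` must contain at least one sparse code.")
  nf <- dim(codes[[1]]$maps)[3]
  counts <- numeric(nf)
  positions <- 0
  for (code in codes) {
    d <- dim(code$maps)
    if (d[3] != nf) abort("codes have inconsistent feature counts.")
    counts <- counts + colSums(matrix(code$maps != 0, ncol = nf))
    positions <- positions + d[1] * d[2]
  }
  out <- tibble::tibble(feature = seq_len(nf),
                        pct_nonzero = 100 * counts / positions)
  attr(out, "overall_fraction") <- sum(counts) / (positions * nf)
  class(out) <- c("sc_sparsity", class(out))
  out
}

#' @export
autoplot.sc_sparsity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pct_nonzero)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::labs(x = "% nonzero activation coefficients per feature map",
                  y = "number of features",
                  title = "Feature-map sparsity distribution")
}

#' Write / read a sparse code as a plain-text coordinate list
#'
#' Header lines (prefixed `#`) carry the geometry (image dimensions,
#' stride, padding, lambda, iterations); the body is CSV with columns
#' `feature,row,col,value`, one line per nonzero coefficient, 1-based
#' indices.
#'
#' @param code a `sparse_code`.
#' @param path file path.
#' @return `write_sparse_code` returns `path` invisibly; `read_sparse_code`
#'   returns the code.
#' @export
write_sparse_code <- function(code, path) {
  stopifnot(inherits(code, "sparse_code"))
  g <- code$geometry
  d <- dim(code$maps)
  nz <- which(code$maps != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# image_dim: %s", paste(g$image_dim, collapse = " ")),
    sprintf("# map_dim: %s", paste(d, collapse = " ")),
    sprintf("# stride: %d", g$stride),
    sprintf("# pad: %d", g$pad),
    sprintf("# lambda: %.17g", code$lambda),
    sprintf("# n_iterations: %d", code$n_iterations),
    "feature,row,col,value"), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d,%d,%d,%.17g", nz[, 3], nz[, 1], nz[, 2],
                       code$maps[nz]), con)
  }
  invisible(path)
}

#' @rdname write_sparse_code
#' @export
read_sparse_code <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(sprintf("^# %s: ", key), "", grep(paste0("^# ", key, ":"), hdr,
                                               value = TRUE))
    as.numeric(strsplit(v, " ")[[1]])
  }
  map_dim <- as.integer(get("map_dim"))
  maps <- array(0, map_dim)
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = body)
  if (nrow(df) > 0) maps[cbind(df$row, df$col, df$feature)] <- df$value
  new_sparse_code(maps, lambda = get("lambda"),
                  n_iterations = as.integer(get("n_iterations")),
                  image_dim = as.integer(get("image_dim")),
                  stride = as.integer(get("stride")),
                  pad = as.integer(get("pad")))
}
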