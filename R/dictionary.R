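#' Convolutional feature dictionary
#'
#' A set of square convolutional feature kernels replicated across the
#' image at a fixed stride. Kernels are stored as a
#' `[kh, kw, channels, n_features]` array; when `normalized` is `TRUE`
#' every kernel has unit Euclidean norm.
#'
#' @param kernels numeric array `[kh, kw, channels, n_features]`.
#' @param stride replication stride in pixels (same in both axes).
#' @param normalized logical; are kernels unit-norm?
#' @param meta optional list of provenance metadata.
#' @return An object of class `sc_dictionary`.
#' @export
sc_dictionary <- function(kernels, stride, normalized = FALSE, meta = list()) {
  d <- dim(kernels)
  if (length(d) != 4L) abort("`kernels` must be [kh, kw, channels, n_features].")
  if (d[1] != d[2]) abort("kernels must be square (kh == kw).")
  if (!is_count(stride)) abort("`stride` must be a positive integer.")
  structure(
    list(kernels = kernels, stride = as.integer(stride),
         normalized = isTRUE(normalized), meta = meta),
    class = "sc_dictionary"
  )
}

#' @export
print.sc_dictionary <- function(x, ...) {
  d <- dim(x$kernels)
  cat(sprintf("<sc_dictionary: %d kernels %dx%dx%d, stride %d%s>\n",
              d[4], d[1], d[2], d[3], x$stride,
              if (x$normalized) ", unit-norm" else ""))
  invisible(x)
}

n_features <- function(dict) dim(dict$kernels)[4]
kernel_side <- function(dict) dim(dict$kernels)[1]
kernel_channels <- function(dict) dim(dict$kernels)[3]

# Kernels flattened to a (kh*kw*channels) x n_features matrix; the layout
# the C++ operators consume.
kernel_matrix <- function(dict) {
  d <- dim(dict$kernels)
  matrix(dict$kernels, nrow = prod(d[1:3]), ncol = d[4])
}

kernel_norms <- function(dict) {
  sqrt(colSums(kernel_matrix(dict)^2))
}

#' Rescale every kernel to unit Euclidean norm
#'
#' @param dict an [sc_dictionary()].
#' @return The dictionary with `normalized = TRUE`.
#' @export
normalize_dictionary <- function(dict) {
  stopifnot(inherits(dict, "sc_dictionary"))
  nrm <- kernel_norms(dict)
  nrm[nrm < 1e-12] <- 1
  dict$kernels <- sweep(dict$kernels, 4, nrm, `/`)
  dict$normalized <- TRUE
  dict
}

# Seeded random dictionary; `smooth` low-pass filters each kernel so
# planted atoms have image-like spatial coherence.
random_dictionary <- function(n_features, kernel, channels, stride,
                              smooth = FALSE) {
  kn <- array(rnorm(kernel * kernel * channels * n_features),
              c(kernel, kernel, channels, n_features))
  if (smooth && kernel >= 4) {
    for (f in seq_len(n_features)) {
      for (ch in seq_len(channels)) {
        kn[, , ch, f] <- EBImage::gblur(kn[, , ch, f], sigma = kernel / 8)
      }
    }
  }
  normalize_dictionary(sc_dictionary(kn, stride))
}

#' Training configuration for dictionary learning
#'
#' Defaults follow the full-scale pipeline: 512 kernels of 32 x 32 x 3
#' pixels replicated at stride 4.
#'
#' @param n_features dictionary size.
#' @param kernel kernel side in pixels.
#' @param channels image channels.
#' @param stride replication stride.
#' @param lambda L1 sparsity tradeoff used during inference.
#' @param learning_rate SGD step size, applied to the activation-power
#'   normalized Hebbian gradient (see [hebbian_update()]); decays as
#'   1/epoch.
#' @param batch_size tiles per update (1 = true SGD).
#' @param n_epochs passes over the corpus.
#' @param seed integer RNG seed.
#' @param normalize_every renormalize kernels after this many updates.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_features = 512, kernel = 32, channels = 3,
                         stride = 4, lambda = 0.15, learning_rate = 0.5,
                         batch_size = 1, n_epochs = 5, seed = 1,
                         normalize_every = 1) {
  if (learning_rate < 0) abort("`learning_rate` must be non-negative.")
  if (!is_count(n_features)) abort("`n_features` must be >= 1.")
  structure(
    list(n_features = as.integer(n_features), kernel = as.integer(kernel),
         channels = as.integer(channels), stride = as.integer(stride),
         lambda = lambda, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), n_epochs = as.integer(n_epochs),
         seed = as.integer(seed), normalize_every = as.integer(normalize_every)),
    class = "train_config"
  )
}

#' Initialize a dictionary from a training configuration
#'
#' Kernels are drawn from a seeded standard normal and unit-normalized.
#'
#' @param cfg a [train_config()].
#' @return An [sc_dictionary()].
#' @export
init_dictionary <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  with_seed(cfg$seed, {
    random_dictionary(cfg$n_features, cfg$kernel, cfg$channels, cfg$stride)
  })
}

#' Save / load a dictionary
#'
#' Dictionaries are serialized with [saveRDS()]: a plain list with the
#' `kernels` array `[kh, kw, channels, n_features]`, integer `stride`,
#' logical `normalized`, and a `meta` list, so other R tools can read the
#' layout directly.
#'
#' @param dict an [sc_dictionary()].
#' @param path file path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns the dictionary.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "sc_dictionary"))
  saveRDS(unclass(dict), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- readRDS(path)
  sc_dictionary(x$kernels, x$stride, x$normalized, x$meta)
}

#' Mosaic plot of dictionary kernels
#'
#' Renders each kernel as an RGB patch (rescaled to `[0, 1]` per kernel)
#' arranged on a near-square grid, the standard way learned dictionaries
#' are inspected.
#'
#' @param object an [sc_dictionary()].
#' @param max_kernels cap on the number of kernels shown.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sc_dictionary <- function(object, max_kernels = 64, ...) {
  d <- dim(object$kernels)
  nf <- min(d[4], max_kernels)
  ncol_grid <- ceiling(sqrt(nf))
  df <- purrr::map_dfr(seq_len(nf), function(f) {
    kn <- object$kernels[, , , f, drop = FALSE]
    rng <- range(kn)
    kn <- (kn - rng[1]) / max(rng[2] - rng[1], 1e-12)
    grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    tibble::tibble(
      feature = f,
      gx = (f - 1) %% ncol_grid, gy = (f - 1) %/% ncol_grid,
      row = grid$row, col = grid$col,
      fill = grDevices::rgb(kn[cbind(grid$row, grid$col, 1, 1)],
                            kn[cbind(grid$row, grid$col, min(2, d[3]), 1)],
                            kn[cbind(grid$row, grid$col, min(3, d[3]), 1)])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gx * (d[2] + 2) + .data$col,
    y = -(.data$gy * (d[1] + 2) + .data$row))) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Dictionary kernels (%d of %d)", nf, d[4]))
}
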