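#' Pool a sparse code to a fixed-length descriptor
#'
#' `average_pool` takes the plain mean of every feature map (zeros
#' included, so the value reflects both how often and how strongly a
#' feature fires); `max_pool` takes the coefficient of largest magnitude
#' with its sign retained; `histogram_pool` bins the nonzero coefficients
#' of each map over fixed edges and concatenates the per-feature counts.
#'
#' @param code a `sparse_code`.
#' @param nonzero_only for `average_pool`: average over nonzero
#'   coefficients only (0 when a map is empty) instead of the plain mean.
#' @return A numeric vector of length `n_features` (or
#'   `n_features * bins` for `histogram_pool`), with attribute `pooling`.
#' @export
average_pool <- function(code, nonzero_only = FALSE) {
  stopifnot(inherits(code, "sparse_code"))
  d <- dim(code$maps)
  if (d[1] == 0 || d[2] == 0) abort("empty feature maps.")
  m <- matrix(code$maps, ncol = d[3])
  v <- if (nonzero_only) {
    nz <- colSums(m != 0)
    ifelse(nz > 0, colSums(m) / pmax(nz, 1), 0)
  } else {
    colMeans(m)
  }
  structure(as.numeric(v), pooling = "average")
}

#' @rdname average_pool
#' @export
max_pool <- function(code) {
  stopifnot(inherits(code, "sparse_code"))
  d <- dim(code$maps)
  if (d[1] == 0 || d[2] == 0) abort("empty feature maps.")
  m <- matrix(code$maps, ncol = d[3])
  idx <- max.col(t(abs(m)), ties.method = "first")
  structure(m[cbind(idx, seq_len(d[3]))], pooling = "max")
}

#' @rdname average_pool
#' @param bins number of histogram bins per feature.
#' @param edges bin edges (length `bins + 1`); defaults to 16 uniform bins
#'   over plus/minus three standard deviations of this code's nonzero
#'   coefficients — compute them once on training codes with
#'   [histogram_edges()] and pass them in for a consistent feature space.
#' @export
histogram_pool <- function(code, bins = 16, edges = NULL) {
  stopifnot(inherits(code, "sparse_code"))
  d <- dim(code$maps)
  if (d[1] == 0 || d[2] == 0) abort("empty feature maps.")
  if (is.null(edges)) edges <- histogram_edges(list(code), bins)
  bins <- length(edges) - 1L
  m <- matrix(code$maps, ncol = d[3])
  out <- vapply(seq_len(d[3]), function(f) {
    x <- m[, f]
    x <- x[x != 0]
    x <- pmin(pmax(x, edges[1]), edges[length(edges)])
    if (length(x) == 0) return(numeric(bins))
    tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
  }, numeric(bins))
  structure(as.numeric(out), pooling = "histogram", edges = edges)
}

#' Histogram bin edges from training codes
#'
#' Sixteen (by default) uniform bins spanning plus/minus three standard
#' deviations of the pooled nonzero coefficients.
#'
#' @param codes list of `sparse_code` objects.
#' @param bins number of bins.
#' @return Numeric vector of `bins + 1` edges.
#' @export
histogram_edges <- function(codes, bins = 16) {
  vals <- unlist(lapply(codes, function(cd) cd$maps[cd$maps != 0]))
  s <- if (length(vals) > 1) sd(vals) else 1
  if (!is.finite(s) || s == 0) s <- 1
  seq(-3 * s, 3 * s, length.out = bins + 1)
}

#' Pool a set of codes into a labeled feature table
#'
#' @param codes list of `sparse_code` objects (one per tile).
#' @param manifest optional tibble with one row per code carrying
#'   `tile_id`, `label`, `group_id`; defaults to the names of `codes`.
#' @param method pooling variant.
#' @param ... passed to the pooling function.
#' @return A tibble: `tile_id`, `label`, `group_id`, then feature columns
#'   `f1 ... fn`.
#' @export
pool_features <- function(codes, manifest = NULL,
                          method = c("average", "max", "histogram"), ...) {
  method <- match.arg(method)
  pooler <- switch(method, average = average_pool, max = max_pool,
                   histogram = histogram_pool)
  extra <- list(...)
  if (method == "histogram" && is.null(extra$edges)) {
    extra$edges <- histogram_edges(codes, bins = extra$bins %||% 16)
    extra$bins <- NULL
  }
  vecs <- lapply(codes, function(cd) do.call(pooler, c(list(cd), extra)))
  feat <- do.call(rbind, vecs)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  if (is.null(manifest)) {
    manifest <- tibble::tibble(
      tile_id = names(codes) %||% sprintf("tile_%03d", seq_along(codes)),
      label = NA_integer_, group_id = NA_character_)
  }
  dplyr::bind_cols(manifest[, intersect(c("tile_id", "label", "group_id"),
                                        names(manifest))],
                   tibble::as_tibble(feat))
}

feature_columns <- function(features) {
  grep("^f[0-9]+$", names(features), value = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
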