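#' Otsu binarization of a grayscale image
#'
#' Picks the threshold that maximizes the between-class variance of a
#' 256-bin histogram and marks pixels darker than the threshold as tissue.
#' Inputs may be in `[0, 1]` or 8-bit (`0..255`); 8-bit input is rescaled
#' to `[0, 1]`. Bin `b` collects values in `[b/256, (b+1)/256)`; a split
#' after bin `k` corresponds to the threshold `(k+1)/256`, and ties are
#' broken toward the smallest `k`.
#'
#' @param gray numeric matrix.
#' @return A list with `threshold` (gray level) and `mask` (logical matrix,
#'   `TRUE` = tissue/dark).
#' @export
binarize_otsu <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray)) abort("`gray` must be a numeric matrix.")
  if (max(gray) > 1) gray <- gray / 255
  if (length(unique(as.vector(gray))) < 2L) abort("degenerate histogram")
  bins <- pmin(floor(gray * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  w <- h / sum(h)
  omega0 <- cumsum(w)
  mu_bin <- cumsum(w * (0:255))
  mu_total <- mu_bin[256]
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_total * omega0[valid] - mu_bin[valid])^2 /
    (omega0[valid] * omega1[valid])
  k <- which.max(sigma_b)  # first maximum: smallest-k tie-break
  threshold <- k / 256     # split after bin k-1 (1-based which.max)
  list(threshold = threshold, mask = gray < threshold)
}

#' Sliding-window tissue density via FFT convolution
#'
#' The fraction of tissue pixels inside every possible `window x window`
#' box, computed as a zero-padded FFT convolution of the binary mask with a
#' box kernel. Values are rounded to 12 decimals so the FFT path agrees
#' exactly with direct counting.
#'
#' @param mask logical (or 0/1 numeric) matrix, `TRUE` = tissue.
#' @param window box side in pixels.
#' @return A `(H - window + 1) x (W - window + 1)` matrix of densities in
#'   `[0, 1]`, value `[y, x]` for the box anchored at top-left `(y, x)`;
#'   attribute `window` records the box side.
#' @export
window_density_fft <- function(mask, window) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  window <- as.integer(window)
  if (window < 1 || window > H || window > W) {
    abort("`window` must be between 1 and the mask dimensions.")
  }
  P <- stats::nextn(H + window - 1)
  Q <- stats::nextn(W + window - 1)
  mp <- matrix(0, P, Q); mp[1:H, 1:W] <- m
  kp <- matrix(0, P, Q); kp[1:window, 1:window] <- 1
  conv <- Re(fft(fft(mp) * fft(kp), inverse = TRUE)) / (P * Q)
  dens <- conv[window:H, window:W, drop = FALSE] / window^2
  dens <- round(dens, 12)
  structure(dens, window = window)
}

#' Greedy selection of the densest non-overlapping windows
#'
#' Repeatedly takes the global maximum of the density map, then invalidates
#' every position whose window would overlap the chosen one, until `n`
#' regions are found, the map is exhausted, or the best remaining density
#' falls below `min_density`. Ties at the maximum go to the smallest
#' row-major index (row first, then column).
#'
#' @param density matrix from [window_density_fft()].
#' @param n maximum number of regions.
#' @param window box side in pixels (defaults to the map's `window`
#'   attribute).
#' @param min_density discard floor; regions below it are never selected.
#' @return A tibble with columns `rank`, `level_x`, `level_y` (0-based
#'   top-left, x = column), `level_window`, `density`; densities
#'   non-increasing in rank.
#' @export
select_rois <- function(density, n, window = attr(density, "window"),
                        min_density = 0.05) {
  if (!is_count(n)) abort("`n` must be >= 1.")
  if (is.null(window)) abort("`window` must be supplied.")
  d <- round(unclass(density), 12)
  H <- nrow(d); W <- ncol(d)
  out <- vector("list", n)
  for (rank in seq_len(n)) {
    best <- max(d)
    if (!is.finite(best) || best < min_density) break
    ties <- which(d == best, arr.ind = TRUE)
    pick <- ties[order((ties[, 1] - 1) * W + ties[, 2])[1], , drop = TRUE]
    r <- unname(pick[1]); c <- unname(pick[2])
    out[[rank]] <- tibble::tibble(rank = rank, level_x = c - 1L,
                                  level_y = r - 1L,
                                  level_window = as.integer(window),
                                  density = best)
    rr <- max(1, r - window + 1):min(H, r + window - 1)
    cc <- max(1, c - window + 1):min(W, c + window - 1)
    d[rr, cc] <- -Inf
  }
  dplyr::bind_rows(out)
}

#' Lift an ROI to full resolution and extract a fixed-size tile
#'
#' Maps the selection-level coordinates to level 0, clamps the window to
#' the slide extent (shifting inward, never shrinking), crops, and
#' resamples so the tile is `target` pixels square at the equivalent of
#' `target_power` magnification: the level-0 crop side is
#' `round(target * objective_power / target_power)`, area-averaged down or
#' bilinearly up to `target`.
#'
#' @param slide a [slide_image()].
#' @param roi one row of the tibble from [select_rois()].
#' @param level index of the selection level within `slide$levels`.
#' @param target output tile side in pixels.
#' @param target_power output magnification equivalent.
#' @return The RGB tile, with attributes `full_x`, `full_y`, `full_window`
#'   (0-based level-0 coordinates of the crop).
#' @export
lift_and_extract <- function(slide, roi, level = length(slide$levels),
                             target = 2048, target_power = 20) {
  stopifnot(inherits(slide, "slide_image"))
  op <- slide$objective_power
  if (is.na(op)) {
    warn("objective power missing; assuming 20X.")
    op <- 20
  }
  full_side <- as.integer(round(target * op / target_power))
  dL <- slide$level_downsamples[level]
  lvl0 <- slide$levels[[1]]
  H0 <- dim(lvl0)[1]; W0 <- dim(lvl0)[2]
  if (full_side > H0 || full_side > W0) abort("tile larger than the slide.")
  fx <- round(roi$level_x * dL)
  fy <- round(roi$level_y * dL)
  fx <- min(max(0, fx), W0 - full_side)
  fy <- min(max(0, fy), H0 - full_side)
  crop <- lvl0[(fy + 1):(fy + full_side), (fx + 1):(fx + full_side), ,
               drop = FALSE]
  tile <- resample_rgb(crop, target)
  attr(tile, "full_x") <- as.integer(fx)
  attr(tile, "full_y") <- as.integer(fy)
  attr(tile, "full_window") <- full_side
  tile
}

#' Extract the densest ROIs of a slide as fixed-size tiles
#'
#' The full pipeline of one slide: grayscale conversion (Rec. 709
#' luminance) of the lowest-resolution level, Otsu binarization, FFT
#' window density, greedy non-overlapping selection, and full-resolution
#' tile extraction.
#'
#' @param slide a [slide_image()].
#' @param n maximum number of ROIs (default 4).
#' @param tile output tile side in pixels.
#' @param target_power output magnification equivalent.
#' @param min_density density floor below which regions are discarded.
#' @param slide_id identifier used in the manifest and error messages.
#' @return A list of class `roi_set`: `tiles` (list of RGB arrays) and
#'   `manifest` (tibble: slide_id, rank, level_x, level_y, level_window,
#'   full_x, full_y, full_window, density).
#' @export
extract_slide_rois <- function(slide, n = 4, tile = 2048, target_power = 20,
                               min_density = 0.05, slide_id = "slide") {
  stopifnot(inherits(slide, "slide_image"))
  level <- length(slide$levels)
  lowres <- slide$levels[[level]]
  bin <- tryCatch(binarize_otsu(luminance(lowres)), error = function(e) {
    abort(sprintf("%s [slide %s]", conditionMessage(e), slide_id))
  })
  op <- slide$objective_power
  if (is.na(op)) op <- 20
  full_side <- round(tile * op / target_power)
  window <- max(1L, as.integer(round(full_side / slide$level_downsamples[level])))
  dens <- window_density_fft(bin$mask, window)
  rois <- select_rois(dens, n = n, window = window, min_density = min_density)
  if (nrow(rois) == 0) {
    return(structure(list(tiles = list(), manifest = tibble::tibble()),
                     class = "roi_set"))
  }
  tiles <- vector("list", nrow(rois))
  meta <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    t_i <- lift_and_extract(slide, rois[i, ], level = level, target = tile,
                            target_power = target_power)
    tiles[[i]] <- t_i
    meta[[i]] <- tibble::tibble(full_x = attr(t_i, "full_x"),
                                full_y = attr(t_i, "full_y"),
                                full_window = attr(t_i, "full_window"))
  }
  manifest <- dplyr::bind_cols(
    tibble::tibble(slide_id = slide_id), rois, dplyr::bind_rows(meta))
  names(tiles) <- sprintf("%s_roi%d", slide_id, rois$rank)
  structure(list(tiles = tiles, manifest = manifest), class = "roi_set")
}
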