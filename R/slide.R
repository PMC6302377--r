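#' Multi-resolution slide image container
#'
#' A lightweight in-memory stand-in for a pyramidal whole-slide image: a
#' list of RGB rasters ordered from highest to lowest resolution, the
#' downsample factor of each level relative to level 0, and the nominal
#' objective magnification of level 0.
#'
#' @param levels list of `H x W x 3` numeric arrays in `[0, 1]`, highest
#'   resolution first.
#' @param level_downsamples numeric vector, one factor per level relative to
#'   level 0; strictly increasing, first element 1.
#' @param objective_power nominal magnification of level 0 (e.g. 20 or 40),
#'   or `NA` if unknown.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(levels, level_downsamples = 1, objective_power = NA) {
  if (!is.list(levels) || length(levels) == 0) {
    abort("`levels` must be a non-empty list of RGB arrays.")
  }
  level_downsamples <- as.numeric(level_downsamples)
  if (length(level_downsamples) != length(levels)) {
    abort("one downsample factor per level is required.")
  }
  if (level_downsamples[1] != 1 || is.unsorted(level_downsamples, strictly = TRUE)) {
    abort("`level_downsamples` must be strictly increasing and start at 1.")
  }
  d0 <- dim(levels[[1]])
  for (i in seq_along(levels)) {
    di <- dim(levels[[i]])
    if (length(di) != 3L || di[3] != 3L) abort("each level must be H x W x 3.")
    expect_hw <- d0[1:2] / level_downsamples[i]
    if (any(abs(di[1:2] - expect_hw) > level_downsamples[i] + 1)) {
      abort("level dimensions inconsistent with downsample factors.")
    }
  }
  structure(
    list(levels = levels, level_downsamples = level_downsamples,
         objective_power = objective_power),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d0 <- dim(x$levels[[1]])
  cat(sprintf("<slide_image: %d x %d px, %d level(s), objective %s>\n",
              d0[1], d0[2], length(x$levels),
              ifelse(is.na(x$objective_power), "unknown",
                     paste0(x$objective_power, "X"))))
  invisible(x)
}

#' Read a single-level slide image from PNG or TIFF
#'
#' Flat PNG/TIFF rasters are treated as one-level slides with a stated
#' objective power; pyramidal SVS input is out of scope.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param objective_power nominal magnification of the raster (default 20).
#' @return A `slide_image` with a single level.
#' @export
read_slide <- function(path, objective_power = 20) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = suppressWarnings(EBImage::imageData(EBImage::transpose(
      EBImage::readImage(path)))),
    abort("only PNG and TIFF input is supported.")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  slide_image(list(clamp01(img)), 1, objective_power)
}

# Resample an H x W x 3 array to side `target` pixels: area averaging
# (block mean) for integer-factor downscales, bilinear otherwise.
resample_rgb <- function(img, target) {
  h <- dim(img)[1]
  if (h == target) return(img)
  if (h > target && h %% target == 0) return(block_mean(img, h %/% target))
  out <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                         w = target, h = target, filter = "bilinear",
                         antialias = h > target)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}
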