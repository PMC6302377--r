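#' Configuration for the synthetic stain-texture generator
#'
#' The generator emulates the gross statistics of hematoxylin-and-eosin
#' pathology slides: a near-white background, several dark tissue regions,
#' pink-textured stroma, and dark-purple nuclei rendered as small disks.
#' The two tissue classes differ only in nucleus density (dots per 1000
#' square pixels); the 3x default gap between the normal and tumor
#' densities is the planted separability the downstream classifiers must
#' recover.
#'
#' @param canvas_size pixels per side of the slide canvas.
#' @param n_blobs number of tissue regions on the slide.
#' @param blob_radius_range two pixels, min and max tissue-disk radius.
#' @param class_label 0 (normal) or 1 (tumor).
#' @param nucleus_density nuclei per 1000 square pixels of tissue; defaults
#'   to 5 for class 0 and 15 for class 1.
#' @param stain_palette list with RGB triples `hematoxylin` (dark purple,
#'   nuclei) and `eosin` (pink, stroma), values in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(canvas_size = 1024, n_blobs = 4,
                         blob_radius_range = c(80, 160),
                         class_label = 0,
                         nucleus_density = if (class_label == 1) 15 else 5,
                         stain_palette = list(
                           hematoxylin = c(0.35, 0.22, 0.55),
                           eosin = c(0.91, 0.65, 0.76)),
                         noise_sd = 0.02, seed = 1) {
  if (!is_count(canvas_size) || canvas_size <= 0) {
    abort("`canvas_size` must be a positive integer.")
  }
  if (!is.numeric(n_blobs) || n_blobs < 0) abort("`n_blobs` must be >= 0.")
  if (!is.numeric(nucleus_density) || nucleus_density < 0) {
    abort("`nucleus_density` must be non-negative.")
  }
  if (!class_label %in% c(0, 1)) abort("`class_label` must be 0 or 1.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(
    list(canvas_size = as.integer(canvas_size), n_blobs = as.integer(n_blobs),
         blob_radius_range = as.numeric(blob_radius_range),
         class_label = as.integer(class_label),
         nucleus_density = nucleus_density, stain_palette = stain_palette,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Pink stroma texture: eosin base plus low-pass filtered Gaussian noise.
render_stroma <- function(h, w, eosin, amplitude = 0.08, sigma = 4) {
  t1 <- EBImage::gblur(matrix(rnorm(h * w), h, w), sigma = sigma)
  t1 <- t1 / max(sd(t1), 1e-12)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) out[, , ch] <- clamp01(eosin[ch] + amplitude * t1)
  out
}

# Stamp anti-aliased dark-purple disks at `n` positions sampled uniformly
# from the TRUE pixels of `mask`. Radii are uniform on `radius_range`.
# `clip_alpha` (same shape as mask) confines disks to the tissue region so
# nuclei near a blob edge never paint onto the white background.
add_nuclei <- function(img, mask, n, hematoxylin, radius_range = c(2, 5),
                       clip_alpha = NULL) {
  if (n <= 0) return(img)
  idx <- which(mask)
  if (length(idx) == 0) return(img)
  h <- nrow(mask)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  rows <- (pick - 1) %% h + 1
  cols <- (pick - 1) %/% h + 1
  radii <- runif(n, radius_range[1], radius_range[2])
  jitter <- matrix(runif(3 * n, -0.05, 0.05), nrow = n)
  H <- nrow(mask); W <- ncol(mask)
  for (q in seq_len(n)) {
    r <- radii[q]
    rr <- max(1, floor(rows[q] - r - 1)):min(H, ceiling(rows[q] + r + 1))
    cc <- max(1, floor(cols[q] - r - 1)):min(W, ceiling(cols[q] + r + 1))
    d <- sqrt(outer((rr - rows[q])^2, (cc - cols[q])^2, `+`))
    alpha <- clamp01(r + 0.5 - d)
    if (!is.null(clip_alpha)) alpha <- alpha * clip_alpha[rr, cc]
    col_q <- clamp01(hematoxylin + jitter[q, ])
    for (ch in 1:3) {
      img[rr, cc, ch] <- (1 - alpha) * img[rr, cc, ch] + alpha * col_q[ch]
    }
  }
  img
}

# Soft-edged union of disks; returns list(alpha matrix, mask = alpha >= 0.5).
place_blobs <- function(canvas, n_blobs, radius_range) {
  alpha <- matrix(0, canvas, canvas)
  centers <- matrix(numeric(0), ncol = 3)  # row, col, radius
  max_r <- (canvas - 2) / 2
  for (b in seq_len(n_blobs)) {
    r <- min(runif(1, radius_range[1], radius_range[2]), max_r)
    ok <- FALSE
    for (try in 1:50) {
      cy <- runif(1, r + 1, canvas - r)
      cx <- runif(1, r + 1, canvas - r)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              0.9 * (centers[, 3] + r))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next  # canvas too crowded; place fewer blobs
    centers <- rbind(centers, c(cy, cx, r))
    rr <- max(1, floor(cy - r - 1)):min(canvas, ceiling(cy + r + 1))
    cc <- max(1, floor(cx - r - 1)):min(canvas, ceiling(cx + r + 1))
    d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, `+`))
    alpha[rr, cc] <- pmax(alpha[rr, cc], clamp01(r + 0.5 - d))
  }
  list(alpha = alpha, mask = alpha >= 0.5, centers = centers)
}

#' Generate a synthetic slide with ground-truth tissue mask
#'
#' Renders a white canvas with `n_blobs` soft-edged tissue disks filled with
#' pink stroma texture and nucleus dots, wraps it as a two-level
#' [slide_image()] (full resolution plus a 4x area-averaged thumbnail), and
#' attaches the exact tissue mask used during rendering.
#'
#' @param cfg a [synth_config()].
#' @return A `slide_image` with extra fields `blob_mask` (level-0 logical
#'   matrix) and `config`.
#' @export
generate_slide <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$canvas_size < 256) abort("`canvas_size` must be at least 256.")
  with_seed(cfg$seed, {
    n <- cfg$canvas_size
    img <- array(0.98, c(n, n, 3))
    blobs <- place_blobs(n, cfg$n_blobs, cfg$blob_radius_range)
    if (nrow(blobs$centers) > 0) {
      stroma <- render_stroma(n, n, cfg$stain_palette$eosin)
      a <- blobs$alpha
      for (ch in 1:3) {
        img[, , ch] <- (1 - a) * img[, , ch] + a * stroma[, , ch]
      }
      n_nuclei <- round(cfg$nucleus_density * sum(blobs$mask) / 1000)
      img <- add_nuclei(img, blobs$mask, n_nuclei,
                        cfg$stain_palette$hematoxylin,
                        clip_alpha = blobs$alpha)
    }
    if (cfg$noise_sd > 0) {
      img <- clamp01(img + array(rnorm(length(img), sd = cfg$noise_sd), dim(img)))
    }
    thumb <- block_mean(img, 4L)
    out <- slide_image(list(img, thumb), c(1, 4), objective_power = 20)
    out$blob_mask <- blobs$mask
    out$config <- cfg
    out
  })
}

# One full-tissue tile (stroma + nuclei everywhere), emulating an ROI cut
# from inside a tissue region.
generate_tile <- function(cfg, tile, seed) {
  with_seed(seed, {
    img <- render_stroma(tile, tile, cfg$stain_palette$eosin)
    n_nuclei <- round(cfg$nucleus_density * tile * tile / 1000)
    img <- add_nuclei(img, matrix(TRUE, tile, tile), n_nuclei,
                      cfg$stain_palette$hematoxylin)
    if (cfg$noise_sd > 0) {
      img <- clamp01(img + array(rnorm(length(img), sd = cfg$noise_sd), dim(img)))
    }
    img
  })
}

#' Generate a labeled two-class tile dataset
#'
#' Produces `2 * n_per_class` full-tissue RGB tiles, class-balanced, with
#' synthetic group IDs emulating patients: tiles within one group share a
#' base placement seed, so grouped and ungrouped train/test splits can be
#' compared. Class 0 tiles follow `cfg0`, class 1 tiles `cfg1`.
#'
#' @param n_per_class tiles per class (>= 1).
#' @param cfg0,cfg1 [synth_config()] for class 0 / class 1.
#' @param tile pixels per tile side.
#' @param seed dataset-level RNG seed.
#' @param group_size tiles per synthetic patient (default 4, matching four
#'   ROIs per slide).
#' @return A list of class `tile_dataset` with `tiles` (list of arrays) and
#'   `manifest` (tibble: tile_id, label, group_id, seed).
#' @export
generate_tile_dataset <- function(n_per_class, cfg0 = synth_config(class_label = 0),
                                  cfg1 = synth_config(class_label = 1),
                                  tile = 256, seed = 1, group_size = 4) {
  if (!is_count(n_per_class)) abort("`n_per_class` must be a positive integer.")
  if (identical(cfg0$seed, cfg1$seed) && identical(cfg0$seed, as.integer(seed))) {
    warn("cfg0, cfg1 and dataset seeds coincide; tiles may repeat patterns.")
  }
  rows <- purrr::map_dfr(c(0L, 1L), function(lab) {
    cfg <- if (lab == 0L) cfg0 else cfg1
    tibble::tibble(
      idx = seq_len(n_per_class),
      label = lab,
      group_id = sprintf("c%d_g%03d", lab, (idx - 1) %/% group_size + 1),
      seed = mapply(function(g, i) derive_seed(seed, lab, g, i),
                    (idx - 1) %/% group_size + 1, idx)
    )
  })
  rows <- dplyr::mutate(rows,
    tile_id = sprintf("tile_%03d_c%d", dplyr::row_number(), .data$label))
  cfgs <- list(cfg0, cfg1)
  tiles <- purrr::pmap(list(rows$label, rows$seed), function(lab, sd) {
    generate_tile(cfgs[[lab + 1L]], tile, sd)
  })
  names(tiles) <- rows$tile_id
  structure(
    list(tiles = tiles,
         manifest = dplyr::select(rows, "tile_id", "label", "group_id", "seed")),
    class = "tile_dataset"
  )
}

#' Write a tile dataset to PNG files plus a CSV manifest
#'
#' @param dataset a `tile_dataset` from [generate_tile_dataset()].
#' @param dir output directory (created if missing).
#' @return The manifest tibble, invisibly, with a `file` column added.
#' @export
write_tile_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tile_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dplyr::mutate(dataset$manifest,
                       file = file.path(dir, paste0(.data$tile_id, ".png")))
  purrr::walk2(dataset$tiles, man$file, function(img, f) {
    png::writePNG(clamp01(img), f)
  })
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Generate a planted sparse-coding instance
#'
#' Draws a random unit-norm convolutional dictionary, samples sparse codes
#' with an exact number of nonzero coefficients, and synthesizes images as
#' the linear reconstruction plus optional Gaussian noise. Because the
#' generating dictionary and codes are known, these instances serve as
#' ground truth for inference and dictionary-recovery experiments.
#'
#' @param n_images number of images.
#' @param n_features dictionary size.
#' @param kernel_size kernel side in pixels.
#' @param stride replication stride in pixels.
#' @param sparsity_fraction fraction of map coefficients that are nonzero,
#'   in `(0, 0.1]`.
#' @param noise_sd additive Gaussian noise sd (0 for exact instances).
#' @param seed integer RNG seed.
#' @param image_size image side in pixels (default 32).
#' @param channels image channels (default 3).
#' @return A list of class `planted_instance` with `dictionary`, `codes`
#'   (list of `sparse_code`), and `images` (list of arrays; linear
#'   reconstructions, not clamped to `[0, 1]`).
#' @export
generate_planted <- function(n_images, n_features, kernel_size, stride,
                             sparsity_fraction = 0.02, noise_sd = 0, seed = 1,
                             image_size = 32, channels = 3) {
  if (sparsity_fraction <= 0 || sparsity_fraction > 0.1) {
    abort("`sparsity_fraction` must be in (0, 0.1].")
  }
  if (kernel_size > image_size) abort("`kernel_size` exceeds image size.")
  with_seed(seed, {
    dict <- random_dictionary(n_features, kernel_size, channels, stride,
                              smooth = TRUE)
    mh <- map_side(image_size, stride)
    nnz <- round(sparsity_fraction * mh * mh * n_features)
    codes <- vector("list", n_images)
    images <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      maps <- array(0, c(mh, mh, n_features))
      at <- sample.int(length(maps), nnz)
      maps[at] <- sample(c(-1, 1), nnz, replace = TRUE) * runif(nnz, 0.5, 1.5)
      code <- new_sparse_code(maps, lambda = NA_real_, n_iterations = 0L,
                              image_dim = c(image_size, image_size, channels),
                              stride = stride,
                              pad = lca_padding(kernel_size, stride))
      img <- reconstruct(dict, code)
      if (noise_sd > 0) {
        img <- img + array(rnorm(length(img), sd = noise_sd), dim(img))
      }
      codes[[i]] <- code
      images[[i]] <- img
    }
    structure(list(true_dictionary = dict, codes = codes, images = images,
                   sparsity_fraction = sparsity_fraction, noise_sd = noise_sd),
              class = "planted_instance")
  })
}
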