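#' Hebbian dictionary update from one coded image
#'
#' Moves each kernel along the negative gradient of the reconstruction
#' error `0.5 * ||I - phi * a||^2`: the correlation of the residual with
#' that kernel's active coefficients, a local Hebbian rule. The step is
#' normalized by the code's total activation power `sum(a^2)`, which makes
#' `learning_rate` dimensionless — the same value behaves the same way on
#' a 32 px planted image and a full-size tile, where the raw gradient
#' (a sum over thousands of map positions) would otherwise diverge.
#' Kernels are renormalized to unit norm afterwards (disable with
#' `normalize = FALSE` when batching updates).
#'
#' @param dict an [sc_dictionary()].
#' @param image the (already centered, if applicable) image the code was
#'   inferred for.
#' @param code the `sparse_code` inferred for `(image, dict)`.
#' @param learning_rate SGD step size.
#' @param normalize renormalize kernels after the step.
#' @return The updated dictionary.
#' @export
hebbian_update <- function(dict, image, code, learning_rate,
                           normalize = TRUE) {
  stopifnot(inherits(dict, "sc_dictionary"), inherits(code, "sparse_code"))
  check_geometry(dict, code)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!all(dim(image) == code$geometry$image_dim)) {
    abort("image dimensions do not match the code geometry.")
  }
  if (learning_rate != 0 && any(code$maps != 0)) {
    g <- code$geometry
    G <- cs_dict_grad(image, code$maps, kernel_matrix(dict),
                      kernel_side(dict), g$stride, g$pad)
    step <- learning_rate / max(sum(code$maps^2), 1e-8)
    dict$kernels <- dict$kernels + step * array(G, dim(dict$kernels))
    dict$normalized <- FALSE
    if (normalize) dict <- normalize_dictionary(dict)
  }
  dict
}

#' Learn a convolutional dictionary by alternating inference and SGD
#'
#' Loops over epochs of the (seeded, shuffled) tile stream: LCA inference
#' of each tile's sparse code, then a Hebbian gradient step on the kernels,
#' with the learning rate decaying as `1/epoch`. Entirely unsupervised —
#' the function never sees labels. Tiles are centered (per-channel mean
#' subtracted) before both inference and the update.
#'
#' @param tiles a list of `H x W x C` arrays, or a `tile_dataset`.
#' @param cfg a [train_config()].
#' @param lca an [lca_config()] used for the inner inference; defaults to
#'   `lca_config(lambda = cfg$lambda)`.
#' @return A list of class `sc_dict_fit` with `dictionary` and `log`
#'   (`sc_train_log`: per-step and per-epoch tibbles).
#' @export
train_dictionary <- function(tiles, cfg,
                             lca = lca_config(lambda = cfg$lambda)) {
  stopifnot(inherits(cfg, "train_config"))
  if (inherits(tiles, "tile_dataset")) tiles <- tiles$tiles
  if (!is.list(tiles) || length(tiles) == 0) {
    abort("`tiles` must be a non-empty list of images.")
  }
  tiles <- lapply(tiles, function(img) {
    if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
    mu <- colMeans(matrix(img, ncol = dim(img)[3]))
    sweep(img, 3, mu, `-`)
  })
  dict <- init_dictionary(cfg)
  step_log <- vector("list", cfg$n_epochs * length(tiles))
  epoch_log <- vector("list", cfg$n_epochs)
  step <- 0L
  pending <- 0L
  with_seed(derive_seed(cfg$seed, 1), {
    for (epoch in seq_len(cfg$n_epochs)) {
      lr <- cfg$learning_rate / epoch
      order <- sample.int(length(tiles))
      for (ti in order) {
        img <- tiles[[ti]]
        code <- encode(img, dict, lca, center = FALSE)
        step <- step + 1L
        pending <- pending + 1L
        renorm <- pending >= cfg$normalize_every
        dict <- hebbian_update(dict, img, code, lr, normalize = renorm)
        if (renorm) pending <- 0L
        st <- attr(code, "lca_state")
        step_log[[step]] <- tibble::tibble(
          epoch = epoch, step = step,
          energy = st$energy_trace[length(st$energy_trace)],
          sparsity = mean(code$maps != 0))
      }
      if (pending > 0) {
        dict <- normalize_dictionary(dict)
        pending <- 0L
      }
      sl <- dplyr::bind_rows(step_log[(step - length(tiles) + 1):step])
      epoch_log[[epoch]] <- tibble::tibble(
        epoch = epoch, mean_energy = mean(sl$energy),
        mean_sparsity = mean(sl$sparsity),
        norm_drift = max(abs(kernel_norms(dict) - 1)))
    }
  })
  log <- structure(list(steps = dplyr::bind_rows(step_log),
                        epochs = dplyr::bind_rows(epoch_log)),
                   class = "sc_train_log")
  dict$meta <- c(dict$meta, list(trained = TRUE, config = cfg))
  structure(list(dictionary = dict, log = log), class = "sc_dict_fit")
}

#' @export
print.sc_dict_fit <- function(x, ...) {
  e <- x$log$epochs
  cat(sprintf("<sc_dict_fit: %d epochs, energy %.4g -> %.4g>\n",
              nrow(e), e$mean_energy[1], e$mean_energy[nrow(e)]))
  print(x$dictionary)
  invisible(x)
}

#' @export
glance.sc_dict_fit <- function(x, ...) {
  e <- x$log$epochs
  tibble::tibble(n_epochs = nrow(e), n_steps = nrow(x$log$steps),
                 initial_energy = e$mean_energy[1],
                 final_energy = e$mean_energy[nrow(e)],
                 final_sparsity = e$mean_sparsity[nrow(e)],
                 norm_drift = e$norm_drift[nrow(e)])
}

#' @export
tidy.sc_train_log <- function(x, ...) x$epochs

#' @export
autoplot.sc_train_log <- function(object, ...) {
  ggplot2::ggplot(object$steps, ggplot2::aes(x = .data$step, y = .data$energy)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(data = dplyr::summarise(
      dplyr::group_by(object$steps, .data$epoch),
      step = max(.data$step), energy = mean(.data$energy)),
      color = "firebrick", size = 2) +
    ggplot2::labs(x = "SGD step", y = "sparse-coding energy",
                  title = "Dictionary training curve",
                  subtitle = "red: epoch-mean energy")
}

#' Cosine similarity matching between two dictionaries
#'
#' For each kernel of `reference`, the best absolute cosine similarity over
#' all kernels of `learned` (sign- and permutation-invariant); used to
#' quantify planted-dictionary recovery.
#'
#' @param reference,learned [sc_dictionary()] objects with identical kernel
#'   geometry.
#' @return A tibble with `reference_kernel`, `matched_kernel`, `abs_cosine`.
#' @export
dictionary_similarity <- function(reference, learned) {
  A <- kernel_matrix(reference)
  B <- kernel_matrix(learned)
  if (nrow(A) != nrow(B)) abort("kernel geometries differ.")
  A <- sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-12), `/`)
  B <- sweep(B, 2, pmax(sqrt(colSums(B^2)), 1e-12), `/`)
  S <- abs(crossprod(A, B))
  tibble::tibble(reference_kernel = seq_len(ncol(A)),
                 matched_kernel = apply(S, 1, which.max),
                 abs_cosine = apply(S, 1, max))
}
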