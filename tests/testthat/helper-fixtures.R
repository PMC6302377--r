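# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 40 small two-class tiles, a briefly trained 16-atom dictionary, their
# sparse codes and pooled features; used by pooling and classification
# tests. ~10 s to build, reused everywhere.
small_pipeline <- function() {
  fixture("small_pipeline", function() {
    ds <- generate_tile_dataset(20, tile = 64, seed = 7)
    cfg <- train_config(n_features = 16, kernel = 8, stride = 4, lambda = 0.3,
                        learning_rate = 0.5, n_epochs = 2, seed = 3)
    lca <- lca_config(lambda = 0.3, dt_over_tau = 0.1, n_iterations = 60)
    fit <- train_dictionary(ds$tiles[1:10], cfg, lca = lca)
    codes <- lapply(ds$tiles, encode, dict = fit$dictionary, cfg = lca)
    list(dataset = ds, fit = fit, codes = codes,
         features = pool_features(codes, ds$manifest))
  })
}

# Rec. 709 luminance and block-mean downsampling, restated locally so the
# tests do not lean on package internals.
luminance_of <- function(img) {
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

block_mean_of <- function(m, f) {
  h <- (nrow(m) %/% f) * f; w <- (ncol(m) %/% f) * f
  m <- m[seq_len(h), seq_len(w)]
  dim(m) <- c(f, h %/% f, f, w %/% f)
  colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
}

# A random labeled feature table with no class signal, for split and
# chance-level tests.
noise_features <- function(n = 120, d = 8, seed = 5) {
  withr::with_seed(seed, {
    feat <- matrix(rnorm(n * d), n, d)
    colnames(feat) <- paste0("f", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(tile_id = sprintf("t%03d", seq_len(n)),
                     label = rep(c(0L, 1L), length.out = n),
                     group_id = sprintf("g%02d", (seq_len(n) - 1) %/% 8)),
      tibble::as_tibble(feat))
  })
}

# Two linearly separable Gaussian clusters.
separable_features <- function(n = 60, d = 6, gap = 6, seed = 9) {
  withr::with_seed(seed, {
    lab <- rep(c(0L, 1L), each = n / 2)
    feat <- matrix(rnorm(n * d), n, d) + gap * lab
    colnames(feat) <- paste0("f", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(tile_id = sprintf("t%03d", seq_len(n)), label = lab,
                     group_id = sprintf("g%02d", (seq_len(n) - 1) %/% 5)),
      tibble::as_tibble(feat))
  })
}
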