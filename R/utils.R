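# Shared internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; every stochastic operation in the package routes through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream indices, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed)
  for (i in idx) x <- (x * 69069 + 10007 * as.double(i) + 1) %% 2147483629
  as.integer(x)
}

# Rec. 709 luminance of an H x W x 3 array in [0, 1].
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

# "Same"-style zero padding giving map side ceil(image / stride).
lca_padding <- function(kernel, stride) {
  if (kernel < stride) abort("kernel side must be >= stride.")
  as.integer(floor((kernel - stride) / 2))
}

map_side <- function(image_side, stride) as.integer(ceiling(image_side / stride))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Block-mean downsample of a matrix or H x W x C array by integer factor
# (area averaging).
block_mean <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.matrix(x)) {
    h <- (nrow(x) %/% factor) * factor
    w <- (ncol(x) %/% factor) * factor
    x <- x[seq_len(h), seq_len(w), drop = FALSE]
    dim(x) <- c(factor, h %/% factor, factor, w %/% factor)
    colMeans(aperm(x, c(1, 3, 2, 4)), dims = 2)
  } else {
    out <- vapply(seq_len(dim(x)[3]), function(ch) block_mean(x[, , ch], factor),
                  matrix(0, nrow(x) %/% factor, ncol(x) %/% factor))
    out
  }
}
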