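# Independent reference implementations used as oracles. Everything here
# is deliberately naive (explicit loops, dense matrices) and shares no code
# with the package's computational path.

# Dense convolution operator: column (i, j, f) of the returned matrix is
# the vectorized image obtained by placing kernel f (scaled by 1) at map
# position (i, j) under stride `s` and zero padding `p`. Column order
# matches the package's map flattening (i fastest, then j, then f).
dense_conv_matrix <- function(kernels, image_dim, stride) {
  k <- dim(kernels)[1]
  ch <- dim(kernels)[3]
  nf <- dim(kernels)[4]
  H <- image_dim[1]; W <- image_dim[2]
  stopifnot(image_dim[3] == ch)
  p <- floor((k - stride) / 2)
  mh <- ceiling(H / stride); mw <- ceiling(W / stride)
  D <- matrix(0, H * W * ch, mh * mw * nf)
  for (f in seq_len(nf)) {
    for (j in seq_len(mw)) {
      for (i in seq_len(mh)) {
        img <- array(0, image_dim)
        r0 <- (i - 1) * stride - p
        c0 <- (j - 1) * stride - p
        for (cc in seq_len(k)) {
          for (rr in seq_len(k)) {
            r <- r0 + rr; c <- c0 + cc
            if (r >= 1 && r <= H && c >= 1 && c <= W) {
              img[r, c, ] <- kernels[rr, cc, , f]
            }
          }
        }
        D[, i + (j - 1) * mh + (f - 1) * mh * mw] <- as.vector(img)
      }
    }
  }
  D
}

# FISTA for 0.5 * ||y - D x||^2 + lambda * ||x||_1 on the dense operator.
fista_lasso <- function(D, y, lambda, n_iter = 3000, tol = 1e-12) {
  DtD <- crossprod(D)
  Dty <- crossprod(D, y)
  # Lipschitz constant via power iteration
  v <- rnorm(ncol(D))
  for (q in 1:100) {
    v <- DtD %*% v
    v <- v / sqrt(sum(v^2))
  }
  L <- as.numeric(crossprod(v, DtD %*% v)) * 1.01
  shrink <- function(u, t) sign(u) * pmax(abs(u) - t, 0)
  x <- numeric(ncol(D))
  z <- x
  tk <- 1
  e_prev <- Inf
  for (it in seq_len(n_iter)) {
    grad <- DtD %*% z - Dty
    x_new <- shrink(z - grad / L, lambda / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    if (it %% 25 == 0) {
      e <- 0.5 * sum((y - D %*% x)^2) + lambda * sum(abs(x))
      if (abs(e_prev - e) < tol * max(e, 1)) break
      e_prev <- e
    }
  }
  energy <- 0.5 * sum((y - D %*% x)^2) + lambda * sum(abs(x))
  list(x = as.numeric(x), energy = energy)
}

# Exhaustive-scan Otsu: for every candidate split of the 256-bin histogram,
# between-class variance computed by explicit summation.
otsu_bruteforce <- function(gray) {
  if (max(gray) > 1) gray <- gray / 255
  bins <- pmin(floor(gray * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  best <- -Inf
  best_k <- NA
  for (k in 0:254) {            # class 0 = bins 0..k
    n0 <- sum(h[1:(k + 1)])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:k) * h[1:(k + 1)]) / n0
    mu1 <- sum(((k + 1):255) * h[(k + 2):256]) / n1
    sb <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (sb > best + 1e-15) {
      best <- sb
      best_k <- k
    }
  }
  (best_k + 1) / 256
}

# Direct sliding-window density by explicit summation.
density_bruteforce <- function(mask, window) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H - window + 1, W - window + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- sum(m[i:(i + window - 1), j:(j + window - 1)]) / window^2
    }
  }
  out
}

# Brute-force greedy window selection: rescan the whole map each round.
greedy_bruteforce <- function(density, n, window, min_density = 0.05) {
  d <- round(density, 12)
  H <- nrow(d); W <- ncol(d)
  picks <- list()
  for (rank in seq_len(n)) {
    best <- -Inf; bi <- NA; bj <- NA
    for (i in seq_len(H)) {       # row-major scan; first strict improvement
      for (j in seq_len(W)) {
        if (is.finite(d[i, j]) && d[i, j] > best) {
          best <- d[i, j]; bi <- i; bj <- j
        }
      }
    }
    if (!is.finite(best) || best < min_density) break
    picks[[rank]] <- c(x = bj - 1, y = bi - 1, density = best)
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (abs(i - bi) < window && abs(j - bj) < window) d[i, j] <- -Inf
      }
    }
  }
  do.call(rbind, picks)
}

# A small centered random image and matching dictionary for solver tests.
random_instance <- function(seed, image_size = 32, n_features = 8,
                            kernel = 8, stride = 4, channels = 3) {
  withr::with_seed(seed, {
    dict <- histosparse::sc_dictionary(
      array(rnorm(kernel^2 * channels * n_features),
            c(kernel, kernel, channels, n_features)), stride)
    dict <- histosparse::normalize_dictionary(dict)
    img <- array(rnorm(image_size^2 * channels, sd = 0.3),
                 c(image_size, image_size, channels))
    list(dict = dict, img = img)
  })
}
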