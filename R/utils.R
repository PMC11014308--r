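# Internal numeric helpers shared across modules.

# Round half away from zero, the convention pinned for all gray-level maps so
# that key images are bit-reproducible across platforms (base round() is
# round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stopf("'%s' must be a finite numeric scalar in [%s, %s]", name, lo, hi)
  invisible(x)
}

# Evaluate expr with a temporary RNG state when seed is non-NULL.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate (edge-value) padding.
blur_matrix <- function(x, sigma_row, sigma_col = sigma_row) {
  x <- conv_along(x, gaussian_kernel(sigma_row), 1L)
  conv_along(x, gaussian_kernel(sigma_col), 2L)
}

conv_along <- function(x, k, dim) {
  nk <- length(k)
  if (nk == 1L) return(x)
  r <- (nk - 1L) / 2L
  if (dim == 2L) return(t(conv_along(t(x), k, 1L)))
  n <- nrow(x)
  xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (i in seq_len(nk)) out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
  out
}

# Smooth Gaussian random field, standardized to mean 0 / sd 1. `scale` is the
# correlation length in pixels (the sd of the smoothing kernel). The noise is
# drawn on a margin-extended grid and cropped so the field is stationary up
# to the borders.
smooth_field <- function(nr, nc, scale) {
  m <- max(1L, ceiling(3 * scale))
  z <- matrix(stats::rnorm((nr + 2 * m) * (nc + 2 * m)), nr + 2 * m, nc + 2 * m)
  f <- blur_matrix(z, scale)[(m + 1):(m + nr), (m + 1):(m + nc)]
  (f - mean(f)) / stats::sd(f)
}

# Moving-average smoothing of a 1D signal with replicate padding.
smooth_vector <- function(y, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(y)
  r <- (window - 1L) / 2L
  n <- length(y)
  yp <- y[c(rep(1L, r), seq_len(n), rep(n, r))]
  as.numeric(stats::filter(yp, rep(1 / window, window), sides = 2L))[(r + 1L):(r + n)]
}

# --- Bicubic (Keys, a = -0.5) interpolation -------------------------------

cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  i2 <- at > 1 & at < 2
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# Weight matrix mapping n_in samples to n_out samples with pixel-center
# alignment and replicate boundary handling. Interpolates exactly at the
# source grid, so n_out == n_in is the identity.
bicubic_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s + 0.5
  w <- matrix(0, n_out, n_in)
  base <- floor(src)
  for (d in -1:2) {
    idx <- clamp(base + d, 1, n_in)
    wt <- cubic_kernel(src - (base + d))
    w[cbind(seq_len(n_out), idx)] <- w[cbind(seq_len(n_out), idx)] + wt
  }
  w
}

bicubic_resize <- function(x, nrow_out, ncol_out) {
  wr <- bicubic_weights(nrow(x), nrow_out)
  wc <- bicubic_weights(ncol(x), ncol_out)
  wr %*% x %*% t(wc)
}
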