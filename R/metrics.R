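#' Global structural similarity index
#'
#' Single-window SSIM computed from whole-image means, variances and
#' covariance (population normalization, dividing by the pixel count):
#' \deqn{SSIM = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
#'                   {(\mu_a^2 + \mu_b^2 + C_1)(\sigma_a^2 + \sigma_b^2 + C_2)}}
#' with the conventional stabilizing constants `c1 = (0.01*255)^2` and
#' `c2 = (0.03*255)^2`. This is the global form, not the sliding-window
#' average. `variant = "printed"` additionally substitutes `c1` for `c2` in
#' the variance term of the denominator, reproducing a variant sometimes
#' printed with the constants conflated; the standard form is the default.
#'
#' @param a,b Numeric matrices of the same shape (8-bit gray scale assumed
#'   for the default constants).
#' @param c1,c2 Positive stabilizing constants.
#' @param variant `"standard"` or `"printed"` (see Details).
#' @return SSIM value in \[-1, 1\].
#' @export
img_ssim <- function(a, b, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                     variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  if (!all(dim(a) == dim(b))) stopf("images must have the same shape")
  assert_scalar_num(c1, "c1", lo = .Machine$double.xmin)
  assert_scalar_num(c2, "c2", lo = .Machine$double.xmin)
  n <- length(a)
  mu_a <- sum(a) / n; mu_b <- sum(b) / n
  va <- sum((a - mu_a)^2) / n
  vb <- sum((b - mu_b)^2) / n
  cab <- sum((a - mu_a) * (b - mu_b)) / n
  cden <- if (variant == "printed") c1 else c2
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + cden))
}

#' Normalized cross-correlation
#'
#' `NCC = sum(a*b) / sqrt(sum(a^2) * sum(b^2))`. Equals 1 for an image with
#' itself; scale-invariant for positive rescaling.
#'
#' @param a,b Numeric matrices of the same shape, not both all-zero.
#' @return NCC value (in \[0, 1\] for non-negative images).
#' @export
img_ncc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stopf("images must have the same shape")
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0) stopf("NCC undefined for an all-zero image")
  sum(a * b) / sqrt(sa * sb)
}

#' Adjacent-pixel correlation
#'
#' Pearson-type correlation over `J` uniformly sampled (with replacement)
#' adjacent pixel pairs in the given direction. Near zero for random-looking
#' images; near one for natural images. The pair-sampling is seeded for
#' reproducibility.
#'
#' @param img Numeric matrix.
#' @param direction `"horizontal"`, `"vertical"` or `"diagonal"`.
#' @param J Number of sampled pairs.
#' @param seed Optional RNG seed for the pair sampling.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
adjacent_correlation <- function(img, direction = c("horizontal", "vertical",
                                                    "diagonal"),
                                 J = 5000L, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(img))
  J <- as.integer(J)
  assert_scalar_num(J, "J", lo = 2)
  nr <- nrow(img); nc <- ncol(img)
  dr <- switch(direction, horizontal = 0L, vertical = 1L, diagonal = 1L)
  dc <- switch(direction, horizontal = 1L, vertical = 0L, diagonal = 1L)
  if (nr - dr < 1L || nc - dc < 1L)
    stopf("image too small to sample %s pairs", direction)
  pairs <- local_seed(seed, {
    i <- sample.int(nr - dr, J, replace = TRUE)
    j <- sample.int(nc - dc, J, replace = TRUE)
    cbind(i, j)
  })
  x <- img[pairs]
  y <- img[pairs + rep(c(dr, dc), each = J)]
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0)
    stopf("degenerate sample: zero variance (constant image?)")
  sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
}

#' Gray-level Shannon entropy
#'
#' `H = -sum_i P(G_i) log2 P(G_i)` over the 256 gray levels of an 8-bit
#' image, skipping empty bins. Bounded by 8 bits, attained by a perfectly
#' uniform histogram.
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @return Entropy in bits, in \[0, 8\].
#' @export
img_entropy <- function(img) {
  p <- gray_histogram(img) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level histogram
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @return Named integer vector of 256 counts (names `"0"`..`"255"`),
#'   summing to the pixel count.
#' @export
gray_histogram <- function(img) {
  v <- as.vector(if (inherits(img, "key_image")) img$data else img)
  if (min(v) < 0 || max(v) > 255 || any(v != floor(v)))
    stopf("gray_histogram expects integer gray levels in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

#' Full similarity / randomness report for an image pair
#'
#' Convenience wrapper computing SSIM, NCC, the three adjacent-pixel
#' correlations of `a`, its entropy and histogram.
#'
#' @inheritParams img_ssim
#' @param J,seed Passed to [adjacent_correlation()].
#' @return List of class `metrics_report`.
#' @export
metrics_report <- function(a, b, J = 5000L, seed = 1L) {
  a <- as_gray_matrix(a); b <- as_gray_matrix(b)
  structure(list(
    ssim = img_ssim(a, b),
    ncc = img_ncc(a, b),
    cor_horizontal = adjacent_correlation(a, "horizontal", J, seed),
    cor_vertical = adjacent_correlation(a, "vertical", J, seed),
    cor_diagonal = adjacent_correlation(a, "diagonal", J, seed),
    entropy_bits = img_entropy(a),
    histogram = gray_histogram(a)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SSIM %.4f | NCC %.4f | COR h/v/d %.4f/%.4f/%.4f | entropy %.4f bits\n",
              x$ssim, x$ncc, x$cor_horizontal, x$cor_vertical, x$cor_diagonal,
              x$entropy_bits))
  invisible(x)
}
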