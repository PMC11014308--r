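#' Orthonormal 2D discrete cosine transform
#'
#' DCT-II with orthonormal scaling, computed as `D %*% X %*% t(D')` with the
#' 1D DCT matrices `D`; with this normalization the inverse transform is the
#' exact transpose, so [idct2()] recovers the input to machine precision.
#'
#' @param x Numeric matrix.
#' @return Matrix of DCT coefficients, same shape.
#' @export
dct2 <- function(x) {
  stopifnot(is.matrix(x))
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

#' @rdname dct2
#' @export
idct2 <- function(x) {
  stopifnot(is.matrix(x))
  t(dct_matrix(nrow(x))) %*% x %*% dct_matrix(ncol(x))
}

.dct_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  m <- .dct_cache[[key]]
  if (!is.null(m)) return(m)
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  m[1, ] <- sqrt(1 / n)
  .dct_cache[[key]] <- m
  m
}

#' Resize a key image to the plaintext shape
#'
#' Interpolates the 101 x 101 key bicubically to the plaintext resolution
#' (256 x 256 by default), then shifts by +1 and clamps to \[1, 256\] so the
#' resized key is division-safe: decryption divides the cipher by the key,
#' and raw keys legitimately contain zeros. The offset is recorded so the
#' scheme is self-contained.
#'
#' @param key A `key_image` (or numeric matrix in \[0,255\]).
#' @param shape Target `(rows, cols)`.
#' @return An object of class `resized_key`: matrix `data` with values in
#'   \[1, 256\] and the recorded `offset`.
#' @export
resize_key <- function(key, shape = c(256L, 256L)) {
  data <- if (inherits(key, "key_image")) key$data else key
  stopifnot(is.matrix(data))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L))
    stopf("target shape must be at least 2 x 2")
  r <- bicubic_resize(data, shape[1], shape[2])
  structure(list(data = clamp(r + 1, 1, 256), offset = 1),
            class = "resized_key")
}

#' @export
print.resized_key <- function(x, ...) {
  cat(sprintf("Resized key: %d x %d, values [%.2f, %.2f] (offset +%g)\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data), x$offset))
  invisible(x)
}

#' Encrypt a grayscale image in the DCT domain
#'
#' Transforms the plaintext with the orthonormal 2D DCT, compresses the
#' spectrum with a low-pass filter that keeps the top-left
#' `ceil(lowpass_frac * N) x ceil(lowpass_frac * M)` coefficient block (the
#' low spatial frequencies) and zeroes the rest, and fuses the result with
#' the biometric key by elementwise multiplication. The cipher is a
#' real-valued array of the plaintext shape.
#'
#' @param plain Integer matrix in \[0,255\] (8-bit grayscale image).
#' @param key A `resized_key` of the same shape.
#' @param lowpass_frac Fraction of each spectral axis retained, in (0, 1].
#'   `1` keeps the full spectrum and makes the scheme lossless.
#' @return An object of class `cipher_image`: matrix `data` and
#'   `scheme_params` (low-pass fraction, key offset, key digest).
#' @export
encrypt_image <- function(plain, key, lowpass_frac = 0.5) {
  stopifnot(inherits(key, "resized_key"))
  plain <- as_gray_matrix(plain)
  if (!all(dim(plain) == dim(key$data)))
    stopf("plaintext is %d x %d but key is %d x %d", nrow(plain), ncol(plain),
          nrow(key$data), ncol(key$data))
  assert_scalar_num(lowpass_frac, "lowpass_frac", lo = 1e-12, hi = 1)
  co <- dct2(plain)
  kr <- ceiling(lowpass_frac * nrow(co))
  kc <- ceiling(lowpass_frac * ncol(co))
  mask <- matrix(0, nrow(co), ncol(co))
  mask[seq_len(kr), seq_len(kc)] <- 1
  structure(list(data = co * mask * key$data,
                 scheme_params = list(lowpass_frac = lowpass_frac,
                                      key_offset = key$offset,
                                      key_digest = key_digest(key))),
            class = "cipher_image")
}

#' Decrypt a DCT-domain cipher
#'
#' Inverts [encrypt_image()]: divides the cipher elementwise by the resized
#' key, applies the inverse DCT, rounds and clips to \[0,255\]. With the full
#' spectrum retained (`lowpass_frac = 1`) and the correct key the plaintext
#' is recovered bit-exactly.
#'
#' @param cipher A `cipher_image`.
#' @param key A `resized_key` of the same shape.
#' @return Integer matrix in \[0,255\].
#' @export
decrypt_image <- function(cipher, key) {
  stopifnot(inherits(cipher, "cipher_image"), inherits(key, "resized_key"))
  if (!all(dim(cipher$data) == dim(key$data)))
    stopf("cipher is %d x %d but key is %d x %d",
          nrow(cipher$data), ncol(cipher$data), nrow(key$data), ncol(key$data))
  if (any(key$data == 0))
    stopf("decryption key contains zeros; use resize_key() to obtain a division-safe key")
  p <- idct2(cipher$data / key$data)
  matrix(as.integer(clamp(round(p), 0, 255)), nrow(p), ncol(p))
}

#' @export
print.cipher_image <- function(x, ...) {
  cat(sprintf("DCT-domain cipher: %d x %d, values [%.2f, %.2f], low-pass fraction %g\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data),
              x$scheme_params$lowpass_frac))
  invisible(x)
}

key_digest <- function(key) {
  v <- as.vector(key$data)
  sprintf("%.0f", sum(v * seq_along(v)) %% 2^31)
}

as_gray_matrix <- function(x) {
  if (inherits(x, "key_image")) x <- x$data
  stopifnot(is.matrix(x))
  if (min(x) < 0 || max(x) > 255)
    stopf("8-bit grayscale values must lie in [0, 255]")
  x
}
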