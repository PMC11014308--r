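#' Read and write OCT volumes as multi-page TIFF
#'
#' Volumes are stored one slice per page, 16-bit grayscale. Volume data is
#' quantized to the 16-bit grid at render time, so the round trip
#' write-then-read is bit-identical.
#'
#' @param volume An `oct_volume`.
#' @param path File path (`.tiff`).
#' @param slice_spacing_um Slice spacing metadata restored on read.
#' @return `read_volume()` returns an `oct_volume`; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  pages <- lapply(seq_len(dim(volume$data)[1]), function(s) {
    m <- volume$data[s, , ]
    if (is.null(dim(m))) m <- matrix(m, dim(volume$data)[2], dim(volume$data)[3])
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, slice_spacing_um = 25) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  bad <- which(vapply(pages, function(p) !identical(dim(p), d), logical(1)))
  if (length(bad))
    stopf("malformed volume TIFF '%s': page %d has a different shape", path, bad[1])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (s in seq_along(pages)) arr[s, , ] <- pages[[s]]
  new_oct_volume(arr, slice_spacing_um)
}

#' Read and write 8-bit grayscale PNG images
#'
#' Integer matrices in \[0,255\] round-trip bit-exactly.
#'
#' @param img Integer matrix in \[0,255\], or a `key_image`.
#' @param path File path (`.png`).
#' @return `read_image()` returns an integer matrix; `write_image()` the
#'   path, invisibly.
#' @export
write_image <- function(img, path) {
  m <- as_gray_matrix(img)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a key image with its transform log
#'
#' The key goes to an 8-bit PNG; the linear-mapping bookkeeping (count
#' minimum/maximum, stretch flag) goes to a JSON sidecar next to it.
#'
#' @param key A `key_image`.
#' @param path PNG path; the sidecar is `<path>.json`.
#' @return `read_key()` returns a `key_image`; `write_key()` the path,
#'   invisibly.
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, "key_image"))
  write_image(key$data, path)
  jsonlite::write_json(key$transform_log, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_key
#' @export
read_key <- function(path) {
  data <- read_image(path)
  side <- paste0(path, ".json")
  tl <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
        else list()
  new_key_image(data, transform_log = tl)
}

#' Read and write DCT-domain ciphers
#'
#' Ciphers are real-valued and are stored as raw 32-bit little-endian IEEE
#' floats with a JSON sidecar carrying the dimensions and the scheme
#' parameters. Writing quantizes the values to 32-bit precision; thereafter
#' the round trip is exact.
#'
#' @param cipher A `cipher_image`.
#' @param path Binary payload path (`.f32`); the sidecar is `<path>.json`.
#' @return `read_cipher()` returns a `cipher_image`; `write_cipher()` the
#'   path, invisibly.
#' @export
write_cipher <- function(cipher, path) {
  stopifnot(inherits(cipher, "cipher_image"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(cipher$data), con, size = 4L, endian = "little")
  jsonlite::write_json(c(list(dim = dim(cipher$data), format = "float32-le"),
                         cipher$scheme_params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cipher
#' @export
read_cipher <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side))
    stopf("cipher payload or sidecar not found for: %s", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  if (length(d) != 2L || !identical(meta$format, "float32-le"))
    stopf("malformed cipher sidecar: %s", side)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 4L, endian = "little")
  if (length(v) != prod(d))
    stopf("cipher payload truncated at value %d of %d (byte offset %d)",
          length(v), prod(d), 4L * length(v))
  sp <- meta[setdiff(names(meta), c("dim", "format"))]
  structure(list(data = matrix(v, d[1], d[2]), scheme_params = sp),
            class = "cipher_image")
}

#' Write traced boundaries as CSV
#'
#' Long format: one row per (slice, column) with the upper and lower
#' boundary rows and the validity flag.
#'
#' @param boundaries A `boundary_set`.
#' @param path CSV path.
#' @return `read_boundaries()` returns a `boundary_set`; `write_boundaries()`
#'   the path, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "boundary_set"))
  ns <- nrow(boundaries$upper); nw <- ncol(boundaries$upper)
  df <- data.frame(slice = rep(seq_len(ns), each = nw),
                   column = rep(seq_len(nw), times = ns),
                   upper = as.vector(t(boundaries$upper)),
                   lower = as.vector(t(boundaries$lower)),
                   valid = as.vector(t(boundaries$valid)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  if (!file.exists(path)) stopf("boundary file not found: %s", path)
  df <- utils::read.csv(path)
  ns <- max(df$slice); nw <- max(df$column)
  ix <- cbind(df$slice, df$column)
  upper <- matrix(NA_real_, ns, nw); upper[ix] <- df$upper
  lower <- matrix(NA_real_, ns, nw); lower[ix] <- df$lower
  valid <- matrix(FALSE, ns, nw); valid[ix] <- df$valid
  new_boundary_set(upper, lower, valid)
}
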