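#' En-face internal fingerprint by maximum intensity projection
#'
#' Projects the volume onto an en-face image by taking, for every
#' (column, slice) position, the maximum intensity along depth restricted to
#' that slice's DEJ envelope region of interest. The result is the internal
#' fingerprint: the ridge topography of the dermis-epidermis junction seen
#' face-on. Output rows index the lateral columns of the volume and output
#' columns index the slices, so a `width x n_slices` image.
#'
#' Positions whose ROI column is empty are set to 0 and flagged in the
#' `empty` attribute.
#'
#' @param volume An `oct_volume`.
#' @param rois List of `envelope_roi` objects, one per slice (see
#'   [envelope_rois()]).
#' @return An object of class `fingerprint_image`: list with `data`
#'   (`width x n_slices` matrix in \[0,1\]) and `empty` (logical matrix).
#' @export
mip_project <- function(volume, rois) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$data)
  ns <- d[1]; nd <- d[2]; nw <- d[3]
  if (length(rois) != ns)
    stopf("number of ROIs (%d) does not match the number of slices (%d)",
          length(rois), ns)
  fp <- matrix(0, nw, ns)
  empty <- matrix(FALSE, nw, ns)
  for (s in seq_len(ns)) {
    sl <- volume$data[s, , ]
    if (nw == 1L) sl <- matrix(sl, nd, 1L)
    m <- rois[[s]]$roi_mask
    if (nrow(m) != nd || ncol(m) != nw)
      stopf("ROI mask of slice %d has shape %dx%d, expected %dx%d",
            s, nrow(m), ncol(m), nd, nw)
    sl[!m] <- -Inf
    mx <- apply(sl, 2L, max)
    none <- !is.finite(mx)
    mx[none] <- 0
    fp[, s] <- mx
    empty[none, s] <- TRUE
  }
  structure(list(data = fp, empty = empty), class = "fingerprint_image")
}

#' @export
print.fingerprint_image <- function(x, ...) {
  cat(sprintf("Internal fingerprint: %d columns x %d slices, intensity [%.3f, %.3f]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  if (any(x$empty))
    cat(sprintf("  %d positions had an empty ROI\n", sum(x$empty)))
  invisible(x)
}

#' @export
plot.fingerprint_image <- function(x, ...) {
  graphics::image(t(x$data)[, rev(seq_len(nrow(x$data)))],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = "Internal fingerprint (MIP)", ...)
  invisible(x)
}

#' Select the square key region of the fingerprint image
#'
#' Marks the `(2*half_width + 1)`-sided square (101 x 101 with the default
#' half-width of 50) centered on the fingerprint pattern. The center can be
#' given explicitly as `(row, col)` coordinates in the fingerprint image
#' (mirroring a manually labelled center point), or `"auto"`, which places it
#' at the intensity centroid of the local ridge energy: the image is
#' band-passed around the ridge frequency, squared, smoothed, and the
#' centroid of the resulting energy map is taken, constrained so the square
#' fits in the image.
#'
#' @param fp A `fingerprint_image`.
#' @param center `"auto"` or a numeric `(row, col)` pair.
#' @param half_width Half side length of the square, pixels.
#' @param ridge_period_px Ridge period used by the auto-center band-pass.
#' @return An object of class `center_roi`: `center`, `half_width`,
#'   `column_range` (fingerprint rows = volume columns) and `slice_range`
#'   (fingerprint columns = slices).
#' @export
select_center_roi <- function(fp, center = "auto", half_width = 50L,
                              ridge_period_px = 36) {
  stopifnot(inherits(fp, "fingerprint_image"))
  half_width <- as.integer(half_width)
  assert_scalar_num(half_width, "half_width", lo = 0)
  nr <- nrow(fp$data); nc <- ncol(fp$data)
  side <- 2L * half_width + 1L
  if (side > nr || side > nc)
    stopf("a %dx%d square cannot fit in a %dx%d fingerprint image",
          side, side, nr, nc)
  if (identical(center, "auto")) {
    center <- ridge_energy_centroid(fp$data, ridge_period_px)
    center <- c(clamp(center[1], half_width + 1L, nr - half_width),
                clamp(center[2], half_width + 1L, nc - half_width))
  }
  center <- as.integer(round(center))
  if (length(center) != 2L) stopf("center must be a (row, col) pair or \"auto\"")
  r <- center[1]; cc <- center[2]
  if (r - half_width < 1L) stopf("ROI exceeds the image at the top edge")
  if (r + half_width > nr) stopf("ROI exceeds the image at the bottom edge")
  if (cc - half_width < 1L) stopf("ROI exceeds the image at the left edge")
  if (cc + half_width > nc) stopf("ROI exceeds the image at the right edge")
  structure(list(center = center, half_width = half_width,
                 column_range = (r - half_width):(r + half_width),
                 slice_range = (cc - half_width):(cc + half_width)),
            class = "center_roi")
}

#' @export
print.center_roi <- function(x, ...) {
  cat(sprintf("Key region: %d x %d px centered at (%d, %d); columns %d..%d, slices %d..%d\n",
              2L * x$half_width + 1L, 2L * x$half_width + 1L,
              x$center[1], x$center[2],
              min(x$column_range), max(x$column_range),
              min(x$slice_range), max(x$slice_range)))
  invisible(x)
}

# Centroid of smoothed band-pass energy at the ridge frequency.
ridge_energy_centroid <- function(img, period) {
  hp <- img - blur_matrix(img, period)       # remove slow illumination
  bp <- blur_matrix(hp, max(1, period / 8))  # suppress pixel noise
  e <- blur_matrix(bp^2, period)
  e <- e - min(e)
  tot <- sum(e)
  if (tot <= 0) return(c(nrow(img) / 2, ncol(img) / 2))
  c(sum(rowSums(e) * seq_len(nrow(img))) / tot,
    sum(colSums(e) * seq_len(ncol(img))) / tot)
}

#' Binary epidermis masks from traced boundaries
#'
#' Builds, for every slice, the binary epidermis cross-section implied by the
#' traced boundaries: a pixel is epidermis (value 255) when its row lies
#' between the rounded upper and lower boundary inclusive, and background
#' (value 0) otherwise. The validity flag is advisory (the traced path is
#' still the best available estimate in a low-contrast column), so flagged
#' columns keep their band; only columns whose boundaries cross are left
#' black.
#'
#' @param boundaries A `boundary_set`.
#' @param depth_px Axial size of the masks.
#' @return Integer array `(n_slices, depth_px, width)` with values {0, 255}.
#' @export
epidermis_masks <- function(boundaries, depth_px) {
  stopifnot(inherits(boundaries, "boundary_set"))
  ns <- nrow(boundaries$upper); nw <- ncol(boundaries$upper)
  u <- round(boundaries$upper); l <- round(boundaries$lower)
  masks <- array(0L, dim = c(ns, depth_px, nw))
  rows <- seq_len(depth_px)
  for (s in seq_len(ns)) {
    us <- matrix(u[s, ], depth_px, nw, byrow = TRUE)
    ls <- matrix(l[s, ], depth_px, nw, byrow = TRUE)
    m <- matrix(0L, depth_px, nw)
    m[rows >= us & rows <= ls & us <= ls] <- 255L
    masks[s, , ] <- m
  }
  masks
}

#' Crop the binary epidermis stack to the key region
#'
#' Restricts the binary epidermis masks to the slices and columns of the key
#' region, yielding the `(2h+1)` cross-sections x depth x `(2h+1)` columns
#' binary stack (101 slices of 101 columns at the default half-width) whose
#' column-wise white-pixel counts form the thickness matrix.
#'
#' @param masks Binary array from [epidermis_masks()].
#' @param roi A `center_roi`.
#' @return Binary integer array `(side, depth, side)` with values {0, 255};
#'   attribute `all_black = TRUE` if the crop contains no epidermis.
#' @export
crop_epidermis_stack <- function(masks, roi) {
  stopifnot(is.array(masks), length(dim(masks)) == 3L,
            inherits(roi, "center_roi"))
  d <- dim(masks)
  if (min(roi$slice_range) < 1L || max(roi$slice_range) > d[1])
    stopf("ROI slice range %d..%d exceeds the stack (%d slices)",
          min(roi$slice_range), max(roi$slice_range), d[1])
  if (min(roi$column_range) < 1L || max(roi$column_range) > d[3])
    stopf("ROI column range %d..%d exceeds the stack width (%d)",
          min(roi$column_range), max(roi$column_range), d[3])
  out <- masks[roi$slice_range, , roi$column_range, drop = FALSE]
  if (all(out == 0L)) attr(out, "all_black") <- TRUE
  out
}
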