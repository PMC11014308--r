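#' Column-wise epidermal thickness counts
#'
#' Counts the white (epidermis) pixels in every column of every cropped
#' binary cross-section: entry `(i, j)` of the result is the epidermal
#' thickness, in pixels, at slice `i` and column `j` of the key region.
#'
#' @param binary_stack Binary integer array `(slices, depth, columns)` with
#'   values in {0, 255}, as returned by [crop_epidermis_stack()].
#' @return An integer matrix of class `thickness_map` (`slices x columns`).
#' @export
count_thickness <- function(binary_stack) {
  stopifnot(is.array(binary_stack), length(dim(binary_stack)) == 3L)
  if (!all(binary_stack %in% c(0L, 255L)))
    stopf("binary stack must contain only the values 0 and 255")
  counts <- apply(binary_stack == 255L, c(1L, 3L), sum)
  structure(counts, class = c("thickness_map", class(counts)))
}

#' Linear gray-level mapping of a thickness map
#'
#' Maps the integer thickness counts linearly onto the 8-bit gray range:
#' `round(255 * (count - min) / (max - min))`, rounding half away from zero.
#' The per-key minimum and maximum are recorded in the transform log so the
#' mapping is invertible up to rounding. A constant map carries no pattern;
#' it is mapped to the mid-gray 128 with a warning (degenerate key).
#'
#' @param map A `thickness_map` (or plain numeric matrix of counts).
#' @return An object of class `key_image`: integer matrix `data` in
#'   \[0,255\] and `transform_log` (list with `min`, `max`, `stretched`).
#' @export
linear_to_gray <- function(map) {
  m <- unclass(map)
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("constant thickness map: degenerate key, mapped to mid-gray 128",
            call. = FALSE)
    data <- matrix(128L, nrow(m), ncol(m))
  } else {
    data <- matrix(as.integer(round_half_away(255 * (m - lo) / (hi - lo))),
                   nrow(m), ncol(m))
  }
  new_key_image(data, transform_log = list(min = lo, max = hi, stretched = FALSE))
}

#' Non-linear gray-scale stretch
#'
#' Applies the quadratic gray-level stretch `DB = DA^2 / 255` (rounded half
#' away from zero and clipped to \[0,255\]) to a key image. The stretch is
#' monotone non-decreasing, fixes 0 and 255, and is contractive below 255,
#' deepening the dark end of the thickness pattern.
#'
#' @param image A `key_image` (or integer matrix in \[0,255\]).
#' @return A `key_image` with `transform_log$stretched = TRUE`.
#' @export
nonlinear_stretch <- function(image) {
  if (inherits(image, "key_image")) {
    data <- image$data
    tl <- image$transform_log
  } else {
    data <- image
    tl <- list()
  }
  if (min(data) < 0 || max(data) > 255)
    stopf("gray values must lie in [0, 255] before the stretch")
  out <- matrix(as.integer(clamp(round_half_away(data^2 / 255), 0, 255)),
                nrow(data), ncol(data))
  tl$stretched <- TRUE
  new_key_image(out, transform_log = tl)
}

new_key_image <- function(data, transform_log = list()) {
  stopifnot(is.matrix(data))
  if (min(data) < 0 || max(data) > 255)
    stopf("key image values must lie in [0, 255]")
  structure(list(data = data, transform_log = transform_log),
            class = "key_image")
}

#' @export
print.key_image <- function(x, ...) {
  cat(sprintf("Thickness-map key image: %d x %d px, gray range [%d, %d]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  if (!is.null(x$transform_log$min))
    cat(sprintf("  linear map from counts [%g, %g]; non-linear stretch: %s\n",
                x$transform_log$min, x$transform_log$max,
                isTRUE(x$transform_log$stretched)))
  invisible(x)
}

#' @export
plot.key_image <- function(x, ...) {
  graphics::image(t(x$data)[, rev(seq_len(nrow(x$data)))], zlim = c(0, 255),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = "Epidermal-thickness key", ...)
  invisible(x)
}

#' Full key-generation pipeline on an OCT volume
#'
#' Runs segmentation, DEJ envelope construction, maximum intensity
#' projection, key-region selection, binary epidermis cropping, thickness
#' counting, linear gray mapping and the non-linear stretch, producing the
#' final 8-bit key image. Deterministic: the same volume and settings yield a
#' bit-identical key.
#'
#' @param volume An `oct_volume`.
#' @param center Key-region center, `"auto"` or `(row, col)` in the
#'   fingerprint image.
#' @param half_width Key-region half side length (50 gives the 101 x 101 key).
#' @param ridge_period_px Ridge period driving the smoothing window
#'   (`period/4`), the extrema separation (`period/3`) and the auto-center
#'   band-pass.
#' @param method Segmentation method identifier.
#' @return A `key_image`; the selected `center_roi` is attached as attribute
#'   `"roi"` and the traced boundaries as `"boundaries"`.
#' @export
generate_key <- function(volume, center = "auto", half_width = 50L,
                         ridge_period_px = 36, method = "dp_gradient") {
  stopifnot(inherits(volume, "oct_volume"))
  depth_px <- dim(volume$data)[2]
  bset <- segment_boundaries(volume, method = method)
  rois <- envelope_rois(bset, depth_px = depth_px,
                        smooth_window = max(3L, round(ridge_period_px / 4)),
                        min_separation = max(2L, round(ridge_period_px / 3)))
  fp <- mip_project(volume, rois)
  roi <- select_center_roi(fp, center = center, half_width = half_width,
                           ridge_period_px = ridge_period_px)
  masks <- epidermis_masks(bset, depth_px)
  stack <- crop_epidermis_stack(masks, roi)
  key <- nonlinear_stretch(linear_to_gray(count_thickness(stack)))
  attr(key, "roi") <- roi
  attr(key, "boundaries") <- bset
  key
}
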