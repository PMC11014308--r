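#' Segment the epidermal boundaries of an OCT volume
#'
#' Traces, in every B-scan, the upper epidermal boundary (the skin surface,
#' a dark-to-bright axial transition) and the lower epidermal boundary (the
#' dermis-epidermis junction, bright-to-dark). The default method
#' `"dp_gradient"` is a two-pass dynamic-programming minimum-cost path over
#' the axial intensity gradient with a continuity constraint of at most
#' `max_jump` pixels between neighbouring columns; the DEJ pass is restricted
#' to run below the traced surface. The segmenter is pluggable (see
#' [register_segmentation_method()]) so a learned model can be dropped in
#' behind the same interface.
#'
#' Columns whose traced boundary sits on a gradient weaker than
#' `min_contrast` are flagged invalid; if more than half of the columns of
#' any slice are invalid (e.g. a constant-intensity volume carries no
#' detectable band) an error is raised.
#'
#' @param volume An `oct_volume`.
#' @param method Name of a registered segmentation method.
#' @param max_jump Maximum boundary jump between adjacent columns, pixels.
#' @param min_gap Minimum axial separation enforced between the two
#'   boundaries, pixels.
#' @param min_contrast Minimum axial gradient magnitude (intensity units per
#'   pixel) at a traced boundary for a column to count as valid.
#' @return An object of class `boundary_set`: matrices `upper`, `lower`
#'   (`n_slices x width`, 1-based depth rows) and logical `valid`.
#' @export
segment_boundaries <- function(volume, method = "dp_gradient", max_jump = 2L,
                               min_gap = 3L, min_contrast = 0.025) {
  stopifnot(inherits(volume, "oct_volume"))
  fn <- .segmenters$methods[[method]]
  if (is.null(fn))
    stopf("unknown segmentation method '%s' (registered: %s)", method,
          paste(names(.segmenters$methods), collapse = ", "))
  fn(volume, max_jump = as.integer(max_jump), min_gap = as.integer(min_gap),
     min_contrast = min_contrast)
}

.segmenters <- new.env(parent = emptyenv())
.segmenters$methods <- list()

#' Register a boundary segmentation method
#'
#' @param name Method identifier used by [segment_boundaries()].
#' @param fn Function `(volume, max_jump, min_gap, min_contrast)` returning a
#'   `boundary_set`.
#' @export
register_segmentation_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .segmenters$methods[[name]] <- fn
  invisible(name)
}

new_boundary_set <- function(upper, lower, valid) {
  if (any(lower[valid] <= upper[valid]))
    stopf("boundary set invalid: lower boundary must stay below upper where valid")
  structure(list(upper = upper, lower = lower, valid = valid),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("Boundary set: %d slices x %d columns (%.1f%% columns valid)\n",
              nrow(x$upper), ncol(x$upper), 100 * mean(x$valid)))
  cat(sprintf("  surface rows [%.1f, %.1f], DEJ rows [%.1f, %.1f]\n",
              min(x$upper), max(x$upper), min(x$lower), max(x$lower)))
  invisible(x)
}

# Axial forward-difference gradient of one B-scan: g[r] = I[r+1] - I[r].
# A forward difference (no pre-smoothing) has a single sharp extremum per
# layer transition, which keeps the minimum-cost path pinned to the exact
# transition row and able to follow the fine-scale DEJ roughness column by
# column; a centred difference would spread each edge over two rows and let
# the path drift within the tie.
axial_gradient <- function(sl) {
  n <- nrow(sl)
  g <- matrix(0, n, ncol(sl))
  g[1:(n - 1), ] <- sl[2:n, , drop = FALSE] - sl[1:(n - 1), , drop = FALSE]
  g
}

# Boxcar matched filter for a step edge: difference between the mean of the
# `w` rows below a row and the mean of the `w` rows above it (truncated at
# the image borders). Averaging suppresses speckle, so adding this term to
# the sharp forward difference keeps spurious single-pixel minima from
# attracting the path.
step_filter <- function(sl, w = 4L) {
  n <- nrow(sl)
  cs <- apply(rbind(0, sl), 2L, cumsum)
  g <- matrix(0, n, ncol(sl))
  for (r in seq_len(n - 1L)) {
    a0 <- max(1L, r - w + 1L)
    b1 <- min(n, r + w)
    above <- (cs[r + 1L, ] - cs[a0, ]) / (r - a0 + 1L)
    below <- (cs[b1 + 1L, ] - cs[r + 1L, ]) / (b1 - r)
    g[r, ] <- below - above
  }
  g
}

# Minimum-cost path through a (depth x width) cost matrix, moving at most
# max_jump rows between adjacent columns. Returns the row index per column.
dp_min_path <- function(cost, max_jump) {
  nd <- nrow(cost); nw <- ncol(cost)
  if (nw == 1L) return(which.min(cost[, 1L]))
  ptr <- matrix(0L, nd, nw)
  acc <- cost[, 1L]
  shifts <- (-max_jump):max_jump
  for (cc in 2:nw) {
    best <- rep(Inf, nd); arg <- integer(nd)
    for (d in shifts) {
      src <- seq_len(nd) + d
      cand <- rep(Inf, nd)
      ok <- src >= 1L & src <= nd
      cand[ok] <- acc[src[ok]]
      upd <- cand < best
      best[upd] <- cand[upd]
      arg[upd] <- d
    }
    ptr[, cc] <- arg
    acc <- cost[, cc] + best
  }
  path <- integer(nw)
  path[nw] <- which.min(acc)
  for (cc in nw:2) path[cc - 1L] <- path[cc] + ptr[path[cc], cc]
  path
}

# Trace one boundary with the two-pass scheme: the median-filtered
# per-column cost minimum gives the slowly varying trend of the curve (the
# ridge undulation); the cost is then re-indexed relative to that trend and
# the minimum-cost path is traced, so the continuity constraint limits the
# jump of the *deviation from the trend* and the full jump budget remains
# available for the pixel-scale boundary roughness riding on a sloped ridge.
dp_trace <- function(cost, max_jump, halfband = 8L) {
  nd <- nrow(cost); nw <- ncol(cost)
  if (nw < 9L) return(dp_min_path(cost, max_jump))
  am <- apply(cost, 2L, which.min)
  trend <- round(smooth_vector(stats::runmed(am, 7L), 5L))
  rel <- (-halfband):halfband
  c2 <- matrix(Inf, length(rel), nw)
  for (k in seq_along(rel)) {
    rows <- trend + rel[k]
    ok <- rows >= 1L & rows <= nd
    c2[k, ok] <- cost[cbind(rows[ok], which(ok))]
  }
  pass2 <- dp_min_path(c2, max_jump)
  clamp(trend + rel[pass2], 1L, nd)
}

segment_dp_gradient <- function(volume, max_jump, min_gap, min_contrast) {
  d <- dim(volume$data)
  ns <- d[1]; nd <- d[2]; nw <- d[3]
  upper <- matrix(0, ns, nw); lower <- matrix(0, ns, nw)
  valid <- matrix(TRUE, ns, nw)
  for (s in seq_len(ns)) {
    sl <- volume$data[s, , ]
    if (nw == 1L) sl <- matrix(sl, nd, 1L)
    g <- axial_gradient(sl) + step_filter(sl)
    # the maximal forward difference sits one row above the first epidermal
    # row, so the surface is the traced row plus one
    up <- dp_trace(-g, max_jump) + 1L
    cost_lo <- g
    floor_row <- clamp(up + min_gap, 1L, nd)
    mask <- row(cost_lo) < matrix(floor_row, nd, nw, byrow = TRUE)
    cost_lo[mask] <- Inf
    lo <- dp_trace(cost_lo, max_jump)
    cols <- seq_len(nw)
    gu <- g[cbind(pmax(up - 1L, 1L), cols)]
    gl <- g[cbind(lo, cols)]
    ok <- gu >= min_contrast & gl <= -min_contrast & lo > up
    if (mean(ok) < 0.5)
      stopf("slice %d: no detectable epidermal band (%.0f%% of columns below the contrast threshold)",
            s, 100 * mean(!ok))
    upper[s, ] <- up; lower[s, ] <- lo; valid[s, ] <- ok
  }
  new_boundary_set(upper, lower, valid)
}

.segmenters$methods[["dp_gradient"]] <- segment_dp_gradient

#' Locate ridge tops and papillae valleys along the DEJ
#'
#' Searches the lower (DEJ) boundary curve of one slice for local extrema
#' after moving-average smoothing. With depth increasing downward, ridge tops
#' are local *minima* of the row coordinate (anatomically superficial) and
#' papillae valleys are local *maxima*; the returned `maxima` element holds
#' the ridge-top columns and `minima` the valley columns, i.e. names follow
#' the anatomical elevation, not the row index. Adjacent extrema of the same
#' kind closer than `min_separation` columns are pruned, keeping the more
#' pronounced one.
#'
#' @param boundaries A `boundary_set`.
#' @param slice_idx Slice index.
#' @param smooth_window Moving-average window (columns) applied before the
#'   extrema search; a sensible choice is a quarter of the ridge period.
#' @param min_separation Minimum column distance between retained extrema of
#'   the same kind; a sensible choice is a third of the ridge period.
#' @return List with integer vectors `maxima` (ridge-top columns) and
#'   `minima` (valley columns); both empty, with attribute `flat = TRUE`, for
#'   a boundary with no interior extrema.
#' @export
locate_dej_extrema <- function(boundaries, slice_idx, smooth_window = 9L,
                               min_separation = 12L) {
  stopifnot(inherits(boundaries, "boundary_set"))
  y <- boundaries$lower[slice_idx, ]
  ys <- smooth_vector(y, smooth_window)
  ridge_tops <- local_extrema(-ys, min_separation)   # minima of row coord
  valleys <- local_extrema(ys, min_separation)
  out <- list(maxima = ridge_tops, minima = valleys)
  if (length(ridge_tops) == 0L && length(valleys) == 0L)
    attr(out, "flat") <- TRUE
  out
}

# Interior local maxima of y, pruned so retained positions are >= min_sep
# apart (most pronounced first). Plateaus count once, at their midpoint.
local_extrema <- function(y, min_sep) {
  d <- diff(y)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # carry the previous non-zero slope through plateaus
  sf <- s
  last <- 0
  for (i in seq_along(sf)) {
    if (sf[i] == 0) sf[i] <- last else last <- sf[i]
  }
  cand <- which(diff(sf) < 0) + 1L        # slope + -> - : local maximum
  cand <- cand[sf[pmax(cand - 1L, 1L)] > 0]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(-y[cand])]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Build the DEJ ridge-envelope region of interest for one slice
#'
#' Interpolates a cubic spline through the ridge-top extrema of the DEJ
#' boundary (the superficial envelope) and another through the papillae
#' valleys (the deep envelope), extending both across the full width by
#' edge-value extrapolation. The region-of-interest mask covers the rows
#' between the two envelopes inclusive, expanded by `pad` pixels on both
#' sides so the true junction stays inside the mask in the presence of
#' fine-scale DEJ roughness. When fewer than two extrema of either kind are
#' found (a flat DEJ) the method falls back, with a warning, to a constant
#' band of half-width `fallback_halfband` around the traced DEJ.
#'
#' @inheritParams locate_dej_extrema
#' @param pad Extra rows added above and below the envelope band in the mask.
#' @param fallback_halfband Half-width (pixels) of the fallback band.
#' @return An object of class `envelope_roi`: numeric vectors `env_sup`
#'   (superficial envelope row per column), `env_deep`, a logical
#'   `roi_mask` (`depth x width`), and a `fallback` flag.
#' @export
build_envelope_roi <- function(boundaries, slice_idx, smooth_window = 9L,
                               min_separation = 12L, pad = 6L,
                               fallback_halfband = 4L) {
  stopifnot(inherits(boundaries, "boundary_set"))
  y <- boundaries$lower[slice_idx, ]
  nw <- length(y)
  ex <- locate_dej_extrema(boundaries, slice_idx, smooth_window, min_separation)
  fallback <- length(ex$maxima) < 2L || length(ex$minima) < 2L
  if (fallback) {
    warning(sprintf("slice %d: fewer than two DEJ extrema of a kind; using a constant band of half-width %d around the DEJ",
                    slice_idx, as.integer(fallback_halfband)), call. = FALSE)
    env_sup <- y - fallback_halfband
    env_deep <- y + fallback_halfband
  } else {
    # spline through the raw extreme values, then a lateral moving average to
    # damp spline oscillation between knots (a no-op for a clean periodic
    # ridge, whose envelopes are constant)
    env_sup <- smooth_vector(eval_envelope(ex$maxima, y[ex$maxima], nw),
                             smooth_window)
    env_deep <- smooth_vector(eval_envelope(ex$minima, y[ex$minima], nw),
                              smooth_window)
  }
  lo <- pmin(env_sup, env_deep)
  hi <- pmax(env_sup, env_deep)
  env_sup <- lo; env_deep <- hi
  depth_px <- infer_depth(boundaries)
  r0 <- clamp(round(env_sup) - pad, 1L, depth_px)
  r1 <- clamp(round(env_deep) + pad, 1L, depth_px)
  rows <- matrix(seq_len(depth_px), depth_px, nw)
  mask <- rows >= matrix(r0, depth_px, nw, byrow = TRUE) &
    rows <= matrix(r1, depth_px, nw, byrow = TRUE)
  structure(list(env_sup = env_sup, env_deep = env_deep, roi_mask = mask,
                 fallback = fallback, slice_idx = slice_idx),
            class = "envelope_roi")
}

# Cubic spline through (x, y), evaluated on 1..nw with edge-value
# extrapolation outside the extrema range.
eval_envelope <- function(x, y, nw) {
  if (length(x) == 1L) return(rep(y, nw))
  f <- stats::splinefun(x, y, method = "natural")
  f(clamp(seq_len(nw), min(x), max(x)))
}

# The boundary set does not carry depth explicitly; use the deepest traced
# row plus the fallback margin as the mask height reference.
infer_depth <- function(boundaries) {
  attr(boundaries, "depth_px") %||% as.integer(ceiling(max(boundaries$lower)) + 8L)
}

#' Envelope ROIs for every slice of a boundary set
#'
#' @inheritParams build_envelope_roi
#' @param depth_px Axial size of the volume the masks should match.
#' @return List of `envelope_roi` objects, one per slice.
#' @export
envelope_rois <- function(boundaries, depth_px = NULL, smooth_window = 9L,
                          min_separation = 12L, pad = 6L,
                          fallback_halfband = 4L) {
  if (!is.null(depth_px)) attr(boundaries, "depth_px") <- as.integer(depth_px)
  lapply(seq_len(nrow(boundaries$lower)), function(s)
    build_envelope_roi(boundaries, s, smooth_window, min_separation, pad,
                       fallback_halfband))
}
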