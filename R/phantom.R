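#' Parameters of the synthetic OCT fingertip phantom
#'
#' Bundles and validates the geometry, texture and deformation parameters of
#' the synthetic 3D OCT phantom. The phantom renders an epidermal band between
#' an undulating skin surface and a ridged dermis-epidermis junction (DEJ),
#' with multiplicative speckle and a pressure-dependent axial compression
#' model, and carries its exact ground-truth boundaries alongside so every
#' downstream stage can be scored against truth.
#'
#' The DEJ ridge pattern is a quasi-periodic oriented sinusoid whose
#' orientation drifts slowly across the volume. The skin surface undulates in
#' phase with the DEJ ridges (surface and internal fingerprint are
#' anatomically co-registered), so the epidermal thickness map is dominated by
#' fine-scale DEJ roughness (`dej_jitter_px`) on top of a weak smooth
#' component (`thickness_smooth_sd_px`) -- the structure that makes the
#' derived key look statistically random while staying reproducible.
#'
#' @param n_slices Number of B-scans in the stack.
#' @param depth_px Axial size of each B-scan in pixels.
#' @param width_px Lateral size of each B-scan in pixels.
#' @param ridge_period_px Period of the DEJ ridge pattern, pixels.
#' @param ridge_amp_px Peak-to-valley amplitude of the DEJ ridges, pixels.
#' @param mean_epi_thickness_px Mean distance between the skin surface and the
#'   DEJ, pixels.
#' @param thickness_field_scale Correlation length (pixels) of the slowly
#'   varying random fields (surface undulation, smooth thickness component,
#'   ridge-orientation drift, pressure perturbation).
#' @param surface_depth_px Mean depth of the skin surface below the top of the
#'   B-scan, pixels.
#' @param surface_smooth_sd_px Standard deviation of the smooth surface
#'   undulation, pixels.
#' @param dej_jitter_px Amplitude of the per-(slice, column) pixel-scale DEJ
#'   roughness: each position is independently displaced by `-a`, `0` or `+a`
#'   pixels with equal probability. The three-level form bounds the
#'   column-to-column excursion of the DEJ at `2*a` pixels, which keeps the
#'   roughness within reach of a continuity-constrained boundary tracer
#'   while staying uncorrelated between neighbouring positions.
#' @param thickness_smooth_sd_px Standard deviation of the smooth component of
#'   the thickness field, pixels.
#' @param speckle_sigma Log-sd of the multiplicative speckle noise.
#' @param pressure_kpa Applied contact pressure in kPa (0 = unloaded).
#' @param compression_coeff Fractional axial thickness reduction per kPa.
#' @param pressure_perturb_px_per_kpa Standard deviation (pixels per kPa) of
#'   the smooth random thickness perturbation accompanying a pressure change,
#'   emulating non-uniform tissue redistribution between scans.
#' @param slice_spacing_um Physical slice spacing, metadata only.
#' @param seed Integer RNG seed; the phantom is bit-reproducible given
#'   (parameters, seed).
#'
#' @return An object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(n_slices = 400L,
                           depth_px = 248L,
                           width_px = 345L,
                           ridge_period_px = 36,
                           ridge_amp_px = 24,
                           mean_epi_thickness_px = 48,
                           thickness_field_scale = 30,
                           surface_depth_px = 60,
                           surface_smooth_sd_px = 3,
                           dej_jitter_px = 0.8,
                           thickness_smooth_sd_px = 0.1,
                           speckle_sigma = 0.12,
                           pressure_kpa = 0,
                           compression_coeff = 0.005,
                           pressure_perturb_px_per_kpa = 0.06,
                           slice_spacing_um = 25,
                           seed = 1L) {
  p <- list(
    n_slices = as.integer(n_slices), depth_px = as.integer(depth_px),
    width_px = as.integer(width_px), ridge_period_px = ridge_period_px,
    ridge_amp_px = ridge_amp_px,
    mean_epi_thickness_px = mean_epi_thickness_px,
    thickness_field_scale = thickness_field_scale,
    surface_depth_px = surface_depth_px,
    surface_smooth_sd_px = surface_smooth_sd_px,
    dej_jitter_px = dej_jitter_px,
    thickness_smooth_sd_px = thickness_smooth_sd_px,
    speckle_sigma = speckle_sigma, pressure_kpa = pressure_kpa,
    compression_coeff = compression_coeff,
    pressure_perturb_px_per_kpa = pressure_perturb_px_per_kpa,
    slice_spacing_um = slice_spacing_um, seed = as.integer(seed)
  )
  for (f in c("n_slices", "depth_px", "width_px"))
    assert_scalar_num(p[[f]], f, lo = 1)
  assert_scalar_num(p$ridge_period_px, "ridge_period_px", lo = 2)
  assert_scalar_num(p$ridge_amp_px, "ridge_amp_px", lo = 0)
  assert_scalar_num(p$speckle_sigma, "speckle_sigma", lo = 0)
  assert_scalar_num(p$pressure_kpa, "pressure_kpa", lo = 0)
  assert_scalar_num(p$compression_coeff, "compression_coeff", lo = 0)
  if (p$ridge_amp_px >= p$depth_px / 4)
    stopf("ridge_amp_px (%g) must be < depth_px/4 (%g)",
          p$ridge_amp_px, p$depth_px / 4)
  if (p$mean_epi_thickness_px + p$ridge_amp_px >= p$depth_px)
    stopf("epidermal band (mean thickness %g + ridge amplitude %g) exceeds depth_px %d",
          p$mean_epi_thickness_px, p$ridge_amp_px, p$depth_px)
  if (p$surface_depth_px + p$mean_epi_thickness_px + p$ridge_amp_px >= p$depth_px)
    stopf("surface depth plus epidermal band exceeds depth_px")
  structure(p, class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf("OCT phantom parameters: %d slices x %d depth x %d width px\n",
              x$n_slices, x$depth_px, x$width_px))
  cat(sprintf("  DEJ ridges: period %g px, peak-to-valley %g px; mean epidermal thickness %g px\n",
              x$ridge_period_px, x$ridge_amp_px, x$mean_epi_thickness_px))
  cat(sprintf("  speckle sigma %g, pressure %g kPa (compression %g/kPa), seed %d\n",
              x$speckle_sigma, x$pressure_kpa, x$compression_coeff, x$seed))
  invisible(x)
}

# Tissue reflectivity levels of the rendered phantom (arbitrary units in
# [0,1]). Epidermis is kept >= 2x the brighter background (dermis). The
# epidermal signal decays exponentially with depth below the surface, the
# standard OCT roll-off; the attenuation coefficient is fixed relative to
# the mean epidermal thickness (`attenuation_budget` optical depths across
# the band), so the junction contrast and the en-face projection behaviour
# are invariant to the pixel scale of the phantom. It is this decay that
# makes the maximum intensity projection encode the DEJ ridge topography.
# The junction itself is rendered mildly hyperreflective (`dej_line_gain`
# times the local epidermal signal), the usual appearance of the papillary
# interface, which sharpens the DEJ edge for segmentation.
.phantom_levels <- list(air = 0.03, epidermis = 0.5, dermis = 0.11,
                        attenuation_budget = 0.67, dej_line_gain = 1.2)

#' Ground-truth boundary fields of a phantom
#'
#' Draws the ground-truth upper (surface) and lower (DEJ) boundary fields for
#' a phantom, at the pressure stored in `params`. Both are `n_slices x
#' width_px` matrices of depth coordinates (1-based rows, increasing
#' downward). Deterministic given (`params`, `params$seed`).
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `oct_ground_truth` with elements `upper`,
#'   `lower` and `thickness` (= `lower - upper`).
#' @export
phantom_truth <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  tr <- local_seed(p$seed, {
    ns <- p$n_slices; nw <- p$width_px
    scale <- p$thickness_field_scale
    # Ridge field: oriented sinusoid, orientation drifting slowly. The mean
    # orientation leans the ridges across the slice axis, so the ridge
    # slope seen along the columns of one B-scan stays gentle (fingerprint
    # ridges are rarely aligned with the scan raster).
    theta <- 0.9 + 0.1 * smooth_field(ns, nw, scale * 2)
    s_ix <- matrix(seq_len(ns), ns, nw)
    c_ix <- matrix(seq_len(nw), ns, nw, byrow = TRUE)
    phase <- 2 * pi / p$ridge_period_px * (c_ix * cos(theta) + s_ix * sin(theta))
    ridge <- (p$ridge_amp_px / 2) * sin(phase)
    surf <- if (p$surface_smooth_sd_px > 0)
      p$surface_smooth_sd_px * smooth_field(ns, nw, scale) else 0
    upper <- p$surface_depth_px + surf + ridge
    th_smooth <- if (p$thickness_smooth_sd_px > 0)
      p$thickness_smooth_sd_px * smooth_field(ns, nw, scale) else 0
    jitter <- if (p$dej_jitter_px > 0)
      p$dej_jitter_px * matrix(sample(c(-1, 0, 1), ns * nw, replace = TRUE),
                               ns, nw) else 0
    thickness <- p$mean_epi_thickness_px + th_smooth + jitter
    list(upper = upper, lower = upper + thickness)
  })
  gt <- new_ground_truth(tr$upper, tr$lower, p$depth_px)
  if (p$pressure_kpa > 0) gt <- apply_pressure(gt, p, p$pressure_kpa)
  gt
}

new_ground_truth <- function(upper, lower, depth_px) {
  if (any(lower <= upper))
    stopf("invalid phantom geometry: lower boundary does not stay below the upper boundary")
  if (any(upper < 1) || any(lower > depth_px))
    stopf("invalid phantom geometry: epidermal band exceeds the axial field of view")
  structure(list(upper = upper, lower = lower, thickness = lower - upper,
                 depth_px = depth_px),
            class = "oct_ground_truth")
}

#' @export
print.oct_ground_truth <- function(x, ...) {
  cat(sprintf("Ground-truth boundaries: %d slices x %d columns, depth %d px\n",
              nrow(x$upper), ncol(x$upper), x$depth_px))
  cat(sprintf("  thickness: mean %.2f px, range [%.2f, %.2f] px\n",
              mean(x$thickness), min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' Render an OCT intensity volume from ground-truth boundaries
#'
#' Renders a three-layer reflectivity model (air / epidermis / dermis, the
#' epidermal band at least twice as bright as the dermis background) and
#' multiplies it by log-normal speckle (`exp(sigma*Z - sigma^2/2)`, unit
#' mean), clipping to \[0,1\] and quantizing to the 16-bit grid so volumes
#' round-trip losslessly through TIFF. Speckle is seeded from `params$seed +
#' seed_offset`, so re-rendering the same tissue at a different offset
#' emulates an independent re-scan.
#'
#' @param truth An `oct_ground_truth` object.
#' @param params A [phantom_params()] object.
#' @param seed_offset Integer offset added to `params$seed` for the speckle
#'   draw.
#' @return An object of class `oct_volume`: list with `data`, a
#'   `(slice, depth, width)` array in \[0,1\], and `slice_spacing_um`.
#' @export
render_volume <- function(truth, params, seed_offset = 0L) {
  stopifnot(inherits(truth, "oct_ground_truth"), inherits(params, "phantom_params"))
  p <- params
  ns <- nrow(truth$upper); nw <- ncol(truth$upper); nd <- p$depth_px
  lv <- .phantom_levels
  u <- round(truth$upper); l <- round(truth$lower)
  vol <- array(lv$air, dim = c(ns, nd, nw))
  rows <- matrix(seq_len(nd), nd, nw)
  for (s in seq_len(ns)) {
    us <- matrix(u[s, ], nd, nw, byrow = TRUE)
    ls <- matrix(l[s, ], nd, nw, byrow = TRUE)
    sl <- matrix(lv$air, nd, nw)
    sl[rows > ls] <- lv$dermis
    att <- lv$attenuation_budget / p$mean_epi_thickness_px
    band <- rows >= us & rows <= ls
    decay <- exp(-att * (rows - us))
    sl[band] <- lv$epidermis * decay[band]
    line <- rows == ls & band
    sl[line] <- lv$dej_line_gain * lv$epidermis * decay[line]
    vol[s, , ] <- sl
  }
  if (p$speckle_sigma > 0) {
    vol <- local_seed(p$seed + as.integer(seed_offset), {
      z <- array(stats::rnorm(length(vol)), dim = dim(vol))
      vol * exp(p$speckle_sigma * z - p$speckle_sigma^2 / 2)
    })
  }
  vol <- round(clamp(vol, 0, 1) * 65535) / 65535
  new_oct_volume(vol, p$slice_spacing_um)
}

new_oct_volume <- function(data, slice_spacing_um = 25) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (min(data) < 0 || max(data) > 1)
    stopf("OCT volume intensities must lie in [0, 1]")
  structure(list(data = data, slice_spacing_um = slice_spacing_um),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OCT volume: %d slices x %d depth x %d width px (spacing %g um)\n",
              d[1], d[2], d[3], x$slice_spacing_um))
  cat(sprintf("  intensity range [%.4f, %.4f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Generate a synthetic OCT fingertip volume with ground truth
#'
#' Convenience wrapper: draws ground-truth boundaries with [phantom_truth()]
#' (applying the pressure stored in `params`) and renders the intensity
#' volume with [render_volume()].
#'
#' @inheritParams phantom_truth
#' @return A list with elements `volume` (an `oct_volume`) and `truth` (an
#'   `oct_ground_truth`).
#' @export
#' @examples
#' ph <- generate_volume(phantom_params(n_slices = 8, depth_px = 60,
#'                                      width_px = 40, ridge_period_px = 12,
#'                                      ridge_amp_px = 8,
#'                                      mean_epi_thickness_px = 20,
#'                                      surface_depth_px = 14))
#' ph$volume
generate_volume <- function(params) {
  truth <- phantom_truth(params)
  list(volume = render_volume(truth, params), truth = truth)
}

#' Apply contact pressure to ground-truth boundaries
#'
#' Models the effect of scanning the same fingertip under a different contact
#' pressure: the epidermal thickness field is compressed axially by the
#' factor `1 - compression_coeff * pressure_kpa` and perturbed by a smooth
#' random field whose standard deviation grows linearly with pressure
#' (`pressure_perturb_px_per_kpa`), emulating non-uniform tissue
#' redistribution between scans. The relative thickness pattern is preserved.
#' A zero pressure or a zero compression coefficient leaves the thickness map
#' unchanged.
#'
#' @param truth An `oct_ground_truth` object (unloaded geometry).
#' @param params A [phantom_params()] object.
#' @param pressure_kpa Applied pressure in kPa.
#' @return A new `oct_ground_truth` with the deformed lower boundary.
#' @export
apply_pressure <- function(truth, params, pressure_kpa) {
  stopifnot(inherits(truth, "oct_ground_truth"), inherits(params, "phantom_params"))
  assert_scalar_num(pressure_kpa, "pressure_kpa", lo = 0)
  p <- params
  if (pressure_kpa == 0 || p$compression_coeff == 0) return(truth)
  scale <- 1 - p$compression_coeff * pressure_kpa
  if (scale <= 0)
    stopf("compression at %g kPa collapses the epidermal thickness (scale %g <= 0)",
          pressure_kpa, scale)
  thick <- truth$thickness * scale
  sd_pert <- p$pressure_perturb_px_per_kpa * pressure_kpa
  if (sd_pert > 0) {
    pert <- local_seed(p$seed + 7919L + as.integer(round(1000 * pressure_kpa)), {
      sd_pert * smooth_field(nrow(thick), ncol(thick), p$thickness_field_scale)
    })
    thick <- thick + pert
  }
  if (any(thick <= 0))
    stopf("pressure deformation produced non-positive epidermal thickness")
  new_ground_truth(truth$upper, truth$upper + thick, truth$depth_px)
}
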