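# Shared phantom geometry for tests: scaled-down stack with the same
# band-contrast, roughness and ridge-slope proportions as the defaults.
small_params <- function(seed = 1L, n_slices = 130L, width_px = 160L, ...) {
  phantom_params(n_slices = n_slices, depth_px = 90L, width_px = width_px,
                 ridge_period_px = 24, ridge_amp_px = 14,
                 mean_epi_thickness_px = 28, surface_depth_px = 20,
                 thickness_field_scale = 16, seed = seed, ...)
}

# Memoised fixtures: phantoms and derived keys are reused across test files
# within one session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

small_phantom <- function(seed = 1L) {
  cached(paste0("phantom", seed), generate_volume(small_params(seed)))
}

# Tall phantom able to hold two disjoint 101-slice key regions.
tall_phantom <- function(seed = 2L) {
  cached(paste0("tall", seed),
         generate_volume(small_params(seed, n_slices = 230L)))
}

tall_keys <- function(seed = 2L) {
  cached(paste0("tallkeys", seed), {
    ph <- tall_phantom(seed)
    list(k1 = generate_key(ph$volume, center = c(80, 60), ridge_period_px = 24),
         k2 = generate_key(ph$volume, center = c(80, 170), ridge_period_px = 24))
  })
}

# The deterministic ridge component of the phantom DEJ (truth channel),
# reconstructed from the same seeded draw order as phantom_truth().
true_ridge_field <- function(params) {
  octkey:::local_seed(params$seed, {
    ns <- params$n_slices; nw <- params$width_px
    scale <- params$thickness_field_scale
    theta <- 0.9 + 0.1 * octkey:::smooth_field(ns, nw, scale * 2)
    s_ix <- matrix(seq_len(ns), ns, nw)
    c_ix <- matrix(seq_len(nw), ns, nw, byrow = TRUE)
    (params$ridge_amp_px / 2) *
      sin(2 * pi / params$ridge_period_px * (c_ix * cos(theta) + s_ix * sin(theta)))
  })
}

# Flat, noiseless degenerate phantom (constant thickness, no ridges).
flat_params <- function(thickness = 20, seed = 1L) {
  phantom_params(n_slices = 12L, depth_px = 70L, width_px = 50L,
                 ridge_period_px = 16, ridge_amp_px = 0,
                 mean_epi_thickness_px = thickness, surface_depth_px = 15,
                 surface_smooth_sd_px = 0, dej_jitter_px = 0,
                 thickness_smooth_sd_px = 0, speckle_sigma = 0, seed = seed)
}
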