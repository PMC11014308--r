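test_that("noiseless flat phantom is traced within 1 px everywhere", {
  ph <- generate_volume(flat_params(thickness = 20))
  b <- segment_boundaries(ph$volume)
  expect_lte(max(abs(b$upper - round(ph$truth$upper))), 1)
  expect_lte(max(abs(b$lower - round(ph$truth$lower))), 1)
  expect_true(all(b$valid))
})

test_that("speckled phantoms are traced with mean error at most 2 px (5 seeds)", {
  for (seed in 1:5) {
    p <- small_params(seed = seed, n_slices = 25L, width_px = 80L)
    ph <- generate_volume(p)
    b <- segment_boundaries(ph$volume)
    err <- mean(abs(b$upper - round(ph$truth$upper))) +
      mean(abs(b$lower - round(ph$truth$lower)))
    expect_lte(err, 2)
    expect_true(all(b$lower[b$valid] > b$upper[b$valid]))
  }
})

test_that("a constant-intensity volume raises a detectable-band error", {
  vol <- octkey:::new_oct_volume(array(0.4, dim = c(3, 50, 40)))
  expect_error(segment_boundaries(vol), "no detectable")
})

test_that("tracing is deterministic", {
  ph <- small_phantom(seed = 1)
  b1 <- segment_boundaries(ph$volume)
  b2 <- segment_boundaries(ph$volume)
  expect_identical(b1$upper, b2$upper)
  expect_identical(b1$lower, b2$lower)
})

test_that("on single-column images the tracer equals the brute-force gradient scan", {
  p <- flat_params(thickness = 18)
  ph <- generate_volume(p)
  one <- octkey:::new_oct_volume(ph$volume$data[, , 1, drop = FALSE])
  b <- segment_boundaries(one)
  profile <- ph$volume$data[, , 1]
  for (s in seq_len(dim(profile)[1])) {
    g <- diff(profile[s, ])
    expect_equal(unname(b$upper[s, 1]), unname(which.max(g) + 1L))
    expect_equal(unname(b$lower[s, 1]), unname(which.min(g)))
  }
})

sin_boundary_set <- function(width = 120, period = 24, amp = 6, base = 40) {
  y <- base + amp * sin(2 * pi * seq_len(width) / period)
  octkey:::new_boundary_set(upper = matrix(10, 1, width),
                            lower = matrix(y, 1, width),
                            valid = matrix(TRUE, 1, width))
}

test_that("extrema of a sinusoidal DEJ are spaced half a period apart", {
  period <- 24
  bs <- sin_boundary_set(period = period)
  ex <- locate_dej_extrema(bs, 1, smooth_window = 5, min_separation = 8)
  pos <- sort(c(ex$maxima, ex$minima))
  expect_gte(length(pos), 6)
  expect_true(all(abs(diff(pos) - period / 2) <= 1))
  # ridge tops ("maxima") are the superficial points: smaller row values
  y <- bs$lower[1, ]
  expect_lt(max(y[ex$maxima]), min(y[ex$minima]))
})

test_that("a monotone ramp boundary has no interior extrema", {
  bs <- octkey:::new_boundary_set(upper = matrix(10, 1, 60),
                                  lower = matrix(seq(30, 59.5, by = 0.5), 1, 60),
                                  valid = matrix(TRUE, 1, 60))
  ex <- locate_dej_extrema(bs, 1, smooth_window = 5, min_separation = 5)
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)
  expect_true(isTRUE(attr(ex, "flat")))
})

test_that("phantom DEJ extrema depths match ground-truth crests within 2 px", {
  p <- small_params(seed = 3, speckle_sigma = 0, dej_jitter_px = 0)
  ph <- generate_volume(p)
  b <- segment_boundaries(ph$volume)
  ex <- locate_dej_extrema(b, 60, smooth_window = 6, min_separation = 8)
  truth <- ph$truth$lower[60, ]
  for (col in ex$maxima) {
    win <- max(1, col - 4):min(length(truth), col + 4)
    expect_lte(abs(b$lower[60, col] - min(truth[win])), 2)
  }
  for (col in ex$minima) {
    win <- max(1, col - 4):min(length(truth), col + 4)
    expect_lte(abs(b$lower[60, col] - max(truth[win])), 2)
  }
})

test_that("envelope separation of a sinusoidal DEJ equals twice the amplitude", {
  amp <- 6
  bs <- sin_boundary_set(period = 24, amp = amp)
  attr(bs, "depth_px") <- 70L
  roi <- build_envelope_roi(bs, 1, smooth_window = 5, min_separation = 8)
  mid <- 40:80
  sep <- roi$env_deep[mid] - roi$env_sup[mid]
  expect_true(all(abs(sep - 2 * amp) <= 1))
  expect_false(roi$fallback)
})

test_that("a flat DEJ triggers the constant-band fallback with a warning", {
  bs <- octkey:::new_boundary_set(upper = matrix(10, 1, 60),
                                  lower = matrix(40, 1, 60),
                                  valid = matrix(TRUE, 1, 60))
  attr(bs, "depth_px") <- 70L
  expect_warning(roi <- build_envelope_roi(bs, 1), "fallback|constant band")
  expect_true(roi$fallback)
  expect_true(any(roi$roi_mask[, 30]))
})

test_that("the ROI mask contains the true DEJ for at least 98% of columns", {
  ph <- small_phantom(seed = 2)
  p <- small_params(seed = 2)
  b <- segment_boundaries(ph$volume)
  rois <- envelope_rois(b, depth_px = p$depth_px, smooth_window = 6,
                        min_separation = 8)
  inside <- vapply(seq_len(p$n_slices), function(s) {
    r <- round(ph$truth$lower[s, ])
    mean(rois[[s]]$roi_mask[cbind(r, seq_len(p$width_px))])
  }, numeric(1))
  expect_gte(mean(inside), 0.98)
})
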