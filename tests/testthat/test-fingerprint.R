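make_roi_list <- function(n_slices, depth, width, r0, r1) {
  mask <- matrix(FALSE, depth, width)
  mask[r0:r1, ] <- TRUE
  rep(list(structure(list(env_sup = rep(r0, width), env_deep = rep(r1, width),
                          roi_mask = mask, fallback = FALSE),
                     class = "envelope_roi")), n_slices)
}

test_that("MIP picks a single bright voxel and preserves uniform volumes", {
  arr <- array(0.1, dim = c(3, 30, 20))
  arr[2, 15, 7] <- 0.9
  vol <- octkey:::new_oct_volume(arr)
  rois <- make_roi_list(3, 30, 20, 10, 20)
  fp <- mip_project(vol, rois)
  expect_equal(fp$data[7, 2], 0.9)
  expect_equal(fp$data[7, 1], 0.1)

  uni <- octkey:::new_oct_volume(array(0.37, dim = c(3, 30, 20)))
  expect_true(all(mip_project(uni, rois)$data == 0.37))
})

test_that("MIP is bounded by the column maximum and depth-permutation invariant", {
  ph <- small_phantom(seed = 1)
  p <- small_params(seed = 1)
  b <- segment_boundaries(ph$volume)
  rois <- envelope_rois(b, depth_px = p$depth_px, smooth_window = 6,
                        min_separation = 8)
  fp <- mip_project(ph$volume, rois)
  for (s in c(1L, 60L)) {
    colmax <- apply(ph$volume$data[s, , ], 2L, max)
    expect_true(all(fp$data[, s] <= colmax + 1e-12))
  }
  # permuting intensities along depth inside the ROI leaves the MIP unchanged
  vol2 <- ph$volume
  s <- 5L
  m <- rois[[s]]$roi_mask
  sl <- vol2$data[s, , ]
  for (cc in seq_len(ncol(m))) {
    rows <- which(m[, cc])
    sl[rows, cc] <- sl[rev(rows), cc]
  }
  vol2$data[s, , ] <- sl
  fp2 <- mip_project(vol2, rois)
  expect_equal(fp2$data[, s], fp$data[, s])
})

test_that("the MIP fingerprint reproduces the DEJ ridge topography", {
  for (seed in c(2L, 3L)) {
    p <- small_params(seed = seed)
    ph <- cached(paste0("phantom", seed), generate_volume(p))
    b <- segment_boundaries(ph$volume)
    rois <- envelope_rois(b, depth_px = p$depth_px, smooth_window = 6,
                          min_separation = 8)
    fp <- mip_project(ph$volume, rois)
    ridge <- true_ridge_field(p)
    # compare ridge-band content: remove the slowly varying level from both
    m <- t(fp$data)
    hp <- m - octkey:::blur_matrix(m, 16)
    rh <- ridge - octkey:::blur_matrix(ridge, 16)
    expect_gte(abs(cor(as.vector(hp), as.vector(rh))), 0.6)
  }
})

test_that("center ROI spans match the stated geometry", {
  fp <- structure(list(data = matrix(0.5, 200, 200),
                       empty = matrix(FALSE, 200, 200)),
                  class = "fingerprint_image")
  roi <- select_center_roi(fp, center = c(60, 60), half_width = 50)
  expect_equal(range(roi$column_range), c(10, 110))
  expect_equal(range(roi$slice_range), c(10, 110))
  expect_length(roi$column_range, 101)

  tiny <- select_center_roi(fp, center = c(60, 60), half_width = 0)
  expect_length(tiny$column_range, 1)

  expect_error(select_center_roi(fp, center = c(20, 100), half_width = 50),
               "top")
  expect_error(select_center_roi(fp, center = c(100, 190), half_width = 50),
               "right")
})

test_that("automatic center lands near the pattern center of a symmetric phantom", {
  ph <- small_phantom(seed = 1)
  p <- small_params(seed = 1)
  b <- segment_boundaries(ph$volume)
  rois <- envelope_rois(b, depth_px = p$depth_px, smooth_window = 6,
                        min_separation = 8)
  fp <- mip_project(ph$volume, rois)
  roi <- select_center_roi(fp, center = "auto", half_width = 20,
                           ridge_period_px = p$ridge_period_px)
  true_center <- c(nrow(fp$data), ncol(fp$data)) / 2
  expect_lte(max(abs(roi$center - true_center)), 5)
})

test_that("cropped flat-phantom stacks count the full band in every column", {
  thickness <- 20
  ph <- generate_volume(flat_params(thickness = thickness))
  b <- segment_boundaries(ph$volume)
  masks <- epidermis_masks(b, 70L)
  roi <- structure(list(center = c(25L, 6L), half_width = 5L,
                        column_range = 20:30, slice_range = 1:11),
                   class = "center_roi")
  stack <- crop_epidermis_stack(masks, roi)
  counts <- count_thickness(stack)
  expect_true(all(counts == thickness + 1))
})

test_that("degenerate and out-of-range crops are handled", {
  masks <- array(0L, dim = c(10, 30, 20))
  roi <- structure(list(center = c(10L, 5L), half_width = 3L,
                        column_range = 7:13, slice_range = 2:8),
                   class = "center_roi")
  stack <- crop_epidermis_stack(masks, roi)
  expect_true(isTRUE(attr(stack, "all_black")))

  bad <- structure(list(center = c(10L, 9L), half_width = 3L,
                        column_range = 7:13, slice_range = 6:12),
                   class = "center_roi")
  expect_error(crop_epidermis_stack(masks, bad), "slice range")
})
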