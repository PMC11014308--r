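# Literal DCT-II definition, quadruple loop — the independent oracle.
naive_dct2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    s <- 0
    for (i in 0:(n - 1)) for (j in 0:(m - 1)) {
      s <- s + x[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * u / (2 * n)) *
        cos(pi * (2 * j + 1) * v / (2 * m))
    }
    au <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    av <- if (v == 0) sqrt(1 / m) else sqrt(2 / m)
    out[u + 1, v + 1] <- au * av * s
  }
  out
}

unit_key <- function(n, m = n) {
  structure(list(data = matrix(1, n, m), offset = 1), class = "resized_key")
}

random_key <- function(n, m = n) {
  structure(list(data = matrix(runif(n * m, 1, 256), n, m), offset = 1),
            class = "resized_key")
}

test_that("encryption with a unit key and full spectrum is the plain DCT", {
  withr::with_seed(11, {
    plain <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    ci <- encrypt_image(plain, unit_key(8), lowpass_frac = 1)
    expect_equal(ci$data, dct2(plain), tolerance = 1e-12)
    expect_equal(ci$data, naive_dct2(plain), tolerance = 1e-9)
    expect_true(all(encrypt_image(matrix(0L, 8, 8), unit_key(8), 1)$data == 0))
  })
})

test_that("encryption equals DCT-then-mask-then-multiply for arbitrary keys", {
  withr::with_seed(12, {
    plain <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    key <- random_key(8)
    ci <- encrypt_image(plain, key, lowpass_frac = 0.5)
    ref <- naive_dct2(plain)
    ref[5:8, ] <- 0; ref[, 5:8] <- 0
    expect_equal(ci$data, ref * key$data, tolerance = 1e-9)
  })
})

test_that("decryption with the correct key and full spectrum is bit-exact", {
  withr::with_seed(13, {
    for (i in 1:5) {
      plain <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
      key <- random_key(32)
      expect_identical(decrypt_image(encrypt_image(plain, key, 1), key), plain)
    }
  })
})

test_that("round-trip quality is non-increasing as the low-pass cutoff shrinks", {
  ks <- tall_keys(seed = 2)
  plain <- demo_image(128)
  rk <- resize_key(ks$k1, c(128, 128))
  ssims <- vapply(c(1, 0.5, 0.25, 0.125), function(f)
    img_ssim(plain, decrypt_image(encrypt_image(plain, rk, f), rk)),
    numeric(1))
  expect_true(all(diff(ssims) <= 0))
})

test_that("the correct key beats mismatched keys from a disjoint region", {
  ks <- tall_keys(seed = 2)
  plain <- demo_image(128)
  rk1 <- resize_key(ks$k1, c(128, 128))
  rk2 <- resize_key(ks$k2, c(128, 128))
  ci <- encrypt_image(plain, rk1, 0.5)
  good <- img_ssim(plain, decrypt_image(ci, rk1))
  bad <- img_ssim(plain, decrypt_image(ci, rk2))
  expect_gt(good, bad)
})

test_that("perturbing one key pixel changes only the coefficient it multiplies", {
  withr::with_seed(14, {
    plain <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    key <- random_key(16)
    ci <- encrypt_image(plain, key, 1)
    key2 <- key
    key2$data[5, 9] <- key2$data[5, 9] + 1
    ci2 <- encrypt_image(plain, key2, 1)
    d <- ci2$data - ci$data
    expect_true(d[5, 9] != 0)
    d[5, 9] <- 0
    expect_true(all(d == 0))
  })
})

test_that("key resizing is division-safe and interpolates exactly at grid points", {
  key <- octkey:::new_key_image(matrix(sample(0:255, 101 * 101, TRUE), 101, 101))
  same <- resize_key(key, c(101, 101))
  expect_equal(same$data, key$data + 1, tolerance = 1e-9)

  const <- resize_key(octkey:::new_key_image(matrix(40L, 101, 101)),
                      c(256, 256))
  expect_equal(unique(round(as.vector(const$data), 9)), 41)

  big <- resize_key(key, c(256, 256))
  expect_equal(dim(big$data), c(256L, 256L))
  expect_gte(min(big$data), 1)
  expect_lte(max(big$data), 256)
  expect_error(resize_key(key, c(1, 1)), "2 x 2")
})

test_that("shape mismatches and zero keys are rejected", {
  key <- unit_key(8)
  expect_error(encrypt_image(matrix(0L, 4, 4), key), "4 x 4")
  ci <- encrypt_image(matrix(1L, 8, 8), key, 1)
  zkey <- key; zkey$data[1, 1] <- 0
  expect_error(decrypt_image(ci, zkey), "zero")
  expect_error(encrypt_image(matrix(300, 8, 8), key), "\\[0, 255\\]")
})
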