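# Scalar transcriptions of the similarity and randomness formulas, written
# with explicit loops so they are independent of the vectorized paths.
scalar_ssim <- function(a, b, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  n <- length(a)
  ma <- 0; mb <- 0
  for (v in a) ma <- ma + v / n
  for (v in b) mb <- mb + v / n
  va <- 0; vb <- 0; cab <- 0
  for (i in seq_len(n)) {
    va <- va + (a[i] - ma)^2 / n
    vb <- vb + (b[i] - mb)^2 / n
    cab <- cab + (a[i] - ma) * (b[i] - mb) / n
  }
  (2 * ma * mb + c1) * (2 * cab + c2) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

scalar_ncc <- function(a, b) {
  num <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]; sa <- sa + a[i]^2; sb <- sb + b[i]^2
  }
  num / sqrt(sa * sb)
}

scalar_cor <- function(x, y) {
  J <- length(x)
  mx <- sum(x) / J; my <- sum(y) / J
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(J)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

scalar_entropy <- function(img) {
  h <- 0
  for (g in 0:255) {
    p <- sum(img == g) / length(img)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

test_that("SSIM equals its term-by-term transcription and is symmetric", {
  withr::with_seed(21, {
    a <- matrix(sample(0:255, 64, TRUE), 8, 8)
    b <- matrix(sample(0:255, 64, TRUE), 8, 8)
    expect_equal(img_ssim(a, b), scalar_ssim(as.vector(a), as.vector(b)),
                 tolerance = 1e-12)
    expect_equal(img_ssim(a, b), img_ssim(b, a), tolerance = 1e-15)
    expect_equal(img_ssim(a, a), 1, tolerance = 1e-12)
    expect_lte(img_ssim(a, b), 1)
  })
})

test_that("SSIM of a binary image with its negative is negative", {
  a <- matrix(rep(c(0, 255), 32), 8, 8)
  expect_lt(img_ssim(a, 255 - a), 0)
})

test_that("the printed-constant SSIM variant is exposed but not the default", {
  withr::with_seed(22, {
    a <- matrix(sample(0:255, 64, TRUE), 8, 8)
    b <- matrix(sample(0:255, 64, TRUE), 8, 8)
    std <- img_ssim(a, b)
    alt <- img_ssim(a, b, variant = "printed")
    expect_false(isTRUE(all.equal(std, alt)))
  })
})

test_that("NCC matches its transcription, self-NCC is 1, and scaling drops out", {
  withr::with_seed(23, {
    a <- matrix(runif(64, 0, 255), 8, 8)
    b <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(img_ncc(a, b), scalar_ncc(as.vector(a), as.vector(b)),
                 tolerance = 1e-12)
    expect_equal(img_ncc(a, a), 1, tolerance = 1e-12)
    expect_equal(img_ncc(a, 3.7 * a), 1, tolerance = 1e-12)
    expect_equal(img_ncc(matrix(c(1, 0, 0, 0), 2, 2),
                         matrix(c(0, 0, 1, 0), 2, 2)), 0)
    expect_error(img_ncc(matrix(0, 2, 2), a[1:2, 1:2]), "all-zero")
  })
})

test_that("adjacent-pixel correlation recovers exact linear structure", {
  grad <- matrix(rep(1:40, each = 30), 30, 40, byrow = FALSE)
  grad <- t(apply(grad, 1, function(r) seq_len(40)))
  expect_equal(adjacent_correlation(grad, "horizontal", J = 2000, seed = 1), 1,
               tolerance = 1e-9)
  checker <- 255 * outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  expect_equal(adjacent_correlation(checker, "horizontal", J = 2000, seed = 1),
               -1, tolerance = 1e-9)
  expect_error(adjacent_correlation(matrix(7, 10, 10), "vertical", seed = 1),
               "degenerate")
})

test_that("adjacent-pixel correlation matches its transcription on fixed pairs", {
  withr::with_seed(24, {
    img <- matrix(sample(0:255, 400, TRUE), 20, 20)
    got <- adjacent_correlation(img, "diagonal", J = 500, seed = 99)
    pairs <- octkey:::local_seed(99, {
      i <- sample.int(19, 500, replace = TRUE)
      j <- sample.int(19, 500, replace = TRUE)
      cbind(i, j)
    })
    x <- img[pairs]; y <- img[pairs + 1L]
    expect_equal(got, scalar_cor(x, y), tolerance = 1e-12)
  })
})

test_that("random images have near-zero adjacent correlation (20 seeds)", {
  withr::with_seed(25, {
    img <- matrix(sample(0:255, 128 * 128, TRUE), 128, 128)
    for (s in 1:20) {
      expect_lt(abs(adjacent_correlation(img, "horizontal", J = 5000,
                                         seed = s)), 0.05)
    }
  })
})

test_that("adjacent correlation is invariant to positive affine maps", {
  withr::with_seed(26, {
    img <- matrix(sample(0:255, 900, TRUE), 30, 30)
    a <- adjacent_correlation(img, "vertical", J = 1000, seed = 5)
    b <- adjacent_correlation(2.5 * img + 11, "vertical", J = 1000, seed = 5)
    expect_equal(a, b, tolerance = 1e-12)
  })
})

test_that("entropy spans its analytic anchors", {
  expect_equal(img_entropy(matrix(17L, 10, 10)), 0)
  two <- matrix(rep(c(0L, 255L), 50), 10, 10)
  expect_equal(img_entropy(two), 1, tolerance = 1e-12)
  uniform <- matrix(rep(0:255, 4), 32, 32)
  expect_equal(img_entropy(uniform), 8, tolerance = 1e-12)
  withr::with_seed(27, {
    img <- matrix(sample(0:255, 1024, TRUE), 32, 32)
    expect_equal(img_entropy(img), scalar_entropy(img), tolerance = 1e-12)
    expect_lte(img_entropy(img), 8)
  })
})

test_that("gray histograms count every pixel once", {
  h <- gray_histogram(matrix(7L, 2, 5))
  expect_equal(unname(h[8]), 10L)
  expect_equal(sum(h), 10L)
  checker <- 255L * matrix((outer(1:8, 1:8, `+`)) %% 2L, 8, 8)
  hc <- gray_histogram(checker)
  expect_equal(unname(hc[c(1, 256)]), c(32L, 32L))
  withr::with_seed(28, {
    img <- matrix(sample(0:255, 123, TRUE), 3, 41)
    expect_equal(sum(gray_histogram(img)), 123L)
  })
  expect_error(gray_histogram(matrix(1.5, 2, 2)), "integer")
})
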