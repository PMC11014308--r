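#' Attack configuration
#'
#' Validated bundle of the noise-attack and data-loss parameters: zero-mean
#' Gaussian noise of variance 0.1 on the unit intensity scale, and the
#' data-loss ladder 6.25%, 12.5%, 25%, 50%, 60%, 70%, 80%, 90%.
#'
#' @param noise_mean Mean of the Gaussian key noise (unit intensity scale).
#' @param noise_variance Variance of the Gaussian key noise.
#' @param loss_fractions Fractions of the cipher area zeroed centrally.
#' @param seed RNG seed for the noise draw.
#' @return List of class `attack_config`.
#' @export
attack_config <- function(noise_mean = 0, noise_variance = 0.1,
                          loss_fractions = c(0.0625, 0.125, 0.25, 0.50,
                                             0.60, 0.70, 0.80, 0.90),
                          seed = 1L) {
  assert_scalar_num(noise_variance, "noise_variance", lo = 0)
  assert_scalar_num(noise_mean, "noise_mean")
  if (length(loss_fractions) &&
      (any(loss_fractions <= 0) || any(loss_fractions >= 1)))
    stopf("loss_fractions must lie strictly inside (0, 1)")
  structure(list(noise_mean = noise_mean, noise_variance = noise_variance,
                 loss_fractions = loss_fractions, seed = as.integer(seed)),
            class = "attack_config")
}

#' Cross-pressure key correlation study
#'
#' Generates one phantom per pressure from a shared unloaded base (same seed;
#' the pressure deformation of [apply_pressure()] plus an independent speckle
#' re-draw per scan), runs the full key pipeline on each, and fills the
#' pairwise normalized-cross-correlation matrix of the resulting key images.
#' The key region is selected automatically on the first pressure and reused
#' for the others, mirroring a fixed landmark on the finger.
#'
#' @param params A [phantom_params()] object (unloaded geometry).
#' @param pressures Numeric vector of at least two pressures in kPa.
#' @param half_width Key-region half side length.
#' @return List of class `pressure_report`: `ncc` (symmetric matrix with unit
#'   diagonal, dimnames = pressures), `keys`, `pressures`, and `errors`
#'   (per-pressure failure messages, if any).
#' @export
pressure_study <- function(params, pressures = c(6, 10, 14), half_width = 50L) {
  stopifnot(inherits(params, "phantom_params"))
  if (length(pressures) < 2L) stopf("at least two pressures are required")
  base <- phantom_truth(params)
  keys <- vector("list", length(pressures))
  errors <- character(0)
  center <- "auto"
  for (k in seq_along(pressures)) {
    p <- pressures[k]
    res <- tryCatch({
      truth_p <- apply_pressure(base, params, p)
      vol <- render_volume(truth_p, params,
                           seed_offset = 13L + as.integer(round(1000 * p)))
      key <- generate_key(vol, center = center, half_width = half_width,
                          ridge_period_px = params$ridge_period_px)
      if (identical(center, "auto")) center <- attr(key, "roi")$center
      key
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("pressure %g kPa: %s", p, conditionMessage(res)))
    } else keys[[k]] <- res
  }
  n <- length(pressures)
  ncc <- matrix(NA_real_, n, n, dimnames = list(pressures, pressures))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (is.null(keys[[i]]) || is.null(keys[[j]])) next
      v <- img_ncc(keys[[i]]$data, keys[[j]]$data)
      ncc[i, j] <- v
      ncc[j, i] <- v
    }
  }
  out <- structure(list(ncc = ncc, keys = keys, pressures = pressures,
                        errors = errors), class = "pressure_report")
  if (length(errors))
    warning(sprintf("pressure study completed partially: %s",
                    paste(errors, collapse = "; ")), call. = FALSE)
  out
}

#' @export
print.pressure_report <- function(x, ...) {
  cat("Cross-pressure key NCC matrix (kPa):\n")
  print(round(x$ncc, 4))
  if (length(x$errors)) cat("Errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Gaussian noise attack on a key
#'
#' Corrupts a key as an attacker-side transmission error: the key is taken to
#' the unit intensity scale, zero-mean Gaussian noise of the configured
#' variance is added, and the result is clipped to \[0,1\] and requantized to
#' 8 bits. Seeded and therefore reproducible; zero variance is the identity.
#'
#' @param key A `key_image`.
#' @param cfg An [attack_config()].
#' @return The corrupted `key_image`.
#' @export
noise_attack <- function(key, cfg = attack_config()) {
  stopifnot(inherits(key, "key_image"), inherits(cfg, "attack_config"))
  if (cfg$noise_variance == 0 && cfg$noise_mean == 0) return(key)
  x <- key$data / 255
  x <- local_seed(cfg$seed, {
    x + stats::rnorm(length(x), mean = cfg$noise_mean,
                     sd = sqrt(cfg$noise_variance))
  })
  data <- matrix(as.integer(round_half_away(255 * clamp(x, 0, 1))),
                 nrow(key$data), ncol(key$data))
  new_key_image(data, transform_log = c(key$transform_log,
                                        list(noise_variance = cfg$noise_variance)))
}

#' Central data loss on a cipher
#'
#' Zeroes a centered square covering the requested fraction of the cipher
#' area: side `round(sqrt(fraction) * min(N, M))`, centered at the image
#' midpoint with ties broken toward the top-left corner.
#'
#' @param cipher A `cipher_image`.
#' @param fraction Fraction of the area lost, in (0, 1).
#' @return The damaged `cipher_image`.
#' @export
data_loss <- function(cipher, fraction) {
  stopifnot(inherits(cipher, "cipher_image"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction >= 1)
    stopf("loss fraction must lie strictly inside (0, 1)")
  d <- dim(cipher$data)
  side <- as.integer(round_half_away(sqrt(fraction) * min(d)))
  side <- max(side, 1L)
  r0 <- floor((d[1] - side) / 2) + 1L
  c0 <- floor((d[2] - side) / 2) + 1L
  cipher$data[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 0
  cipher$scheme_params$data_loss_fraction <- fraction
  cipher
}

#' Randomness comparison of an original and a fake key
#'
#' Computes, for each key, the adjacent-pixel correlation in the horizontal,
#' vertical and diagonal directions -- averaged over `n_rep` independent
#' pair-sampling seeds -- together with the gray-level entropy, and attaches
#' both histograms. A constant (degenerate) key is flagged.
#'
#' @param original,fake `key_image` objects.
#' @param J Sampled pairs per correlation estimate.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param n_rep Number of sampling repeats averaged per direction.
#' @return List of class `key_randomness_report` with a `table` data frame
#'   (one row per key) and `histograms`.
#' @export
key_randomness_report <- function(original, fake, J = 5000L, seed = 1L,
                                  n_rep = 10L) {
  stopifnot(inherits(original, "key_image"), inherits(fake, "key_image"))
  keys <- list(original = original, fake = fake)
  rows <- lapply(names(keys), function(nm) {
    k <- keys[[nm]]$data
    degenerate <- min(k) == max(k)
    if (degenerate) {
      return(data.frame(key = nm, cor_horizontal = NA_real_,
                        cor_vertical = NA_real_, cor_diagonal = NA_real_,
                        entropy_bits = img_entropy(k), degenerate = TRUE))
    }
    avg <- vapply(c("horizontal", "vertical", "diagonal"), function(dir) {
      mean(vapply(seq_len(n_rep), function(r)
        adjacent_correlation(k, dir, J = J, seed = seed + r), numeric(1)))
    }, numeric(1))
    data.frame(key = nm, cor_horizontal = avg[["horizontal"]],
               cor_vertical = avg[["vertical"]],
               cor_diagonal = avg[["diagonal"]],
               entropy_bits = img_entropy(k), degenerate = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 histograms = lapply(keys, function(k) gray_histogram(k$data))),
            class = "key_randomness_report")
}

#' @export
print.key_randomness_report <- function(x, ...) {
  cat("Key randomness (adjacent-pixel correlation, averaged; entropy in bits):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
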