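#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema accepted by
#' [read_pipeline_config()]: a `phantom` section (any [phantom_params()]
#' argument), a `fingerprint` section (`center`, `half_width`), a
#' `segmentation` section (`method`), and a `crypto` section
#' (`lowpass_frac`).
#'
#' @return Named list.
#' @export
default_pipeline_config <- function() {
  list(
    phantom = list(),
    segmentation = list(method = "dp_gradient"),
    fingerprint = list(center = "auto", half_width = 50L),
    crypto = list(lowpass_frac = 0.5),
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown sections or keys, and merges the
#' values over [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Configuration list to validate and merge over the defaults.
#' @export
validate_pipeline_config <- function(cfg) {
  def <- default_pipeline_config()
  allowed <- list(
    phantom = names(formals(phantom_params)),
    segmentation = c("method"),
    fingerprint = c("center", "half_width"),
    crypto = c("lowpass_frac"),
    seed = NULL
  )
  unknown <- setdiff(names(cfg), names(allowed))
  if (length(unknown))
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad))
      stopf("unknown key(s) in config section '%s': %s", sec,
            paste(bad, collapse = ", "))
    def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  if (!is.null(cfg$seed)) def$seed <- as.integer(cfg$seed)
  def
}

#' Synthetic demonstration plaintext
#'
#' Deterministic procedural grayscale test scene (smooth background gradient,
#' a bright disk, a dark ring and a sinusoidal texture patch) used as the
#' plaintext when no image is supplied. Synthetic stand-in for a natural
#' photograph.
#'
#' @param n Side length in pixels.
#' @return Integer matrix `n x n` in \[0,255\].
#' @export
demo_image <- function(n = 256L) {
  n <- as.integer(n)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  x <- (j - 1) / (n - 1); y <- (i - 1) / (n - 1)
  img <- 90 + 110 * x + 20 * y
  r1 <- sqrt((x - 0.35)^2 + (y - 0.4)^2)
  img[r1 < 0.18] <- 215
  r2 <- sqrt((x - 0.7)^2 + (y - 0.65)^2)
  img[r2 > 0.12 & r2 < 0.2] <- 35
  tex <- x > 0.55 & y < 0.35
  img[tex] <- img[tex] + 35 * sin(40 * x[tex]) * cos(30 * y[tex])
  matrix(as.integer(clamp(round(img), 0, 255)), n, n)
}

#' Run the full phantom-to-metrics pipeline
#'
#' Orchestrates phantom generation, boundary segmentation, internal
#' fingerprint extraction, key generation, encryption and decryption of a
#' plaintext, and the similarity metrics, persisting every intermediate
#' artifact together with a manifest (MD5 hashes, seed, package version)
#' under `out_dir`.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Output directory, created if missing.
#' @param plain Plaintext image (integer matrix in \[0,255\]); default
#'   [demo_image()].
#' @return Invisibly, a list with the key, cipher, decrypted image, metrics
#'   and manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         plain = demo_image()) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  stage <- "phantom"
  manifest <- list(seed = config$seed, package_version =
                     as.character(utils::packageVersion("octkey")))
  res <- tryCatch({
    params <- do.call(phantom_params,
                      c(config$phantom, list(seed = config$seed)))
    ph <- generate_volume(params)
    write_volume(ph$volume, art("volume.tiff"))

    stage <- "segmentation"
    bset <- segment_boundaries(ph$volume, method = config$segmentation$method)
    write_boundaries(bset, art("boundaries.csv"))

    stage <- "keygen"
    key <- generate_key(ph$volume, center = config$fingerprint$center,
                        half_width = config$fingerprint$half_width,
                        ridge_period_px = params$ridge_period_px,
                        method = config$segmentation$method)
    write_key(key, art("key.png"))

    stage <- "crypto"
    rk <- resize_key(key, dim(plain))
    cipher <- encrypt_image(plain, rk, config$crypto$lowpass_frac)
    write_cipher(cipher, art("cipher.f32"))
    dec <- decrypt_image(cipher, rk)
    write_image(plain, art("plain.png"))
    write_image(dec, art("decrypted.png"))

    stage <- "metrics"
    rep <- metrics_report(plain, dec, seed = config$seed)
    jsonlite::write_json(rep[setdiff(names(rep), "histogram")],
                         art("metrics.json"), auto_unbox = TRUE, digits = NA)
    list(params = params, key = key, cipher = cipher, decrypted = dec,
         metrics = rep)
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
    stop(e)
  })
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$artifacts <- as.list(tools::md5sum(files))
  names(manifest$artifacts) <- basename(files)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
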