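# Synthetic SR-SIM time series: per-FOV stacks whose statistics mimic the
# real acquisitions the denoisers are trained on — filament or vesicle
# phantoms, exponential photobleaching of the fluorescent signal across
# timestamps, mixed Poisson-Gaussian (MPG) camera noise on top of a constant
# baseline offset, and, for vesicle data, the periodic "honeycomb"
# reconstruction artifact of frequency-domain SIM reconstruction.

#' Configuration of the synthetic SR-SIM generator
#'
#' Defaults mirror the acquisition geometry of the published tubulin /
#' vesicle datasets: 101 fields of view recorded over 200 timestamps at
#' 1024 x 1024 pixels, 16-bit counts with a 500-count camera baseline, and a
#' bleaching rate that loses ~95% of the fluorescent signal by the last
#' timestamp. Noise and artifact strengths are free parameters of the
#' phantom, not estimates of the real microscope.
#'
#' @param structure_kind `"filament"` (smooth random curves, tubulin-like)
#'   or `"vesicle"` (rings and discs, lysosome-like).
#' @param image_size Square image side; a power of two, at least 64.
#' @param n_fovs Number of fields of view.
#' @param n_timestamps Frames per field of view.
#' @param n_objects Structures drawn per field of view.
#' @param peak_signal Peak fluorescence in photons/pixel at timestamp 1.
#' @param bleach_rate Exponential per-timestamp decay constant (>= 0).
#' @param read_noise_sigma Gaussian read-noise SD in counts.
#' @param baseline_offset Constant camera baseline in counts.
#' @param honeycomb_amplitude Relative modulation depth of the honeycomb
#'   artifact (applied to vesicle data only by [generate_dataset()]).
#' @param honeycomb_period Grating period of the artifact in pixels.
#' @param seed Integer master seed; every FOV and frame derives its own
#'   stream from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(structure_kind = c("filament", "vesicle"),
                             image_size = 1024L, n_fovs = 101L,
                             n_timestamps = 200L, n_objects = 10L,
                             peak_signal = 2000, bleach_rate = 0.015,
                             read_noise_sigma = 2, baseline_offset = 500,
                             honeycomb_amplitude = 0.15,
                             honeycomb_period = 8, seed = 1L) {
  structure_kind <- match.arg(structure_kind)
  image_size <- as.integer(image_size)
  if (image_size < 64L || bitwAnd(image_size, image_size - 1L) != 0L) {
    stop("image_size must be a power of two >= 64")
  }
  stopifnot(image_size %% 32L == 0L, n_fovs >= 1L, n_timestamps >= 1L,
            n_objects >= 0L, peak_signal > 0, honeycomb_period > 0)
  for (v in c(bleach_rate, read_noise_sigma, baseline_offset,
              honeycomb_amplitude)) {
    if (!is.finite(v) || v < 0) stop("rates and amplitudes must be finite and non-negative")
  }
  structure(list(structure_kind = structure_kind, image_size = image_size,
                 n_fovs = as.integer(n_fovs),
                 n_timestamps = as.integer(n_timestamps),
                 n_objects = as.integer(n_objects),
                 peak_signal = peak_signal, bleach_rate = bleach_rate,
                 read_noise_sigma = read_noise_sigma,
                 baseline_offset = baseline_offset,
                 honeycomb_amplitude = honeycomb_amplitude,
                 honeycomb_period = honeycomb_period,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# small separable Gaussian blur, used to give rasterized curves a smooth
# cross-section
blur_gauss <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  n <- nrow(img); m <- ncol(img)
  pad <- function(k, len) pmin(pmax(k, 1L), len)
  out <- matrix(0, n, m)
  for (i in seq_along(w)) {
    out <- out + w[i] * img[pad(seq_len(n) + (i - r - 1L), n), ]
  }
  img <- out
  out <- matrix(0, n, m)
  for (i in seq_along(w)) {
    out <- out + w[i] * img[, pad(seq_len(m) + (i - r - 1L), m)]
  }
  out
}

draw_filaments <- function(size, n_objects) {
  img <- matrix(0, size, size)
  for (o in seq_len(n_objects)) {
    npts <- sample(4:7, 1L)
    px <- stats::runif(npts, 1, size)
    py <- stats::runif(npts, 1, size)
    tt <- seq(0, 1, length.out = npts)
    ts <- seq(0, 1, length.out = 8L * size)
    cx <- stats::spline(tt, px, xout = ts)$y
    cy <- stats::spline(tt, py, xout = ts)$y
    keep <- cx >= 1 & cx <= size & cy >= 1 & cy <= size
    amp <- stats::runif(1, 0.5, 1)
    ij <- unique(cbind(round(cy[keep]), round(cx[keep])))
    img[ij] <- pmax(img[ij], amp)
  }
  blur_gauss(img, 1.2)
}

draw_vesicles <- function(size, n_objects) {
  img <- matrix(0, size, size)
  for (o in seq_len(n_objects)) {
    cx <- stats::runif(1, 5, size - 4)
    cy <- stats::runif(1, 5, size - 4)
    r <- stats::runif(1, 3, min(10, size / 8))
    amp <- stats::runif(1, 0.5, 1)
    ring <- stats::runif(1) < 0.7
    ext <- ceiling(r + 4)
    rows <- max(1, floor(cy - ext)):min(size, ceiling(cy + ext))
    cols <- max(1, floor(cx - ext)):min(size, ceiling(cx + ext))
    dd <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
    patch <- if (ring) {
      amp * exp(-(dd - r)^2 / (2 * 1.2^2))
    } else {
      amp / (1 + exp((dd - r) / 0.8))          # soft disc
    }
    img[rows, cols] <- pmax(img[rows, cols], patch)
  }
  img
}

#' Generate one noise-free phantom image
#'
#' Filament phantoms are smooth random spline curves rasterized with a
#' Gaussian cross-section; vesicle phantoms are rings and soft discs. The
#' background is zero and the maximum intensity is scaled to
#' `config$peak_signal`. Identical `(config, fov_seed)` give a bit-identical
#' image.
#'
#' @param config A [synthetic_config()].
#' @param fov_seed Integer seed for this field of view.
#' @return A nonnegative `image_size` x `image_size` matrix (photons/pixel).
#' @export
generate_clean_image <- function(config, fov_seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(as.integer(fov_seed), {
    img <- switch(config$structure_kind,
                  filament = draw_filaments(config$image_size,
                                            config$n_objects),
                  vesicle = draw_vesicles(config$image_size,
                                          config$n_objects),
                  stop("invalid structure_kind"))
    mx <- max(img)
    if (mx > 0) img <- img * (config$peak_signal / mx)
    img
  })
}

#' Photobleaching decay
#'
#' Scales the clean fluorescence by `exp(-bleach_rate * (t - 1))`: the
#' timestamp-1 frame is unbleached and later frames decay exponentially, the
#' mechanism behind the drop in SNR across an acquisition series.
#'
#' @param clean Nonnegative image matrix.
#' @param t Timestamp (1-based).
#' @param bleach_rate Decay constant per timestamp (>= 0).
#' @export
apply_bleaching <- function(clean, t, bleach_rate) {
  if (t < 1) stop("timestamp must be >= 1")
  clean * exp(-bleach_rate * (t - 1))
}

#' Mixed Poisson-Gaussian camera noise
#'
#' Per pixel: `Poisson(signal) + Normal(baseline_offset, read_noise_sigma^2)`,
#' clipped at zero. Photon shot noise dominates; the Gaussian term models
#' read/thermal noise on top of a constant camera baseline. Quantization to
#' 16-bit integers happens when frames are written to TIFF, not here.
#'
#' @param signal Nonnegative expected photon image.
#' @param baseline_offset Constant baseline in counts.
#' @param read_noise_sigma Gaussian SD in counts.
#' @param seed Integer seed; identical inputs give identical noise.
#' @export
apply_mpg_noise <- function(signal, baseline_offset, read_noise_sigma, seed) {
  if (any(signal < 0)) stop("signal must be nonnegative")
  with_seed(as.integer(seed), {
    n <- length(signal)
    noisy <- stats::rpois(n, lambda = as.vector(signal)) +
      stats::rnorm(n, mean = baseline_offset, sd = read_noise_sigma)
    matrix(pmax(noisy, 0), nrow(signal), ncol(signal))
  })
}

#' Honeycomb reconstruction artifact
#'
#' Multiplies the image by `1 + amplitude * h(x, y)` where `h` is the
#' normalized sum of three cosine gratings at 0, 60 and 120 degrees with the
#' given period — the hexagonal interference symmetry that frequency-domain
#' SIM reconstruction imprints on noisy raw data.
#'
#' @param image Image matrix.
#' @param amplitude Relative modulation depth (0 = identity).
#' @param period Grating period in pixels (> 0).
#' @export
apply_honeycomb_artifact <- function(image, amplitude, period) {
  if (period <= 0) stop("period must be > 0")
  if (amplitude == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  k <- 2 * pi / period
  y <- matrix(seq_len(H) - 1, H, W)
  x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  h <- (cos(k * x) +
        cos(k * (x * cos(pi / 3) + y * sin(pi / 3))) +
        cos(k * (x * cos(2 * pi / 3) + y * sin(2 * pi / 3)))) / 3
  image * (1 + amplitude * h)
}

quantize16 <- function(img) {
  matrix(as.integer(round(pmin(pmax(img, 0), 65535))), nrow(img), ncol(img))
}

#' Write / read a single-page 16-bit grayscale TIFF of camera counts
#'
#' Values are clipped to `[0, 65535]` and rounded on write, matching a
#' 16-bit camera; `read_count_tiff()` returns the integer counts.
#'
#' @param img Numeric matrix of counts.
#' @param path File path.
#' @export
write_count_tiff <- function(img, path) {
  tiff::writeTIFF(quantize16(img) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_count_tiff
#' @export
read_count_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("expected a single-channel TIFF: ", path)
    img <- img[, , 1L]
  }
  storage.mode(img) <- "numeric"
  img
}

#' Generate a synthetic SR-SIM dataset on disk
#'
#' Writes one 16-bit TIFF per (FOV, timestamp), named `fov{F}_t{T}.tif`.
#' Timestamp 1 is the reference: the unbleached phantom with MPG noise at
#' its minimal level. Later timestamps apply bleaching, then MPG noise,
#' then (vesicle phantoms only) the honeycomb artifact. A `manifest.csv`
#' with columns `fov,timestamp,path,role` lists every file.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", config$n_fovs * config$n_timestamps)
  k <- 0L
  for (f in seq_len(config$n_fovs)) {
    fov_seed <- config$seed + 100003L * f
    clean <- generate_clean_image(config, fov_seed)
    for (t in seq_len(config$n_timestamps)) {
      frame <- apply_bleaching(clean, t, config$bleach_rate)
      frame <- apply_mpg_noise(frame, config$baseline_offset,
                               config$read_noise_sigma, fov_seed + t)
      if (t > 1L && config$structure_kind == "vesicle") {
        frame <- apply_honeycomb_artifact(frame, config$honeycomb_amplitude,
                                          config$honeycomb_period)
      }
      fn <- sprintf("fov%d_t%d.tif", f, t)
      write_count_tiff(frame, file.path(out_dir, fn))
      k <- k + 1L
      rows[[k]] <- data.frame(fov = f, timestamp = t, path = fn,
                              role = if (t == 1L) "reference" else "input",
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Build one in-memory FOV time series
#'
#' Like [generate_dataset()] but without touching disk: returns the clean
#' frame and the list of noisy frames for one field of view.
#'
#' @param config A [synthetic_config()].
#' @param fov 1-based FOV index.
#' @return List with `fov_id`, `clean_frame`, and `frames` (length
#'   `n_timestamps`).
#' @export
generate_fov_series <- function(config, fov) {
  fov_seed <- config$seed + 100003L * as.integer(fov)
  clean <- generate_clean_image(config, fov_seed)
  frames <- vector("list", config$n_timestamps)
  for (t in seq_len(config$n_timestamps)) {
    frame <- apply_bleaching(clean, t, config$bleach_rate)
    frame <- apply_mpg_noise(frame, config$baseline_offset,
                             config$read_noise_sigma, fov_seed + t)
    if (t > 1L && config$structure_kind == "vesicle") {
      frame <- apply_honeycomb_artifact(frame, config$honeycomb_amplitude,
                                        config$honeycomb_period)
    }
    frames[[t]] <- frame
  }
  list(fov_id = as.integer(fov), clean_frame = clean, frames = frames)
}
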