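#' Speed-of-sound map
#'
#' Pixel-wise sound-speed field on an [image_grid()]. Values are stored as an
#' `nx x ny` matrix `values[i, j]` whose column-major vectorization matches
#' the linear pixel index. Speeds outside a 500-5000 m/s physiological guard
#' rail are rejected at construction.
#'
#' @param grid an [image_grid()].
#' @param values numeric matrix (`nx x ny`) or vector (length `K`) of sound
#'   speeds, m/s.
#' @param background_speed background medium speed v0, m/s.
#' @param masks optional named list of logical region masks (same shape as
#'   `values`) kept for regional statistics.
#' @return an object of class `sos_map`.
#' @export
sos_map <- function(grid, values, background_speed, masks = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  v <- matrix(as.numeric(values), grid$nx, grid$ny)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("sound speeds must be finite and positive")
  if (any(v < 500) || any(v > 5000))
    stop("sound speeds outside the 500-5000 m/s guard rail")
  stopifnot(background_speed >= 500, background_speed <= 5000)
  structure(list(grid = grid, values = v,
                 background_speed = background_speed, masks = masks),
            class = "sos_map")
}

#' @export
print.sos_map <- function(x, ...) {
  cat(sprintf("<sos_map> %d x %d, v in [%.0f, %.0f] m/s, v0 = %.0f m/s\n",
              x$grid$nx, x$grid$ny, min(x$values), max(x$values),
              x$background_speed))
  invisible(x)
}

disc_mask <- function(grid, center, diameter) {
  pc <- grid_pixel_centers(grid)
  d2 <- (pc[, 1] - center[1])^2 + (pc[, 2] - center[2])^2
  matrix(d2 < (diameter / 2)^2, grid$nx, grid$ny)
}

#' Single-disc SOS phantom
#'
#' A circular inclusion of speed `v_inside` in a uniform background. Pixels
#' whose centers lie strictly inside the disc take `v_inside`. The region
#' mask is kept on the returned map (`masks$target`, `masks$background`) for
#' later regional statistics.
#'
#' @param grid an [image_grid()].
#' @param center disc center, meters.
#' @param diameter disc diameter, meters (0 gives a uniform map).
#' @param v_inside,v_background speeds inside / outside the disc, m/s.
#' @return an `sos_map` with `masks$target` and `masks$background`.
#' @export
disc_phantom <- function(grid, center = c(0, 0), diameter = 16e-3,
                         v_inside = 1650, v_background = 1500) {
  if (diameter < 0) stop("disc diameter must be non-negative")
  m <- disc_mask(grid, center, diameter)
  v <- matrix(v_background, grid$nx, grid$ny)
  v[m] <- v_inside
  sos_map(grid, v, v_background,
          masks = list(target = m, background = !m))
}

#' Multi-region SOS phantom
#'
#' Piecewise-constant map of several circular regions in a common
#' background. Later regions overwrite earlier ones where they overlap
#' (a warning is raised). Per-region masks are kept for regional statistics;
#' a region's mask excludes pixels later overwritten.
#'
#' @param grid an [image_grid()].
#' @param regions list of regions, each a list with elements `center`
#'   (meters), `diameter` (meters) and `speed` (m/s), optionally `label`.
#' @param v_background background speed, m/s.
#' @return an `sos_map` with one mask per region plus `background`.
#' @export
multi_region_phantom <- function(grid, regions, v_background = 1500) {
  v <- matrix(v_background, grid$nx, grid$ny)
  masks <- list()
  speeds <- numeric(0)
  any_mask <- matrix(FALSE, grid$nx, grid$ny)
  for (s in seq_along(regions)) {
    r <- regions[[s]]
    m <- disc_mask(grid, r$center, r$diameter)
    if (any(m & any_mask)) {
      warning("overlapping phantom regions: later region overwrites earlier")
      for (q in seq_along(masks)) masks[[q]] <- masks[[q]] & !m
    }
    v[m] <- r$speed
    lab <- if (!is.null(r$label)) r$label else sprintf("%g m/s", r$speed)
    masks[[lab]] <- m
    speeds[lab] <- r$speed
    any_mask <- any_mask | m
  }
  masks$background <- !any_mask
  out <- sos_map(grid, v, v_background, masks = masks)
  attr(out, "region_speeds") <- speeds
  out
}

#' Four-region reference phantom
#'
#' The multi-target study phantom: four discs at 1545, 1580, 1615 and
#' 1650 m/s in a 1500 m/s background, placed in the four quadrants at
#' (+-7, +-7) mm with diameters 14, 12, 10 and 8 mm (scaled with the grid
#' extent). Diameters decrease with increasing contrast, and the whole
#' object stays strictly inside the 19 mm beacon scan circle (largest
#' radial extent ~16.9 mm), as it must for a beacon scanned around the
#' object.
#'
#' @param grid an [image_grid()].
#' @return an `sos_map` with per-region masks and a `region_speeds`
#'   attribute.
#' @export
four_region_phantom <- function(grid) {
  sc <- grid$extent / 40e-3
  off <- 7e-3 * sc
  regions <- list(
    list(center = c(-off,  off), diameter = 14e-3 * sc, speed = 1545,
         label = "1545 m/s"),
    list(center = c( off,  off), diameter = 12e-3 * sc, speed = 1580,
         label = "1580 m/s"),
    list(center = c(-off, -off), diameter = 10e-3 * sc, speed = 1615,
         label = "1615 m/s"),
    list(center = c( off, -off), diameter = 8e-3 * sc, speed = 1650,
         label = "1650 m/s"))
  multi_region_phantom(grid, regions, v_background = 1500)
}

#' Absorber map
#'
#' Relative initial-pressure amplitude per pixel (dimensionless, >= 0) for
#' synthesizing the imaged object's own photoacoustic signal.
#'
#' @param grid an [image_grid()].
#' @param values non-negative amplitude matrix or vector.
#' @return an object of class `absorber_map`.
#' @export
absorber_map <- function(grid, values) {
  v <- matrix(as.numeric(values), grid$nx, grid$ny)
  if (!all(is.finite(v)) || any(v < 0))
    stop("absorber amplitudes must be finite and non-negative")
  structure(list(grid = grid, values = v), class = "absorber_map")
}

#' Beacon waveform specification
#'
#' @param center_frequency wavelet center frequency, Hz (default 5 MHz).
#' @param beacon_amplitude envelope peak amplitude of the beacon wavelet.
#' @param target_amplitude default amplitude for interferer (target) wavelets.
#' @param noise_sigma standard deviation of additive white Gaussian noise.
#' @param seed integer seed for the noise generator.
#' @return an object of class `waveform_spec`.
#' @export
waveform_spec <- function(center_frequency = 5e6, beacon_amplitude = 10,
                          target_amplitude = 1, noise_sigma = 0, seed = 0L) {
  stopifnot(center_frequency > 0, beacon_amplitude >= 0,
            target_amplitude >= 0, noise_sigma >= 0)
  structure(list(center_frequency = center_frequency,
                 beacon_amplitude = beacon_amplitude,
                 target_amplitude = target_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "waveform_spec")
}

#' Channel-time sinogram
#'
#' @param data `M x T` matrix of recorded pressure (channels in rows).
#' @param acq an [acq_params()].
#' @param beacon_index optional index of the beacon position this sinogram
#'   belongs to.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(data, acq, beacon_index = NULL) {
  stopifnot(is.matrix(data), inherits(acq, "acq_params"),
            ncol(data) == acq$n_samples)
  if (!all(is.finite(data))) stop("sinogram values must be finite")
  structure(list(data = data, acq = acq, beacon_index = beacon_index),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d channels x %d samples @ %.0f MHz\n",
              nrow(x$data), ncol(x$data), x$acq$sampling_rate / 1e6))
  invisible(x)
}

# Bipolar first-derivative-of-Gaussian wavelet sampled at times tt (seconds,
# relative to the arrival time). sigma is set so the spectral magnitude peaks
# at the requested center frequency; the returned samples are scaled so the
# wavelet's *envelope* peak equals 1.
dog_wavelet <- function(tt, center_frequency) {
  sigma <- 1 / (2 * pi * center_frequency)
  w <- -tt * exp(-tt^2 / (2 * sigma^2))
  # envelope peak of the continuous wavelet: |w + i*H(w)| at t = 0 equals
  # sigma * sqrt(2/e) * ... -- normalize numerically on a dense grid instead
  w / (sigma * exp(-0.5))  # peak |w| at t = sigma; envelope rescaled below
}

# Numerically computed ratio between the envelope peak and the amplitude
# peak of the unit-amplitude derivative-of-Gaussian wavelet (depends only on
# shape, not frequency). Cached per session.
dog_envelope_gain <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- 4096L
    tt <- (seq_len(n) - n / 2) / n * 64  # in units of sigma, sigma = 1
    w <- -tt * exp(-tt^2 / 2) / exp(-0.5)
    cache <<- max(signal_envelope(matrix(w, 1)))
    cache
  }
})

#' Synthesize a beacon sinogram
#'
#' Places a band-limited bipolar wavelet (first derivative of a Gaussian at
#' the center frequency given in `spec`) on every channel with its envelope peak at
#' the given arrival time and envelope amplitude `beacon_amplitude`.
#' Optional interferer wavelet trains (e.g. the imaged object's own
#' photoacoustic signal) are superposed at their own amplitudes, then white
#' Gaussian noise is added (seeded, reproducible).
#'
#' @param arrivals numeric vector of per-channel beacon arrival times,
#'   seconds (length M).
#' @param spec a [waveform_spec()].
#' @param acq an [acq_params()].
#' @param interferers optional list; each element a list with `arrivals`
#'   (per-channel times, seconds) and optional `amplitude` (defaults to
#'   `spec$target_amplitude`).
#' @param beacon_index optional beacon position index stored on the result.
#' @return a [sinogram()].
#' @export
synthesize_beacon_sinogram <- function(arrivals, spec, acq,
                                       interferers = NULL,
                                       beacon_index = NULL) {
  stopifnot(inherits(spec, "waveform_spec"), inherits(acq, "acq_params"))
  if (!all(is.finite(arrivals))) stop("arrival times must be finite")
  M <- length(arrivals)
  Tn <- acq$n_samples
  t_axis <- acq$t0 + (seq_len(Tn) - 1) / acq$sampling_rate
  t_end <- acq$t0 + (Tn - 1) / acq$sampling_rate
  if (any(arrivals < acq$t0 | arrivals > t_end))
    warning("some arrivals fall outside the recorded window; channels left empty")
  gain <- dog_envelope_gain()
  place <- function(data, times, amp) {
    sigma <- 1 / (2 * pi * spec$center_frequency)
    for (m in seq_len(M)) {
      tau <- times[m]
      if (!is.finite(tau) || tau < acq$t0 || tau > t_end) next
      # only evaluate within +-8 sigma of the arrival
      lo <- max(1L, floor((tau - 8 * sigma - acq$t0) * acq$sampling_rate) + 1L)
      hi <- min(Tn, ceiling((tau + 8 * sigma - acq$t0) * acq$sampling_rate) + 1L)
      idx <- lo:hi
      data[m, idx] <- data[m, idx] +
        (amp / gain) * dog_wavelet(t_axis[idx] - tau, spec$center_frequency)
    }
    data
  }
  data <- matrix(0, M, Tn)
  data <- place(data, arrivals, spec$beacon_amplitude)
  if (!is.null(interferers)) {
    for (itf in interferers) {
      amp <- if (!is.null(itf$amplitude)) itf$amplitude else spec$target_amplitude
      data <- place(data, itf$arrivals, amp)
    }
  }
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed + if (is.null(beacon_index)) 0L else as.integer(beacon_index))
    data <- data + matrix(stats::rnorm(M * Tn, sd = spec$noise_sigma), M, Tn)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  sinogram(data, acq, beacon_index = beacon_index)
}

#' Background time-of-flight table
#'
#' Beacon-to-element travel times through a homogeneous medium at speed
#' `v0`: `t_b[n, m] = |beacon_n - element_m| / v0`.
#'
#' @param geom a [ring_array()].
#' @param scan a [beacon_scan()].
#' @param v0 background sound speed, m/s.
#' @return a [tof_table()] of kind `"background"` (N x M seconds).
#' @export
background_tof <- function(geom, scan, v0 = 1500) {
  stopifnot(v0 > 0)
  el <- element_positions(geom)
  bc <- beacon_positions(scan)
  d <- outer(seq_len(nrow(bc)), seq_len(nrow(el)),
             function(n, m) sqrt((bc[n, 1] - el[m, 1])^2 +
                                 (bc[n, 2] - el[m, 2])^2))
  tof_table(d / v0, kind = "background")
}
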