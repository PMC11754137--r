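#' Beamformed image container
#'
#' @param grid an [image_grid()].
#' @param values `nx x ny` matrix of beamformed amplitude (a.u.).
#' @return an object of class `recon_image`.
#' @export
recon_image <- function(grid, values) {
  v <- matrix(as.numeric(values), grid$nx, grid$ny)
  if (!all(is.finite(v))) stop("image values must be finite")
  structure(list(grid = grid, values = v), class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d, max %.4g\n",
              x$grid$nx, x$grid$ny, max(abs(x$values))))
  invisible(x)
}

# Linearly interpolated temporal lookup of channel data at fractional
# delays. times outside the record contribute 0.
sample_channels <- function(data, acq, tau) {
  # tau: P x M matrix of times; data: M x T
  Tn <- ncol(data)
  s <- (tau - acq$t0) * acq$sampling_rate + 1  # 1-based fractional sample
  out <- matrix(0, nrow(tau), ncol(tau))
  i0 <- floor(s)
  frac <- s - i0
  ok <- i0 >= 1 & i0 < Tn
  for (m in seq_len(ncol(tau))) {
    okm <- ok[, m]
    if (!any(okm)) next
    i <- i0[okm, m]
    out[okm, m] <- (1 - frac[okm, m]) * data[m, i] + frac[okm, m] * data[m, i + 1]
  }
  out
}

# Same lookup for a single channel trace.
sample_one_channel <- function(trace, acq, tau) {
  Tn <- length(trace)
  s <- (tau - acq$t0) * acq$sampling_rate + 1
  out <- numeric(length(tau))
  i0 <- floor(s)
  ok <- i0 >= 1 & i0 < Tn
  if (any(ok)) {
    i <- i0[ok]
    frac <- s[ok] - i
    out[ok] <- (1 - frac) * trace[i] + frac * trace[i + 1]
  }
  out
}

#' Delay-and-sum reconstruction at a uniform sound speed
#'
#' `P(k) = sum_m p(m, tau_m(k))` with `tau_m(k) = |pixel_k - element_m| / v`,
#' using linear interpolation between time samples; delays outside the
#' record contribute zero.
#'
#' @param sino a [sinogram()] of the imaged object.
#' @param grid reconstruction [image_grid()].
#' @param geom a [ring_array()].
#' @param v_uniform assumed uniform sound speed, m/s.
#' @return a [recon_image()].
#' @export
das <- function(sino, grid, geom, v_uniform) {
  stopifnot(inherits(sino, "sinogram"), v_uniform > 0)
  el <- element_positions(geom)
  pc <- grid_pixel_centers(grid)
  d <- sqrt(outer(pc[, 1], el[, 1], "-")^2 + outer(pc[, 2], el[, 2], "-")^2)
  acc <- rowSums(sample_channels(sino$data, sino$acq, d / v_uniform))
  recon_image(grid, acc)
}

#' Coarse-grid heterogeneous TOF volume
#'
#' One-way travel times from every pixel center of `coarse_grid` to every
#' transducer element as straight-ray line integrals of slowness through
#' the SOS map (out-of-grid portions at the background speed). The SOS map
#' is resampled to the coarse grid by nearest-pixel lookup.
#'
#' @param sos an [sos_map()].
#' @param geom a [ring_array()].
#' @param coarse_grid an [image_grid()] for the TOF computation.
#' @return an object of class `tof_volume`: `times` is a `K_coarse x M`
#'   matrix (pixels in linear index order).
#' @export
compute_tof_volume <- function(sos, geom, coarse_grid) {
  stopifnot(inherits(sos, "sos_map"), inherits(coarse_grid, "image_grid"))
  el <- element_positions(geom)
  v_coarse <- resample_nearest(sos, coarse_grid)
  corner <- grid_corner(coarse_grid)
  times <- cpp_tof_points(coarse_grid$nx, coarse_grid$ny, coarse_grid$spacing,
                          corner[1], corner[2],
                          1 / as.vector(v_coarse), 1 / sos$background_speed,
                          el, grid_pixel_centers(coarse_grid))
  structure(list(times = times, grid = coarse_grid, n_elements = nrow(el)),
            class = "tof_volume")
}

# Nearest-pixel resampling of an sos_map onto another grid; background
# speed outside the map extent.
resample_nearest <- function(sos, grid) {
  g <- sos$grid
  corner <- grid_corner(g)
  pc <- grid_pixel_centers(grid)
  ix <- floor((pc[, 1] - corner[1]) / g$spacing)
  iy <- floor((pc[, 2] - corner[2]) / g$spacing)
  v <- rep(sos$background_speed, nrow(pc))
  ok <- ix >= 0 & ix < g$nx & iy >= 0 & iy < g$ny
  v[ok] <- sos$values[cbind(ix[ok] + 1L, iy[ok] + 1L)]
  matrix(v, grid$nx, grid$ny)
}

# 1D cubic-spline interpolation matrix mapping values at coarse cell
# centers to fine cell centers. Interpolation is linear in the data, so the
# operator is built by passing unit vectors through the spline once per grid
# pair. FMM end conditions (cubic through the four boundary points) keep
# fourth-order accuracy up to the edges; constants are reproduced exactly.
spline_matrix <- function(coarse_centers, fine_centers) {
  n <- length(coarse_centers)
  B <- matrix(0, length(fine_centers), n)
  unit <- numeric(n)
  for (j in seq_len(n)) {
    unit[j] <- 1
    B[, j] <- stats::splinefun(coarse_centers, unit,
                               method = "fmm")(fine_centers)
    unit[j] <- 0
  }
  B
}

# Pair of x/y interpolation matrices from a coarse to a fine grid.
bicubic_operators <- function(coarse_grid, fine_grid) {
  cx <- grid_corner(coarse_grid)[1] +
    (seq_len(coarse_grid$nx) - 0.5) * coarse_grid$spacing
  cy <- grid_corner(coarse_grid)[2] +
    (seq_len(coarse_grid$ny) - 0.5) * coarse_grid$spacing
  fx <- grid_corner(fine_grid)[1] +
    (seq_len(fine_grid$nx) - 0.5) * fine_grid$spacing
  fy <- grid_corner(fine_grid)[2] +
    (seq_len(fine_grid$ny) - 0.5) * fine_grid$spacing
  list(Bx = spline_matrix(cx, fx), By = spline_matrix(cy, fy))
}

#' Bicubic upsampling of a TOF volume
#'
#' Separable bicubic-spline interpolation of each element's coarse TOF map
#' onto a finer grid (same origin; the coarse grid may extend beyond the
#' fine one, which [ti_mdas()] exploits to keep every stencil interior).
#' Constants are reproduced exactly; on smooth fields the error decays with
#' fourth order in the coarse spacing.
#'
#' @param coarse a [compute_tof_volume()] result.
#' @param fine_grid an [image_grid()] with the same extent and origin.
#' @return a `tof_volume` on the fine grid.
#' @export
interp_tof <- function(coarse, fine_grid) {
  stopifnot(inherits(coarse, "tof_volume"), inherits(fine_grid, "image_grid"))
  if (coarse$grid$extent < fine_grid$extent - 1e-12 ||
      any(abs(coarse$grid$origin - fine_grid$origin) > 1e-12))
    stop("coarse grid must cover the fine grid extent (same origin)")
  ops <- bicubic_operators(coarse$grid, fine_grid)
  M <- coarse$n_elements
  out <- matrix(0, grid_n_pixels(fine_grid), M)
  for (m in seq_len(M)) {
    cm <- matrix(coarse$times[, m], coarse$grid$nx, coarse$grid$ny)
    out[, m] <- as.vector(ops$Bx %*% cm %*% t(ops$By))
  }
  structure(list(times = out, grid = fine_grid, n_elements = M),
            class = "tof_volume")
}

#' SOS-corrected delay-and-sum (TI-MDAS)
#'
#' Multi-SOS delay-and-sum: per-pixel delays are straight-ray slowness
#' integrals through the reconstructed SOS map, computed on a coarse grid
#' and bicubically upsampled to the reconstruction grid (TOF-interpolation
#' acceleration), then summed over channels with linear temporal
#' interpolation. With a uniform map this reduces to [das()].
#'
#' @param sino a [sinogram()] of the imaged object.
#' @param sos an [sos_map()] used for the delays.
#' @param geom a [ring_array()].
#' @param coarse_n coarse TOF grid resolution per side (default 100).
#' @param fine_n reconstruction grid resolution per side (default 400).
#' @return a [recon_image()] on the fine grid.
#' @export
ti_mdas <- function(sino, sos, geom, coarse_n = 100L, fine_n = 400L) {
  stopifnot(inherits(sino, "sinogram"), inherits(sos, "sos_map"),
            coarse_n <= fine_n)
  fov <- sos$grid$extent
  fine_grid <- image_grid(fov, fine_n, sos$grid$origin)
  # pad the coarse grid by two pixel rings so every fine-pixel bicubic
  # stencil is interior (no clamped extrapolation at the FOV border)
  pad <- if (coarse_n < fine_n) 2L else 0L
  s_c <- fov / coarse_n
  coarse_grid <- image_grid(fov + 2 * pad * s_c, coarse_n + 2L * pad,
                            sos$grid$origin)
  vol <- compute_tof_volume(sos, geom, coarse_grid)
  M <- vol$n_elements
  acc <- numeric(grid_n_pixels(fine_grid))
  if (coarse_n == fine_n) {
    acc <- rowSums(sample_channels(sino$data, sino$acq, vol$times))
  } else {
    ops <- bicubic_operators(coarse_grid, fine_grid)
    for (m in seq_len(M)) {
      cm <- matrix(vol$times[, m], coarse_grid$nx, coarse_grid$ny)
      fm <- as.vector(ops$Bx %*% cm %*% t(ops$By))
      acc <- acc + sample_one_channel(sino$data[m, ], sino$acq, fm)
    }
  }
  recon_image(fine_grid, acc)
}
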