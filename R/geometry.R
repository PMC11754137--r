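#' Ring-array transducer geometry
#'
#' Describes a (possibly partial) circular transducer array in 2D. The array
#' occupies an arc of `arc_span` degrees; the remaining gap is centered at
#' `gap_center_angle`. Elements are laid out cell-centered on the arc, so no
#' element sits exactly on an arc edge: element `m` (0-based) lies at angle
#' `gap_center_angle + 180 - arc_span/2 + (m + 0.5) * arc_span / n_elements`
#' unless `start_angle` overrides the arc start explicitly.
#'
#' Defaults mirror a 128-element, 270-degree ring of radius 40.5 mm with a
#' 5 MHz center frequency, the geometry of a small-animal cross-sectional
#' photoacoustic tomograph.
#'
#' @param n_elements number of transducer elements (M), at least 2.
#' @param ring_radius ring radius in meters.
#' @param arc_span angular extent of the active arc, degrees, in (0, 360].
#' @param gap_center_angle angle (degrees, CCW from +x) at which the inactive
#'   gap is centered. Ignored when `start_angle` is given.
#' @param center 2D coordinates of the ring center, meters.
#' @param start_angle optional explicit angle (degrees) of the start of the
#'   arc; element `m` then sits at `start_angle + (m + 0.5)*arc_span/M`.
#' @return an object of class `ring_array`.
#' @export
ring_array <- function(n_elements = 128L, ring_radius = 40.5e-3,
                       arc_span = 270, gap_center_angle = 90,
                       center = c(0, 0), start_angle = NULL) {
  stopifnot(n_elements >= 2, arc_span > 0, arc_span <= 360, ring_radius > 0,
            length(center) == 2)
  structure(list(n_elements = as.integer(n_elements),
                 ring_radius = ring_radius,
                 arc_span = arc_span,
                 gap_center_angle = gap_center_angle,
                 center = as.numeric(center),
                 start_angle = start_angle),
            class = "ring_array")
}

#' Beacon scan trajectory
#'
#' Positions of a photoacoustic reversal beacon scanned on a circle inside
#' the transducer ring. Positions are uniformly spaced over 360 degrees.
#'
#' @param n_positions number of beacon positions (N), at least 1.
#' @param scan_radius scan circle radius in meters (default 19 mm).
#' @param start_angle angle of the first beacon, degrees CCW from +x.
#' @param center scan circle center, meters.
#' @return an object of class `beacon_scan`.
#' @export
beacon_scan <- function(n_positions = 80L, scan_radius = 19e-3,
                        start_angle = 0, center = c(0, 0)) {
  stopifnot(n_positions >= 1, scan_radius > 0, length(center) == 2)
  structure(list(n_positions = as.integer(n_positions),
                 scan_radius = scan_radius,
                 start_angle = start_angle,
                 center = as.numeric(center)),
            class = "beacon_scan")
}

#' Square image grid
#'
#' Cell-centered regular pixel grid. Pixel `(i, j)` (0-based, `i` along x,
#' `j` along y) has its center at
#' `origin + ((i + 0.5)*s - extent/2, (j + 0.5)*s - extent/2)` with spacing
#' `s = extent/n`. The linear pixel index is `k = i + n*j + 1` (1-based), so
#' `as.vector()` of an `n x n` value matrix stored as `values[i, j]` walks
#' the pixels in index order.
#'
#' @param extent side length of the square field of view, meters.
#' @param n number of pixels per side.
#' @param origin grid center, meters.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(extent = 40e-3, n = 100L, origin = c(0, 0)) {
  if (extent <= 0) stop("grid extent must be positive")
  stopifnot(n >= 1, length(origin) == 2)
  n <- as.integer(n)
  structure(list(nx = n, ny = n, extent = extent,
                 origin = as.numeric(origin),
                 spacing = extent / n),
            class = "image_grid")
}

#' Acquisition parameters
#'
#' @param sampling_rate sampling frequency in Hz (default 40 MHz).
#' @param n_samples number of recorded time samples per channel (T).
#' @param t0 acquisition start time, seconds.
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(sampling_rate = 40e6, n_samples = 2048L, t0 = 0) {
  stopifnot(sampling_rate > 0, n_samples >= 1)
  structure(list(sampling_rate = sampling_rate,
                 n_samples = as.integer(n_samples), t0 = t0),
            class = "acq_params")
}

deg2rad <- function(a) a * pi / 180

#' Transducer element positions
#'
#' @param geom a [ring_array()].
#' @return an `M x 2` matrix of element coordinates (meters), ordered
#'   monotonically in angle along the arc.
#' @export
element_positions <- function(geom) {
  stopifnot(inherits(geom, "ring_array"))
  M <- geom$n_elements
  start <- if (!is.null(geom$start_angle)) geom$start_angle
           else geom$gap_center_angle + 180 - geom$arc_span / 2
  ang <- deg2rad(start + (seq_len(M) - 0.5) * geom$arc_span / M)
  cbind(x = geom$center[1] + geom$ring_radius * cos(ang),
        y = geom$center[2] + geom$ring_radius * sin(ang))
}

#' Beacon positions
#'
#' @param scan a [beacon_scan()].
#' @return an `N x 2` matrix of beacon coordinates (meters), uniformly
#'   spaced over 360 degrees starting at `start_angle`.
#' @export
beacon_positions <- function(scan) {
  stopifnot(inherits(scan, "beacon_scan"))
  N <- scan$n_positions
  ang <- deg2rad(scan$start_angle + (seq_len(N) - 1) * 360 / N)
  cbind(x = scan$center[1] + scan$scan_radius * cos(ang),
        y = scan$center[2] + scan$scan_radius * sin(ang))
}

#' Pixel centers of an image grid
#'
#' @param grid an [image_grid()].
#' @return a `K x 2` matrix of pixel-center coordinates in linear pixel-index
#'   order (`k = i + nx*j + 1`).
#' @export
grid_pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  s <- grid$spacing
  cx <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * s - grid$extent / 2
  cy <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * s - grid$extent / 2
  cbind(x = rep(cx, times = grid$ny), y = rep(cy, each = grid$nx))
}

#' Number of pixels of a grid
#' @param grid an [image_grid()].
#' @return integer pixel count `K = nx * ny`.
#' @export
grid_n_pixels <- function(grid) grid$nx * grid$ny

# Lower-left corner of the grid square (pixel edges, not centers).
grid_corner <- function(grid) {
  c(grid$origin[1] - grid$extent / 2, grid$origin[2] - grid$extent / 2)
}

#' Convert between pixel indices and (i, j) subscripts
#'
#' `pixel_index` maps 0-based subscripts `(i, j)` to the 1-based linear index;
#' `pixel_subscript` inverts it.
#'
#' @param grid an [image_grid()].
#' @param i,j 0-based pixel subscripts along x and y.
#' @param k 1-based linear pixel index.
#' @return `pixel_index`: integer vector; `pixel_subscript`: two-column
#'   integer matrix of `(i, j)`.
#' @export
pixel_index <- function(grid, i, j) as.integer(i + grid$nx * j + 1L)

#' @rdname pixel_index
#' @export
pixel_subscript <- function(grid, k) {
  k0 <- as.integer(k) - 1L
  cbind(i = k0 %% grid$nx, j = k0 %/% grid$nx)
}

#' @export
print.ring_array <- function(x, ...) {
  cat(sprintf("<ring_array> M = %d elements, radius %.1f mm, arc %g deg\n",
              x$n_elements, x$ring_radius * 1e3, x$arc_span))
  invisible(x)
}

#' @export
print.beacon_scan <- function(x, ...) {
  cat(sprintf("<beacon_scan> N = %d positions, radius %.1f mm\n",
              x$n_positions, x$scan_radius * 1e3))
  invisible(x)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, extent %.1f mm, spacing %.3f mm\n",
              x$nx, x$ny, x$extent * 1e3, x$spacing * 1e3))
  invisible(x)
}
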