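#' Time-of-flight table
#'
#' An `N x M` matrix of beacon-to-element times (seconds): measured arrival
#' times (`kind = "measured"`), homogeneous background times
#' (`"background"`) or their difference (`"delta"`). Vectorization is
#' beacon-major: row `r = (n-1)*M + m` of the path operator corresponds to
#' `values[n, m]`, i.e. `as.vector(t(values))`.
#'
#' @param values `N x M` numeric matrix of times, seconds.
#' @param kind one of `"measured"`, `"background"`, `"delta"`.
#' @return an object of class `tof_table`.
#' @export
tof_table <- function(values, kind = c("measured", "background", "delta")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (kind != "delta" && any(values < 0))
    stop("measured/background times must be non-negative")
  structure(list(values = values, kind = kind), class = "tof_table")
}

#' @export
print.tof_table <- function(x, ...) {
  cat(sprintf("<tof_table:%s> %d beacons x %d channels, range [%.3g, %.3g] us\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values) * 1e6, max(x$values) * 1e6))
  invisible(x)
}

#' Vectorize a TOF table into the model's data vector
#'
#' Beacon-major order matching the path-operator row convention.
#'
#' @param tof a [tof_table()].
#' @return numeric vector of length `N * M`.
#' @export
tof_vector <- function(tof) as.vector(t(tof$values))

#' Trace a ray through an image grid
#'
#' Exact per-pixel intersection lengths of the segment `p0 -> p1` with the
#' grid cells (parametric Siddon-style traversal). Pixels outside the grid
#' contribute nothing; the lengths sum to the segment length clipped to the
#' grid square.
#'
#' @param grid an [image_grid()].
#' @param p0,p1 segment end points, meters.
#' @return a list with `index` (1-based linear pixel indices) and `length`
#'   (intersection lengths, meters).
#' @export
trace_ray <- function(grid, p0, p1) {
  if (isTRUE(all(p0 == p1))) stop("zero-length segment")
  corner <- grid_corner(grid)
  cpp_trace_ray(grid$nx, grid$ny, grid$spacing, corner[1], corner[2],
                as.numeric(p0), as.numeric(p1))
}

#' Build the sparse straight-ray path operator
#'
#' The `(M*N) x K` operator W whose entry `W[r, k]` is the length (meters)
#' of the beacon-to-element segment inside pixel `k`, for row
#' `r = (n-1)*M + m` (beacon `n`, element `m`). The part of each segment
#' outside the grid square is tracked separately (`out_grid_len`) and is
#' assigned background slowness in [forward_tof()].
#'
#' @param grid an [image_grid()].
#' @param geom a [ring_array()].
#' @param scan a [beacon_scan()].
#' @return an object of class `path_operator` with elements `W` (a
#'   `dgCMatrix`), `out_grid_len`, `total_len`, and the dimensions
#'   `M`, `N`, `K`.
#' @export
build_path_operator <- function(grid, geom, scan) {
  el <- element_positions(geom)
  bc <- beacon_positions(scan)
  corner <- grid_corner(grid)
  tr <- cpp_build_operator(grid$nx, grid$ny, grid$spacing,
                           corner[1], corner[2], bc, el)
  K <- grid_n_pixels(grid)
  nr <- nrow(bc) * nrow(el)
  W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nr, K))
  structure(list(W = W,
                 out_grid_len = tr$total_len - tr$ingrid_len,
                 total_len = tr$total_len,
                 grid = grid,
                 M = nrow(el), N = nrow(bc), K = K),
            class = "path_operator")
}

#' @export
print.path_operator <- function(x, ...) {
  cat(sprintf("<path_operator> %d x %d (N = %d beacons, M = %d channels), %d nonzeros\n",
              nrow(x$W), ncol(x$W), x$N, x$M, Matrix::nnzero(x$W)))
  invisible(x)
}

#' Straight-ray forward travel times
#'
#' Applies the path operator to a slowness field: for each beacon-element
#' pair, the time is the line integral of slowness over the in-grid part of
#' the segment plus the out-of-grid chord at background slowness `1/v0`.
#'
#' @param op a [build_path_operator()] result.
#' @param slowness per-pixel slowness `1/v`, s/m (length K, or an
#'   `nx x ny` matrix).
#' @param v0 background speed for the out-of-grid part, m/s.
#' @return a [tof_table()] of kind `"measured"`.
#' @export
forward_tof <- function(op, slowness, v0) {
  s <- as.numeric(slowness)
  if (length(s) != op$K) stop("slowness length must equal the pixel count K")
  if (any(!is.finite(s)) || any(s <= 0)) stop("slowness must be positive")
  y <- as.numeric(op$W %*% s) + op$out_grid_len / v0
  tof_table(matrix(y, op$N, op$M, byrow = TRUE), kind = "measured")
}

#' Straight-ray forward times for an SOS map
#'
#' Convenience wrapper: `forward_tof(op, 1/values, v0)` using the map's
#' background speed for the out-of-grid part.
#'
#' @param op a [build_path_operator()] result.
#' @param sos an [sos_map()] on the operator's grid.
#' @return a [tof_table()] of kind `"measured"`.
#' @export
forward_tof_map <- function(op, sos) {
  stopifnot(inherits(sos, "sos_map"))
  forward_tof(op, 1 / as.vector(sos$values), sos$background_speed)
}

#' Eikonal first-arrival travel times
#'
#' Solves `|grad T| = 1/v` by first-order fast marching on a node-centered
#' solver grid covering the SOS map, the source and all receivers (exterior
#' filled with the map's background speed), and reads receiver times by
#' bilinear interpolation. Serves as a refraction-aware physics surrogate
#' for full-wave simulation: it returns Fermat first-arrival times, which
#' lower-bound the straight-ray times on heterogeneous media.
#'
#' @param sos an [sos_map()].
#' @param source source position, meters.
#' @param receivers `R x 2` matrix of receiver positions, meters.
#' @param solver_spacing solver node spacing, meters (default 0.1 mm).
#' @param pad extra padding around the hull of source/receivers/grid, meters.
#' @param init_radius radius (in solver nodes) of the analytic source
#'   initialization disc.
#' @return numeric vector of first-arrival times, one per receiver.
#' @export
eikonal_tof <- function(sos, source, receivers, solver_spacing = 1e-4,
                        pad = 2e-3, init_radius = 5) {
  stopifnot(inherits(sos, "sos_map"), solver_spacing > 0)
  receivers <- matrix(as.numeric(receivers), ncol = 2)
  g <- sos$grid
  corner <- grid_corner(g)
  xs <- c(corner[1], corner[1] + g$extent, source[1], receivers[, 1])
  ys <- c(corner[2], corner[2] + g$extent, source[2], receivers[, 2])
  h <- solver_spacing
  xmin <- min(xs) - pad
  ymin <- min(ys) - pad
  nx <- ceiling((max(xs) + pad - xmin) / h) + 1L
  ny <- ceiling((max(ys) + pad - ymin) / h) + 1L
  if (nx > 4096 || ny > 4096)
    stop("receivers outside the supported padded solver domain ",
         "(solver grid would exceed 4096 nodes per side)")

  # sample the SOS map at solver nodes (nearest pixel; v0 outside the map)
  node_x <- xmin + (seq_len(nx) - 1) * h
  node_y <- ymin + (seq_len(ny) - 1) * h
  ix <- floor((node_x - corner[1]) / g$spacing)
  iy <- floor((node_y - corner[2]) / g$spacing)
  inx <- ix >= 0 & ix < g$nx
  iny <- iy >= 0 & iy < g$ny
  v <- matrix(sos$background_speed, nx, ny)
  if (any(inx) && any(iny))
    v[inx, iny] <- sos$values[cbind(rep(ix[inx] + 1L, sum(iny)),
                                    rep(iy[iny] + 1L, each = sum(inx)))]
  Tf <- cpp_fmm(nx, ny, h, xmin, ymin, 1 / as.vector(v),
                source[1], source[2], init_radius)
  Tm <- matrix(Tf, nx, ny)

  fx <- (receivers[, 1] - xmin) / h
  fy <- (receivers[, 2] - ymin) / h
  if (any(fx < 0 | fx > nx - 1 | fy < 0 | fy > ny - 1))
    stop("receivers outside the padded solver domain")
  i0 <- pmin(floor(fx), nx - 2)
  j0 <- pmin(floor(fy), ny - 2)
  wx <- fx - i0
  wy <- fy - j0
  idx <- function(i, j) cbind(i + 1L, j + 1L)
  (1 - wx) * (1 - wy) * Tm[idx(i0, j0)] +
    wx * (1 - wy) * Tm[idx(i0 + 1, j0)] +
    (1 - wx) * wy * Tm[idx(i0, j0 + 1)] +
    wx * wy * Tm[idx(i0 + 1, j0 + 1)]
}

#' Eikonal beacon-to-element TOF table
#'
#' Runs [eikonal_tof()] once per beacon position and assembles the full
#' `N x M` measured table.
#'
#' @param sos an [sos_map()].
#' @param geom a [ring_array()].
#' @param scan a [beacon_scan()].
#' @param ... further arguments passed to [eikonal_tof()].
#' @return a [tof_table()] of kind `"measured"`.
#' @export
eikonal_tof_table <- function(sos, geom, scan, ...) {
  el <- element_positions(geom)
  bc <- beacon_positions(scan)
  vals <- t(vapply(seq_len(nrow(bc)),
                   function(n) eikonal_tof(sos, bc[n, ], el, ...),
                   numeric(nrow(el))))
  tof_table(matrix(vals, nrow(bc), nrow(el)), kind = "measured")
}
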