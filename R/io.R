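# On-disk formats
#
# Maps and images: single-page 32-bit float TIFF plus a JSON sidecar
# (<file>.json) carrying grid metadata in mm.
# Sinogram sets and TOF tables: flat little-endian float binaries with a
# JSON header (shape, dtype, sampling parameters), one .f32/.f64 file per
# dataset -- a deliberately simple, language-neutral container.
# Path operators: CSC component vectors (indptr/indices/data) in the same
# flat container.

write_json_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
}

read_json_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

grid_meta <- function(grid) {
  list(nx = grid$nx, ny = grid$ny, extent_mm = grid$extent * 1e3,
       origin_mm = grid$origin * 1e3)
}

grid_from_meta <- function(m) {
  image_grid(extent = m$extent_mm * 1e-3, n = m$nx,
             origin = m$origin_mm * 1e-3)
}

#' Write / read an SOS map as 32-bit float TIFF
#'
#' The speed field (m/s) goes into a single-page float TIFF; grid metadata
#' (pixel size, extent, origin, background speed) into a JSON sidecar next
#' to it. Values round-trip at float32 precision.
#'
#' @param sos an [sos_map()].
#' @param path output TIFF path (the sidecar is `<path>.json`).
#' @return `write_sos_tiff`: the path, invisibly. `read_sos_tiff`: an
#'   [sos_map()].
#' @export
write_sos_tiff <- function(sos, path) {
  stopifnot(inherits(sos, "sos_map"))
  # tiff expects [row, col] with rows top-to-bottom; store y as rows, top row
  # = max y, so the image displays with +y up. Values are scaled into [0, 1]
  # (TIFF sample range); the scale is recorded in the sidecar.
  scale <- 5000  # guard-rail ceiling, m/s
  img <- t(sos$values)[rev(seq_len(sos$grid$ny)), , drop = FALSE] / scale
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(grid_meta(sos$grid),
            list(background_speed = sos$background_speed, units = "m/s",
                 value_scale = scale))
  write_json_sidecar(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_sos_tiff
#' @export
read_sos_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  meta <- read_json_sidecar(paste0(path, ".json"))
  grid <- grid_from_meta(meta)
  values <- t(img[rev(seq_len(nrow(img))), , drop = FALSE]) * meta$value_scale
  sos_map(grid, values, meta$background_speed)
}

#' Write / read a reconstructed image as 32-bit float TIFF
#'
#' Amplitudes are affinely mapped into the TIFF sample range [0, 1]; the
#' offset and scale are stored in the JSON sidecar together with the grid
#' metadata, so values round-trip at float32 precision.
#'
#' @param img a [recon_image()].
#' @param path output TIFF path.
#' @return `write_recon_tiff`: the path, invisibly; `read_recon_tiff`: a
#'   [recon_image()].
#' @export
write_recon_tiff <- function(img, path) {
  stopifnot(inherits(img, "recon_image"))
  m <- t(img$values)[rev(seq_len(img$grid$ny)), , drop = FALSE]
  # map amplitudes into [0, 1] (TIFF sample range); offset/scale in sidecar
  lo <- min(m)
  scale <- max(m) - lo
  if (scale == 0) scale <- 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  write_json_sidecar(c(grid_meta(img$grid),
                       list(value_offset = lo, value_scale = scale)),
                     paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_recon_tiff
#' @export
read_recon_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  meta <- read_json_sidecar(paste0(path, ".json"))
  recon_image(grid_from_meta(meta),
              t(m[rev(seq_len(nrow(m))), , drop = FALSE]) * meta$value_scale +
                meta$value_offset)
}

write_flat <- function(x, path, size) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = size, endian = "little")
}

read_flat <- function(path, n, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = size, endian = "little")
}

#' Write / read a set of beacon sinograms
#'
#' The N sinograms (M x T each) are stored as one flat little-endian
#' float32 binary in (beacon, channel, sample) order with a JSON header
#' holding the shape and acquisition parameters. Values round-trip exactly
#' at float32 precision.
#'
#' @param sinos list of [sinogram()]s with common acquisition parameters.
#' @param path output path (`.f32` binary; header at `<path>.json`).
#' @return `write_sinogram_set`: the path, invisibly;
#'   `read_sinogram_set`: a list of [sinogram()]s.
#' @export
write_sinogram_set <- function(sinos, path) {
  stopifnot(length(sinos) >= 1, all(vapply(sinos, inherits, TRUE, "sinogram")))
  acq <- sinos[[1]]$acq
  M <- nrow(sinos[[1]]$data)
  Tn <- acq$n_samples
  dat <- unlist(lapply(sinos, function(s) as.vector(t(s$data))))
  write_flat(dat, path, size = 4L)
  write_json_sidecar(list(n_beacons = length(sinos), n_channels = M,
                          n_samples = Tn, dtype = "float32",
                          order = "beacon,channel,sample",
                          sampling_rate_hz = acq$sampling_rate,
                          t0_s = acq$t0),
                     paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_sinogram_set
#' @export
read_sinogram_set <- function(path) {
  h <- read_json_sidecar(paste0(path, ".json"))
  acq <- acq_params(h$sampling_rate_hz, h$n_samples, h$t0_s)
  n <- h$n_beacons * h$n_channels * h$n_samples
  v <- read_flat(path, n, size = 4L)
  lapply(seq_len(h$n_beacons), function(b) {
    off <- (b - 1) * h$n_channels * h$n_samples
    m <- matrix(v[off + seq_len(h$n_channels * h$n_samples)],
                h$n_channels, h$n_samples, byrow = TRUE)
    sinogram(m, acq, beacon_index = b)
  })
}

#' Write / read a TOF table
#'
#' Stored as a flat float64 binary (beacon-major) plus a JSON header with
#' the shape and kind; round-trips bit-exactly.
#'
#' @param tof a [tof_table()].
#' @param path output path.
#' @return `write_tof_table`: the path, invisibly; `read_tof_table`: a
#'   [tof_table()].
#' @export
write_tof_table <- function(tof, path) {
  stopifnot(inherits(tof, "tof_table"))
  write_flat(tof_vector(tof), path, size = 8L)
  write_json_sidecar(list(n_beacons = nrow(tof$values),
                          n_channels = ncol(tof$values),
                          kind = tof$kind, dtype = "float64",
                          order = "beacon-major"),
                     paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_tof_table
#' @export
read_tof_table <- function(path) {
  h <- read_json_sidecar(paste0(path, ".json"))
  v <- read_flat(path, h$n_beacons * h$n_channels, size = 8L)
  tof_table(matrix(v, h$n_beacons, h$n_channels, byrow = TRUE),
            kind = h$kind)
}

#' Write / read a path operator
#'
#' Compressed sparse column components (`indptr`, `indices`, `data`) plus
#' the out-of-grid chord lengths and grid metadata; float64 throughout, so
#' row sums round-trip to 0 ULP.
#'
#' @param op a [build_path_operator()] result.
#' @param path base output path; component files get suffixes.
#' @return `write_path_operator`: the path, invisibly;
#'   `read_path_operator`: a `path_operator`.
#' @export
write_path_operator <- function(op, path) {
  stopifnot(inherits(op, "path_operator"))
  W <- methods::as(op$W, "CsparseMatrix")
  write_flat(W@x, paste0(path, ".data.f64"), size = 8L)
  write_flat(W@i, paste0(path, ".indices.f64"), size = 8L)
  write_flat(W@p, paste0(path, ".indptr.f64"), size = 8L)
  write_flat(op$out_grid_len, paste0(path, ".outlen.f64"), size = 8L)
  write_flat(op$total_len, paste0(path, ".totlen.f64"), size = 8L)
  write_json_sidecar(c(list(n_rows = nrow(W), n_cols = ncol(W),
                            nnz = length(W@x), M = op$M, N = op$N, K = op$K),
                       grid_meta(op$grid)),
                     paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_path_operator
#' @export
read_path_operator <- function(path) {
  h <- read_json_sidecar(paste0(path, ".json"))
  x <- read_flat(paste0(path, ".data.f64"), h$nnz, 8L)
  i <- as.integer(read_flat(paste0(path, ".indices.f64"), h$nnz, 8L))
  p <- as.integer(read_flat(paste0(path, ".indptr.f64"), h$n_cols + 1, 8L))
  W <- Matrix::sparseMatrix(i = i + 1L, p = p, x = x,
                            dims = c(h$n_rows, h$n_cols))
  structure(list(W = W,
                 out_grid_len = read_flat(paste0(path, ".outlen.f64"),
                                          h$n_rows, 8L),
                 total_len = read_flat(paste0(path, ".totlen.f64"),
                                       h$n_rows, 8L),
                 grid = grid_from_meta(h),
                 M = h$M, N = h$N, K = h$K),
            class = "path_operator")
}

#' Export a TOF table as CSV
#'
#' Long format for inspection: one row per (beacon, channel) with the time
#' in microseconds.
#'
#' @param tof a [tof_table()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_tof_csv <- function(tof, path) {
  stopifnot(inherits(tof, "tof_table"))
  df <- data.frame(beacon_index = rep(seq_len(nrow(tof$values)),
                                      each = ncol(tof$values)),
                   channel = rep(seq_len(ncol(tof$values)),
                                 times = nrow(tof$values)),
                   tof_us = as.vector(t(tof$values)) * 1e6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
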