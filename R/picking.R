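#' Signal envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal of each row (channel) of a
#' matrix, computed in the frequency domain.
#'
#' @param x numeric matrix, channels in rows.
#' @return matrix of the same shape with the per-channel envelope.
#' @export
signal_envelope <- function(x) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  t(apply(x, 1, function(row) {
    Mod(stats::fft(stats::fft(row) * h, inverse = TRUE) / n)
  }))
}

#' Extract the beacon search strip from a sinogram
#'
#' For each channel the beacon arrival must fall between
#' `d_m / v_max` and `d_m / v_min` (`d_m` the beacon-element distance), so a
#' window covering that bracket plus `margin` samples is cut out of the
#' envelope of the sinogram. Windows are padded to a uniform width across
#' channels; windows reaching past the record are clipped with a warning.
#'
#' @param sino a [sinogram()].
#' @param beacon beacon position, meters.
#' @param geom a [ring_array()].
#' @param v_min,v_max sound-speed bracket, m/s (defaults 1400 / 1700).
#' @param margin extra samples on each side of the bracket (default 32).
#' @return an object of class `dp_strip` with elements `data` (M x width
#'   envelope), `window_start` (0-based per-channel sample offset), `acq`.
#' @export
extract_strip <- function(sino, beacon, geom, v_min = 1400, v_max = 1700,
                          margin = 32L) {
  stopifnot(inherits(sino, "sinogram"), v_min > 0, v_min < v_max)
  el <- element_positions(geom)
  M <- nrow(el)
  if (nrow(sino$data) != M) stop("sinogram channel count does not match geometry")
  acq <- sino$acq
  fs <- acq$sampling_rate
  d <- sqrt((el[, 1] - beacon[1])^2 + (el[, 2] - beacon[2])^2)
  lo <- floor((d / v_max - acq$t0) * fs) - margin      # 0-based sample
  hi <- ceiling((d / v_min - acq$t0) * fs) + margin
  width <- as.integer(max(hi - lo) + 1L)
  Tn <- acq$n_samples
  if (width > Tn) {
    width <- Tn
    warning("search window wider than the record; using the full record")
  }
  start <- pmax(0L, pmin(as.integer(lo), Tn - width))
  if (any(hi > Tn - 1L) || any(lo < 0L))
    warning("beacon search window clipped to the recorded samples")
  env <- signal_envelope(sino$data)
  dat <- matrix(0, M, width)
  for (m in seq_len(M)) {
    dat[m, ] <- env[m, (start[m] + 1L):(start[m] + width)]
  }
  structure(list(data = dat, window_start = start, acq = acq),
            class = "dp_strip")
}

#' @export
print.dp_strip <- function(x, ...) {
  cat(sprintf("<dp_strip> %d channels x %d samples\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

pick_result <- function(strip, sample_index, path_cost, method,
                        low_confidence = FALSE) {
  fs <- strip$acq$sampling_rate
  tof <- strip$acq$t0 + (strip$window_start + sample_index) / fs
  structure(list(sample_index = sample_index, tof = tof,
                 path_cost = path_cost, method = method,
                 low_confidence = low_confidence),
            class = "pick_result")
}

#' @export
print.pick_result <- function(x, ...) {
  cat(sprintf("<pick_result:%s> %d channels, cost %.4g%s\n", x$method,
              length(x$tof), x$path_cost,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Dynamic-programming beacon trace picking
#'
#' Finds the channel-ordered path of sample indices with minimal total cost,
#' where the node cost is `1 - e` (envelope `e` normalized to peak 1 over
#' the strip) and moving by `d` samples between adjacent channels costs
#' `smoothness_weight * |d|`, with `|d| <= jump_limit`. The optimum is exact
#' by dynamic programming over channels; ties are broken toward the earlier
#' sample. The continuity constraint is what separates the beacon trace from
#' stronger but isolated interferer transients.
#'
#' @param strip a [extract_strip()] result.
#' @param jump_limit maximum inter-channel index jump, samples (default 3).
#' @param smoothness_weight transition cost per sample of jump (default
#'   1e-4). The continuity constraint proper is the hard jump limit; the
#'   weight's role is to break ties and disfavor gratuitous detours, so it
#'   is set far below the node-cost increase of leaving the beacon
#'   wavelet's envelope peak by one sample (about 0.3 for a 5 MHz wavelet
#'   at 40 MHz sampling). Larger weights straighten the picked trace at the
#'   price of a possible one-sample bias where the true arrival falls near
#'   a half-sample boundary.
#' @return a `pick_result` with integer `sample_index` (0-based within the
#'   window), per-channel `tof` in seconds, and the accumulated `path_cost`.
#'   An all-zero strip yields a flat low-confidence pick, not an error.
#' @export
dp_pick <- function(strip, jump_limit = 3L, smoothness_weight = 1e-4) {
  stopifnot(inherits(strip, "dp_strip"), jump_limit >= 1)
  e <- strip$data
  M <- nrow(e)
  Wd <- ncol(e)
  peak <- max(e)
  low_conf <- peak <= 0
  node <- if (low_conf) matrix(1, M, Wd) else 1 - e / peak
  L <- as.integer(jump_limit)
  D <- node[1, ]
  bp <- matrix(0L, M, Wd)  # backpointer: previous sample index (1-based)
  for (m in seq_len(M)[-1]) {
    best <- rep(Inf, Wd)
    barg <- integer(Wd)
    for (d in (-L):L) {
      # previous index jp = j + d, valid where 1 <= j + d <= Wd
      j <- seq_len(Wd)
      jp <- j + d
      ok <- jp >= 1L & jp <= Wd
      cand <- rep(Inf, Wd)
      cand[ok] <- D[jp[ok]] + smoothness_weight * abs(d)
      upd <- cand < best  # strict: earlier jp (smaller d) wins ties
      best[upd] <- cand[upd]
      barg[upd] <- jp[upd]
    }
    D <- node[m, ] + best
    bp[m, ] <- barg
  }
  jend <- which.min(D)  # which.min takes the earliest minimum
  path <- integer(M)
  path[M] <- jend
  for (m in rev(seq_len(M - 1))) path[m] <- bp[m + 1, path[m + 1]]
  pick_result(strip, sample_index = path - 1L, path_cost = D[jend],
              method = "dp", low_confidence = low_conf)
}

#' Maximum-value picking baseline
#'
#' Per-channel argmax of the envelope, with no continuity constraint. Prone
#' to jumping onto stronger interferer transients; kept as the comparison
#' baseline for [dp_pick()].
#'
#' @param strip a [extract_strip()] result.
#' @return a `pick_result` (`method = "max"`); `path_cost` is evaluated
#'   under the same cost function as [dp_pick()] for comparability.
#' @param jump_limit,smoothness_weight cost parameters used only to price
#'   the resulting path for comparison with [dp_pick()].
#' @export
max_pick <- function(strip, jump_limit = 3L, smoothness_weight = 1e-4) {
  stopifnot(inherits(strip, "dp_strip"))
  e <- strip$data
  peak <- max(e)
  low_conf <- peak <= 0
  idx <- apply(e, 1, which.max)
  node <- if (low_conf) rep(1, nrow(e)) else
    1 - e[cbind(seq_len(nrow(e)), idx)] / peak
  cost <- sum(node) + smoothness_weight * sum(abs(diff(idx)))
  pick_result(strip, sample_index = idx - 1L, path_cost = cost,
              method = "max", low_confidence = low_conf)
}

#' Sub-sample refinement of integer picks
#'
#' Three-point parabolic interpolation of the log-envelope around each
#' integer pick (exact for Gaussian-shaped envelopes; falls back to the
#' plain envelope when a neighbor sample is non-positive); the fractional
#' correction is bounded by half a sample. Picks at window edges are left
#' unrefined.
#'
#' @param strip a [extract_strip()] result.
#' @param picks a `pick_result` with integer sample indices.
#' @return a `pick_result` with fractional `sample_index` and updated `tof`.
#' @export
refine_subsample <- function(strip, picks) {
  stopifnot(inherits(strip, "dp_strip"), inherits(picks, "pick_result"))
  e <- strip$data
  Wd <- ncol(e)
  j <- as.integer(round(picks$sample_index)) + 1L  # 1-based
  frac <- numeric(length(j))
  interior <- j > 1L & j < Wd
  if (any(interior)) {
    m <- which(interior)
    y0 <- e[cbind(m, j[m] - 1L)]
    y1 <- e[cbind(m, j[m])]
    y2 <- e[cbind(m, j[m] + 1L)]
    uselog <- y0 > 0 & y1 > 0 & y2 > 0
    y0 <- ifelse(uselog, log(y0), y0)
    y1 <- ifelse(uselog, log(y1), y1)
    y2 <- ifelse(uselog, log(y2), y2)
    den <- y0 - 2 * y1 + y2
    del <- ifelse(abs(den) > 0, 0.5 * (y0 - y2) / den, 0)
    frac[m] <- pmax(-0.5, pmin(0.5, del))
  }
  pick_result(strip, sample_index = j - 1L + frac,
              path_cost = picks$path_cost, method = picks$method,
              low_confidence = picks$low_confidence)
}

#' Background-subtracted TOF
#'
#' The SOS perturbation caused by the imaged object:
#' `delta = t_b - t` element-wise. Any constant picking bias common to both
#' tables (e.g. the envelope-peak offset of the wavelet) cancels.
#'
#' @param t measured [tof_table()].
#' @param t_b background [tof_table()].
#' @return a [tof_table()] of kind `"delta"`.
#' @export
delta_tof <- function(t, t_b) {
  stopifnot(inherits(t, "tof_table"), inherits(t_b, "tof_table"))
  if (!all(dim(t$values) == dim(t_b$values)))
    stop("TOF table shapes do not match")
  tof_table(t_b$values - t$values, kind = "delta")
}

#' Pick beacon TOFs for a whole scan
#'
#' Runs strip extraction, DP picking and optional sub-sample refinement on
#' one sinogram per beacon position and assembles the `N x M` measured TOF
#' table.
#'
#' @param sinograms list of N [sinogram()]s, one per beacon position (in
#'   beacon order).
#' @param geom a [ring_array()].
#' @param scan a [beacon_scan()].
#' @param v_min,v_max,margin see [extract_strip()].
#' @param jump_limit,smoothness_weight see [dp_pick()].
#' @param refine logical; apply [refine_subsample()] (default TRUE).
#' @return a [tof_table()] of kind `"measured"`.
#' @export
pick_tof_table <- function(sinograms, geom, scan, v_min = 1400, v_max = 1700,
                           margin = 32L, jump_limit = 3L,
                           smoothness_weight = 1e-4, refine = TRUE) {
  bc <- beacon_positions(scan)
  N <- nrow(bc)
  if (length(sinograms) != N)
    stop("need one sinogram per beacon position")
  M <- geom$n_elements
  vals <- matrix(NA_real_, N, M)
  for (n in seq_len(N)) {
    strip <- extract_strip(sinograms[[n]], bc[n, ], geom,
                           v_min = v_min, v_max = v_max, margin = margin)
    pk <- dp_pick(strip, jump_limit = jump_limit,
                  smoothness_weight = smoothness_weight)
    if (refine) pk <- refine_subsample(strip, pk)
    vals[n, ] <- pk$tof
  }
  tof_table(vals, kind = "measured")
}
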