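make_strip <- function(env, fs = 40e6) {
  structure(list(data = env, window_start = rep(0L, nrow(env)),
                 acq = acq_params(fs, ncol(env))),
            class = "dp_strip")
}

test_that("strip windows bracket the speed range with margins", {
  # beacon-element distance 60 mm: bracket alone spans >= 303 samples
  geom <- ring_array(n_elements = 2, ring_radius = 40.5e-3, arc_span = 360,
                     start_angle = -90)
  acq <- acq_params()
  sino <- sinogram(matrix(0, 2, acq$n_samples), acq)
  beacon <- c(-19.5e-3, 0)  # element 1 at (40.5, 0): d = 60 mm
  expect_warning(strip <- extract_strip(sino, beacon, geom, margin = 32L),
                 NA)
  d <- sqrt(sum((c(40.5e-3, 0) - beacon)^2))
  expect_gte(ncol(strip$data), (d * (1 / 1400 - 1 / 1700)) * 40e6 + 64)
  # planted arrival inside the window for any in-bracket speed
  for (v0 in c(1405, 1500, 1695)) {
    s_arr <- d / v0 * 40e6
    expect_gte(s_arr, strip$window_start[1])
    expect_lte(s_arr, strip$window_start[1] + ncol(strip$data) - 1)
  }
})

test_that("DP picking equals brute-force enumeration on random small strips", {
  set.seed(42)
  for (i in seq_len(100)) {
    env <- matrix(runif(4 * 6), 4, 6)
    strip <- make_strip(env)
    jl <- sample(1:3, 1)
    w <- runif(1, 0, 0.5)
    pk <- dp_pick(strip, jump_limit = jl, smoothness_weight = w)
    bf <- dp_brute_force(env, jl, w)
    expect_equal(pk$path_cost, bf$cost, tolerance = 1e-12)
    expect_equal(pk$sample_index + 1L, unname(bf$path))
    # DP optimum never exceeds the cost of any feasible path, in
    # particular the max-pick path when its jumps respect the limit
    mp <- max_pick(strip, jump_limit = jl, smoothness_weight = w)
    if (all(abs(diff(mp$sample_index)) <= jl))
      expect_lte(pk$path_cost, mp$path_cost + 1e-12)
  }
})

test_that("a planted constant trace is picked exactly; all-zero strips flagged", {
  env <- matrix(0, 5, 10)
  env[, 4] <- 1
  pk <- dp_pick(make_strip(env))
  expect_equal(pk$sample_index, rep(3L, 5))
  expect_false(pk$low_confidence)
  z <- dp_pick(make_strip(matrix(0, 4, 6)))
  expect_true(z$low_confidence)
})

test_that("DP resists a strong isolated transient that fools max picking", {
  # smooth planted trace + a stronger interferer crossing two channels at a
  # distant sample, as in mixed beacon/object data
  set.seed(3)
  M <- 16; Wd <- 40
  true_idx <- round(20 + 3 * sin(seq_len(M) / 3))
  env <- matrix(0.01, M, Wd)
  for (m in seq_len(M)) {
    env[m, ] <- env[m, ] + exp(-0.5 * ((seq_len(Wd) - true_idx[m]) / 1.5)^2)
  }
  for (m in 7:8) {
    env[m, ] <- env[m, ] + 1.8 * exp(-0.5 * ((seq_len(Wd) - 33) / 1.5)^2)
  }
  strip <- make_strip(env)
  dp <- dp_pick(strip)
  mx <- max_pick(strip)
  expect_gte(sum(mx$sample_index + 1L != true_idx), 2)  # max picking fooled
  expect_lte(sum(abs(dp$sample_index + 1L - true_idx) > 1), 2)
  expect_lte(max(abs((dp$sample_index + 1L - true_idx)[-(6:9)])), 0)
})

test_that("sub-sample refinement recovers fractional arrivals within 0.1 sample", {
  acq <- acq_params(n_samples = 1024L)
  spec <- waveform_spec(noise_sigma = 0)
  for (frac in c(0, 0.25, 0.4)) {
    tau <- (500 + frac) / acq$sampling_rate
    sino <- synthesize_beacon_sinogram(rep(tau, 8), spec, acq)
    strip <- make_strip(signal_envelope(sino$data))
    pk <- dp_pick(strip)
    pr <- refine_subsample(strip, pk)
    got <- pr$sample_index + strip$window_start
    expect_lt(max(abs(got - tau * acq$sampling_rate)), 0.1)
    # refinement moves picks by at most half a sample
    expect_lte(max(abs(pr$sample_index - pk$sample_index)), 0.5)
    # symmetric peak on a sample: no shift
    if (frac == 0) expect_lt(max(abs(pr$sample_index - pk$sample_index)), 0.01)
  }
})

test_that("noise-free pipeline recovers planted arrivals and the pick error grows with noise", {
  # 32 elements: in-window drift between adjacent channels is several
  # samples, so the jump limit is opened up relative to the 128-element
  # default
  geom <- small_geom(32)
  jl <- 12L
  scan <- beacon_scan(2)
  acq <- acq_params()
  tb <- background_tof(geom, scan, 1500)
  bc <- beacon_positions(scan)
  errs <- c()
  for (sigma in c(0, 0.5, 2)) {
    spec <- waveform_spec(beacon_amplitude = 10, noise_sigma = sigma, seed = 5)
    err <- 0
    for (n in 1:2) {
      sino <- synthesize_beacon_sinogram(tb$values[n, ], spec, acq)
      strip <- extract_strip(sino, bc[n, ], geom)
      pk <- refine_subsample(strip, dp_pick(strip, jump_limit = jl))
      true_s <- (tb$values[n, ] - acq$t0) * acq$sampling_rate
      err <- max(err, max(abs(pk$sample_index + strip$window_start - true_s)))
    }
    errs <- c(errs, err)
  }
  expect_lt(errs[1], 0.1)           # noise-free: sub-sample exact
  expect_true(all(diff(errs) >= 0)) # non-decreasing with noise
})

test_that("background subtraction cancels the common picking bias", {
  geom <- small_geom(64)
  jl <- 16L
  scan <- beacon_scan(2)
  acq <- acq_params()
  g <- image_grid(40e-3, 50)
  ph <- disc_phantom(g, c(0, 0), 16e-3, 1650, 1500)
  op <- build_path_operator(g, geom, scan)
  t_true <- forward_tof_map(op, ph)
  t_b_true <- background_tof(geom, scan, 1500)
  spec <- waveform_spec(noise_sigma = 0)
  bc <- beacon_positions(scan)
  pick_one <- function(times, n) {
    sino <- synthesize_beacon_sinogram(times[n, ], spec, acq)
    strip <- extract_strip(sino, bc[n, ], geom)
    refine_subsample(strip, dp_pick(strip, jump_limit = jl))$tof
  }
  t_meas <- tof_table(t(vapply(1:2, function(n) pick_one(t_true$values, n),
                               numeric(64))), "measured")
  t_bg <- tof_table(t(vapply(1:2, function(n) pick_one(t_b_true$values, n),
                             numeric(64))), "measured")
  dt_picked <- delta_tof(t_meas, t_bg)
  dt_true <- delta_tof(t_true, t_b_true)
  expect_lt(max(abs(dt_picked$values - dt_true$values)) * acq$sampling_rate,
            0.05)
  # delta sign convention and shape errors
  expect_true(all(dt_true$values > -1e-12))
  expect_error(delta_tof(t_meas, background_tof(geom, beacon_scan(3), 1500)),
               "shape")
  # t = t_b gives identically zero delta
  expect_true(all(delta_tof(t_b_true, t_b_true)$values == 0))
})
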