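test_that("axis-aligned and out-of-grid rays trace as expected", {
  g <- image_grid(40e-3, 100)
  # horizontal segment through one full row
  tr <- trace_ray(g, c(-25e-3, 0.21e-3), c(25e-3, 0.21e-3))
  expect_equal(length(tr$index), 100)
  expect_true(all(abs(tr$length - 0.4e-3) < 1e-12))
  # entirely outside
  tr2 <- trace_ray(g, c(-25e-3, 21e-3), c(25e-3, 21e-3))
  expect_equal(length(tr2$index), 0)
  expect_error(trace_ray(g, c(0, 0), c(0, 0)), "zero-length")
})

test_that("random rays agree with a dense-sampling oracle", {
  g <- image_grid(40e-3, 50)
  set.seed(11)
  n_ray <- 60
  for (i in seq_len(n_ray)) {
    a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    p0 <- 19e-3 * c(cos(a1), sin(a1))
    p1 <- 40.5e-3 * c(cos(a2), sin(a2))
    tr <- trace_ray(g, p0, p1)
    got <- tapply(tr$length, tr$index, sum)
    oracle <- ray_sampling_oracle(g, p0, p1, n = 1e5)
    L <- sqrt(sum((p1 - p0)^2))
    all_k <- union(names(got), names(oracle))
    gv <- ifelse(all_k %in% names(got), got[all_k], 0)
    ov <- ifelse(all_k %in% names(oracle), oracle[all_k], 0)
    expect_lt(max(abs(gv - ov), 0), 3 * L / 1e5)
  }
})

test_that("path operator has the documented shape, ordering and row sums", {
  g <- image_grid(40e-3, 100)
  geom <- ring_array()
  scan <- beacon_scan(10)
  op <- build_path_operator(g, geom, scan)
  expect_equal(dim(op$W), c(1280, 10000))
  expect_true(all(op$W@x >= 0))
  # row sums + out-of-grid part = total chord length
  rs <- Matrix::rowSums(op$W)
  expect_lt(max(abs(rs + op$out_grid_len - op$total_len)), 1e-9)
  # single-pair operator equals trace_ray
  op1 <- build_path_operator(g, ring_array(n_elements = 2), beacon_scan(1))
  el <- element_positions(ring_array(n_elements = 2))
  bc <- beacon_positions(beacon_scan(1))
  tr <- trace_ray(g, bc[1, ], el[1, ])
  row <- op1$W[1, ]
  expect_equal(as.numeric(row[tr$index]), tr$length)
  expect_equal(sum(row > 0), length(tr$index))
})

test_that("relabeling beacons permutes operator rows and tables consistently", {
  g <- image_grid(40e-3, 40)
  geom <- ring_array(n_elements = 8)
  s1 <- beacon_scan(4, start_angle = 0)
  s2 <- beacon_scan(4, start_angle = 90)  # rotation by one beacon step
  op1 <- build_path_operator(g, geom, s1)
  op2 <- build_path_operator(g, geom, s2)
  # beacon n of s2 is beacon n+1 of s1
  perm <- c(2, 3, 4, 1)
  rows1 <- do.call(rbind, lapply(perm, function(n)
    as.matrix(op1$W[(n - 1) * 8 + 1:8, ])))
  expect_equal(as.matrix(op2$W), rows1, tolerance = 1e-12)
})

test_that("forward TOF is linear, matches background on uniform media and the chord formula", {
  g <- image_grid(40e-3, 100)
  geom <- ring_array()
  scan <- beacon_scan(10)
  op <- build_path_operator(g, geom, scan)
  tb <- background_tof(geom, scan, 1500)
  t_uni <- forward_tof(op, rep(1 / 1500, op$K), 1500)
  expect_lt(max(abs(t_uni$values - tb$values)), 1e-12)
  # disc: rays through the disc are early, others match background
  ph <- disc_phantom(g, c(0, 0), 16e-3, 1650, 1500)
  tm <- forward_tof_map(op, ph)
  dt <- tb$values - tm$values
  bc <- beacon_positions(scan)
  el <- element_positions(geom)
  # chord length of the segment (not the infinite line) through the disc
  chord <- function(p0, p1, r = 8e-3) {
    d <- p1 - p0
    L <- sqrt(sum(d^2))
    u <- d / L
    tmid <- -sum(p0 * u)
    h2 <- sum(p0^2) - tmid^2
    if (h2 >= r^2) return(0)
    half <- sqrt(r^2 - h2)
    max(min(tmid + half, L) - max(tmid - half, 0), 0)
  }
  ch <- outer(seq_len(10), seq_len(128),
              Vectorize(function(n, m) chord(bc[n, ], el[m, ])))
  ch9 <- outer(seq_len(10), seq_len(128),
               Vectorize(function(n, m) chord(bc[n, ], el[m, ], r = 9e-3)))
  # fast inclusion: no ray is ever late
  expect_true(all(dt > -1e-12))
  # rays with a chord deep enough to cover interior pixel centers are early
  expect_true(all(dt[ch > 7e-3] > 0))
  # rays clearing the disc by >1 mm never touch disc-labeled pixels
  expect_true(all(abs(dt[ch9 == 0]) < 1e-12))
  # central ray: delta = chord * (1/1500 - 1/1650), pixelization tolerance
  m0 <- which.max(ch[1, ])
  expect_equal(dt[1, m0], ch[1, m0] * (1 / 1500 - 1 / 1650),
               tolerance = 3e-2)
  # linearity of the in-grid part
  s1 <- rep(1 / 1500, op$K)
  s2 <- 1 / as.vector(ph$values)
  y1 <- as.numeric(op$W %*% s1)
  y2 <- as.numeric(op$W %*% s2)
  y12 <- as.numeric(op$W %*% (0.3 * s1 + 0.7 * s2))
  expect_equal(y12, 0.3 * y1 + 0.7 * y2, tolerance = 1e-12)
})

test_that("forward TOF agrees across grid refinement", {
  geom <- ring_array()
  scan <- beacon_scan(5)
  t100 <- forward_tof_map(build_path_operator(image_grid(40e-3, 100), geom, scan),
                          disc_phantom(image_grid(40e-3, 100)))
  t400 <- forward_tof_map(build_path_operator(image_grid(40e-3, 400), geom, scan),
                          disc_phantom(image_grid(40e-3, 400)))
  # dominated by re-pixelization of the disc boundary between grids
  expect_lt(max(abs(t100$values - t400$values) / t400$values), 2e-3)
})

test_that("eikonal times match the closed form on homogeneous media", {
  g <- image_grid(40e-3, 50)
  ph <- disc_phantom(g, diameter = 0)
  src <- c(19e-3, 0)
  rec <- rbind(c(-20e-3, 0), c(0, 19e-3), c(40.5e-3, 0))
  tt <- eikonal_tof(ph, src, rec, solver_spacing = 1e-4)
  d <- sqrt(rowSums(sweep(rec, 2, src)^2))
  # first-order solver: ~0.5 % on the nearby receiver, slightly more on the
  # longest diagonal paths
  expect_lt(abs(tt[3] - d[3] / 1500) / (d[3] / 1500), 0.005)
  expect_lt(max(abs(tt - d / 1500) / (d / 1500)), 0.007)
  expect_error(eikonal_tof(ph, src, rbind(c(1, 1)), solver_spacing = 1e-4),
               "outside")
})

test_that("eikonal first arrivals respect Fermat's bound and contrast limits", {
  g <- image_grid(40e-3, 50)
  geom <- ring_array(n_elements = 16)
  scan <- beacon_scan(4)
  op <- build_path_operator(g, geom, scan)
  tb <- background_tof(geom, scan, 1500)
  te_bg <- eikonal_tof_table(disc_phantom(g, diameter = 0), geom, scan,
                             solver_spacing = 2e-4)
  prev <- NULL
  for (v_in in c(1520, 1560, 1650)) {
    ph <- disc_phantom(g, c(0, 0), 16e-3, v_in, 1500)
    te <- eikonal_tof_table(ph, geom, scan, solver_spacing = 2e-4)
    ts <- forward_tof_map(op, ph)
    # first arrival <= straight-ray time (+ first-order solver tolerance)
    slack <- 0.012 * tb$values
    expect_true(all(te$values <= ts$values + slack))
    expect_true(all(te$values <= tb$values + slack))
    # central-ray perturbation (solver bias cancelled by the eikonal
    # background) grows with contrast toward the straight-chord value
    dtc <- max(te_bg$values - te$values)
    if (!is.null(prev)) expect_gt(dtc, prev)
    prev <- dtc
    if (v_in == 1650) {
      chord_dt <- 16e-3 * (1 / 1500 - 1 / 1650)
      expect_lt(abs(dtc - chord_dt) / chord_dt, 0.15)
    }
  }
})
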