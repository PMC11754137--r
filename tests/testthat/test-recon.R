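# Point-absorber sinogram with a unipolar Gaussian pulse: its amplitude
# peaks exactly at the geometric delay, so focusing behaviour of the
# beamformers can be judged on the raw-sample peak.
gaussian_pulse_sinogram <- function(tau, acq, sigma = 1 / (2 * pi * 5e6)) {
  tt <- acq$t0 + (seq_len(acq$n_samples) - 1) / acq$sampling_rate
  data <- t(vapply(tau, function(tc) exp(-(tt - tc)^2 / (2 * sigma^2)),
                   numeric(acq$n_samples)))
  sinogram(data, acq)
}

point_source_sinogram <- function(pos, geom, acq, v = 1500) {
  el <- element_positions(geom)
  d <- sqrt((el[, 1] - pos[1])^2 + (el[, 2] - pos[2])^2)
  gaussian_pulse_sinogram(d / v, acq)
}

test_that("DAS focuses a point absorber and is linear", {
  geom <- ring_array()
  acq <- acq_params()
  g <- image_grid(40e-3, 100)
  sino <- point_source_sinogram(c(0, 0), geom, acq)
  img <- das(sino, g, geom, 1500)
  k <- which.max(img$values)
  ctr <- grid_pixel_centers(g)[k, ]
  expect_lt(sqrt(sum(ctr^2)), 0.5e-3)  # peak within a pixel of the source
  # all-zero sinogram -> all-zero image
  z <- das(sinogram(matrix(0, 128, acq$n_samples), acq), g, geom, 1500)
  expect_true(all(z$values == 0))
  # 5 % speed error defocuses: matched-speed peak is strictly higher
  img_wrong <- das(sino, g, geom, 1575)
  expect_lt(max(img_wrong$values), max(img$values))
  # linearity
  sino2 <- point_source_sinogram(c(5e-3, -3e-3), geom, acq)
  mix <- sinogram(2 * sino$data - 0.5 * sino2$data, acq)
  img_mix <- das(mix, g, geom, 1500)
  img2 <- das(sino2, g, geom, 1500)
  expect_equal(img_mix$values, 2 * img$values - 0.5 * img2$values,
               tolerance = 1e-12)
})

test_that("TOF volumes match closed forms on uniform and layered media", {
  geom <- ring_array(n_elements = 8)
  g <- image_grid(40e-3, 50)
  ph0 <- disc_phantom(g, diameter = 0)
  vol <- compute_tof_volume(ph0, geom, g)
  expect_equal(dim(vol$times), c(2500, 8))
  el <- element_positions(geom)
  pc <- grid_pixel_centers(g)
  d <- sqrt(outer(pc[, 1], el[, 1], "-")^2 + outer(pc[, 2], el[, 2], "-")^2)
  expect_lt(max(abs(vol$times - d / 1500)), 1e-12)
  # two-layer medium along an exactly axis-aligned ray: element shifted to
  # (40.5, 0.4) mm so the ray from pixel (-10, 0.4) mm runs along one row
  v2 <- matrix(1500, 50, 50)
  v2[pc[seq_len(50), 1] > 0, ] <- 1600  # x > 0 half at 1600
  ph2 <- sos_map(g, v2, 1500)
  # element 1 at (40.5, 0.4) mm: ray from pixel (-10, 0.4) mm runs along a row
  geom_ax <- ring_array(n_elements = 2, arc_span = 360, start_angle = -90,
                        center = c(0, 0.4e-3))
  volx <- compute_tof_volume(ph2, geom_ax, g)
  px <- which(abs(pc[, 1] + 10e-3) < 1e-9 & abs(pc[, 2] - 0.4e-3) < 1e-9)
  t_hand <- (10e-3 / 1500) + (20e-3 / 1600) + ((40.5e-3 - 20e-3) / 1500)
  expect_equal(volx$times[px, 1], t_hand, tolerance = 1e-12)
})

test_that("bicubic TOF upsampling reproduces constants and converges fast", {
  g_f <- image_grid(40e-3, 80)
  const_vol <- structure(list(times = matrix(2.5e-5, 400, 3),
                              grid = image_grid(40e-3, 20), n_elements = 3L),
                         class = "tof_volume")
  fine <- interp_tof(const_vol, g_f)
  expect_true(all(abs(fine$times - 2.5e-5) < 1e-16))
  # smooth analytic field: error shrinks by >= 4x when resolution doubles
  f <- function(p) 1e-5 * (2 + sin(150 * p[, 1]) * cos(130 * p[, 2]))
  errs <- vapply(c(20, 40), function(nc) {
    gc <- image_grid(40e-3, nc)
    vol <- structure(list(times = matrix(f(grid_pixel_centers(gc)), ncol = 1),
                          grid = gc, n_elements = 1L), class = "tof_volume")
    fi <- interp_tof(vol, g_f)
    # judge interior pixels: boundary handling is tested separately
    pc <- grid_pixel_centers(g_f)
    interior <- pmin(pc[, 1] + 20e-3, 20e-3 - pc[, 1],
                     pc[, 2] + 20e-3, 20e-3 - pc[, 2]) > 4e-3
    max(abs(fi$times[interior, 1] - f(pc)[interior]))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 4)
  # extent mismatch rejected
  expect_error(interp_tof(structure(list(times = matrix(0, 400, 1),
                                         grid = image_grid(20e-3, 20),
                                         n_elements = 1L),
                                    class = "tof_volume"),
                          g_f), "cover")
})

test_that("TI-MDAS reduces to DAS on uniform media", {
  geom <- ring_array()
  acq <- acq_params()
  g <- image_grid(40e-3, 100)
  ph0 <- disc_phantom(image_grid(40e-3, 100), diameter = 0)
  sino <- point_source_sinogram(c(2e-3, -4e-3), geom, acq)
  ref <- das(sino, g, geom, 1500)
  ti <- ti_mdas(sino, ph0, geom, coarse_n = 50L, fine_n = 100L)
  # 0.8 mm coarse pixels: interpolation error well above the reference-grid
  # consistency level but still parts-per-million of the peak
  expect_lt(max(abs(ti$values - ref$values)) / max(abs(ref$values)), 5e-6)
  # coarse = fine: identical to direct computation (no interpolation)
  ti2 <- ti_mdas(sino, ph0, geom, coarse_n = 100L, fine_n = 100L)
  expect_lt(max(abs(ti2$values - ref$values)) / max(abs(ref$values)), 1e-11)
})

test_that("SOS-corrected beamforming outperforms any uniform speed behind a lens", {
  geom <- ring_array()
  acq <- acq_params()
  g <- image_grid(40e-3, 100)
  # lens between the absorber and the bulk of the (bottom-heavy) array, so
  # most channels see heterogeneous delays; absorber on a pixel center
  ph <- disc_phantom(g, c(0, -5e-3), 14e-3, 1650, 1500)
  src <- c(0.2e-3, 6.2e-3)
  # heterogeneous arrivals from the true map (straight-ray travel times)
  el <- element_positions(geom)
  corner <- c(-20e-3, -20e-3)
  tau <- prbtomo:::cpp_tof_points(100L, 100L, g$spacing, corner[1], corner[2],
                                  1 / as.vector(ph$values), 1 / 1500, el,
                                  matrix(src, 1))[1, ]
  sino <- gaussian_pulse_sinogram(tau, acq)
  ti <- ti_mdas(sino, ph, geom, coarse_n = 50L, fine_n = 100L)
  best_uniform <- max(vapply(seq(1500, 1700, by = 25), function(v)
    max(das(sino, g, geom, v)$values), numeric(1)))
  expect_gt(max(ti$values), best_uniform)
})

test_that("reflecting the map and geometry reflects the TOF volume", {
  g <- image_grid(40e-3, 40)
  ph <- disc_phantom(g, c(3e-3, 5e-3), 10e-3, 1650, 1500)
  ph_r <- disc_phantom(g, c(3e-3, -5e-3), 10e-3, 1650, 1500)
  geom <- ring_array(n_elements = 6, gap_center_angle = 90)
  geom_r <- ring_array(n_elements = 6, gap_center_angle = -90)
  vol <- compute_tof_volume(ph, geom, g)
  vol_r <- compute_tof_volume(ph_r, geom_r, g)
  # element m of geom reflects to element (7-m) of geom_r; pixel (i, j)
  # reflects to (i, ny-1-j)
  Tm <- array(vol$times, c(40, 40, 6))
  Tr <- array(vol_r$times, c(40, 40, 6))
  for (m in 1:6) {
    expect_equal(Tm[, , m], Tr[, 40:1, 7 - m], tolerance = 1e-12)
  }
})
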