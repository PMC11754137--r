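#' Default experiment configuration
#'
#' Nested configuration for the end-to-end simulation campaign, mirroring
#' the reference system: 128-element 270-degree ring of radius 40.5 mm,
#' beacons scanned at 19 mm, 40 mm field of view on a 100 x 100 inversion
#' grid, 40 MHz sampling, 5 MHz beacon wavelets. Serializable to YAML with
#' [write_experiment_config()].
#'
#' @param phantom `"disc"` or `"four_region"`.
#' @param n_beacons vector of beacon counts to run (default `c(10, 20, 40, 80)`).
#' @param forward `"straight"` (inverse-crime recovery) or `"eikonal"`
#'   (refraction-aware first-arrival surrogate).
#' @param pick logical: synthesize sinograms and pick arrivals with the DP
#'   tracker (TRUE), or feed the forward TOFs directly to the inversion
#'   (FALSE, default).
#' @param seed integer seed for all stochastic stages.
#' @return a nested list of class `experiment_config`.
#' @export
default_experiment_config <- function(phantom = "disc",
                                      n_beacons = c(10, 20, 40, 80),
                                      forward = "straight",
                                      pick = FALSE, seed = 0L) {
  structure(list(
    geometry = list(n_elements = 128L, ring_radius_mm = 40.5,
                    arc_span_deg = 270, gap_center_deg = 90),
    scan = list(n_beacons = n_beacons, scan_radius_mm = 19,
                start_angle_deg = 0),
    grid = list(fov_mm = 40, n = 100L),
    acquisition = list(fs_hz = 40e6, n_samples = 2048L, t0_s = 0),
    phantom = list(type = phantom, center_mm = c(0, 0), diameter_mm = 16,
                   v_inside = 1650, v_background = 1500),
    forward = list(model = forward, solver_spacing_mm = 0.1),
    picking = list(enabled = isTRUE(pick), v_min = 1400, v_max = 1700,
                   margin = 32L, jump_limit = 3L, smoothness_weight = 1e-4,
                   refine = TRUE),
    waveform = list(center_frequency_hz = 5e6, beacon_amplitude = 10,
                    target_amplitude = 1, noise_sigma = 0),
    inversion = list(lambda_reg = NULL, max_iterations = 200L,
                     tolerance = 1e-10),
    seed = as.integer(seed)
  ), class = "experiment_config")
}

known_config_blocks <- c("geometry", "scan", "grid", "acquisition", "phantom",
                         "forward", "picking", "waveform", "inversion", "seed")

#' Validate an experiment configuration
#'
#' Checks block names against the known schema and basic value sanity;
#' unknown keys are rejected with a message naming them.
#'
#' @param cfg an experiment configuration list.
#' @return the validated config, invisibly.
#' @export
validate_experiment_config <- function(cfg) {
  extra <- setdiff(names(cfg), known_config_blocks)
  if (length(extra))
    stop("unknown configuration blocks: ", paste(extra, collapse = ", "))
  ref <- default_experiment_config()
  for (b in setdiff(known_config_blocks, "seed")) {
    if (is.null(cfg[[b]])) next
    bad <- setdiff(names(cfg[[b]]), names(ref[[b]]))
    if (length(bad))
      stop("unknown keys in block '", b, "': ", paste(bad, collapse = ", "))
  }
  stopifnot(all(cfg$scan$n_beacons >= 1), cfg$grid$fov_mm > 0, cfg$grid$n >= 1)
  invisible(cfg)
}

#' Read / write an experiment configuration as YAML
#'
#' @param cfg an experiment configuration list.
#' @param path YAML file path.
#' @return `write_experiment_config`: the path, invisibly;
#'   `read_experiment_config`: a validated `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_experiment_config()
  for (b in names(cfg)) {
    if (b == "seed") { base$seed <- as.integer(cfg$seed); next }
    for (k in names(cfg[[b]])) base[[b]][[k]] <- cfg[[b]][[k]]
  }
  validate_experiment_config(base)
  base
}

config_objects <- function(cfg) {
  list(geom = ring_array(cfg$geometry$n_elements,
                         cfg$geometry$ring_radius_mm * 1e-3,
                         cfg$geometry$arc_span_deg,
                         cfg$geometry$gap_center_deg),
       grid = image_grid(cfg$grid$fov_mm * 1e-3, cfg$grid$n),
       acq = acq_params(cfg$acquisition$fs_hz, cfg$acquisition$n_samples,
                        cfg$acquisition$t0_s))
}

config_phantom <- function(cfg, grid) {
  p <- cfg$phantom
  if (p$type == "disc") {
    disc_phantom(grid, p$center_mm * 1e-3, p$diameter_mm * 1e-3,
                 p$v_inside, p$v_background)
  } else if (p$type == "four_region") {
    four_region_phantom(grid)
  } else stop("unknown phantom type: ", p$type)
}

phantom_true_speeds <- function(sos) {
  sp <- attr(sos, "region_speeds")
  if (is.null(sp)) {
    sp <- c(target = max(sos$values), background = sos$background_speed)
  } else {
    sp <- c(sp, background = sos$background_speed)
  }
  sp
}

#' Simulate one beacon scan
#'
#' Computes beacon-to-element arrival times through the phantom with the
#' chosen forward model and (optionally) synthesizes the corresponding
#' beacon sinograms.
#'
#' @param sos an [sos_map()] phantom.
#' @param geom a [ring_array()].
#' @param scan a [beacon_scan()].
#' @param forward `"straight"` or `"eikonal"`.
#' @param op optional precomputed [build_path_operator()] (straight model).
#' @param solver_spacing eikonal solver spacing, meters.
#' @param synthesize logical; also generate sinograms.
#' @param spec a [waveform_spec()] (needed when `synthesize = TRUE`).
#' @param acq an [acq_params()] (needed when `synthesize = TRUE`).
#' @return list with `tof` (measured [tof_table()]) and `sinograms`
#'   (list of N [sinogram()]s or NULL).
#' @export
simulate_prb_scan <- function(sos, geom, scan, forward = "straight",
                              op = NULL, solver_spacing = 1e-4,
                              synthesize = FALSE, spec = NULL, acq = NULL) {
  tof <- if (forward == "straight") {
    if (is.null(op)) op <- build_path_operator(sos$grid, geom, scan)
    forward_tof_map(op, sos)
  } else if (forward == "eikonal") {
    eikonal_tof_table(sos, geom, scan, solver_spacing = solver_spacing)
  } else stop("unknown forward model: ", forward)
  sinos <- NULL
  if (synthesize) {
    stopifnot(inherits(spec, "waveform_spec"), inherits(acq, "acq_params"))
    sinos <- lapply(seq_len(scan$n_positions), function(n) {
      synthesize_beacon_sinogram(tof$values[n, ], spec, acq,
                                 beacon_index = n)
    })
  }
  list(tof = tof, sinograms = sinos)
}

#' Run a full SOS reconstruction experiment
#'
#' For each beacon count in the configuration: builds the phantom, computes
#' (or synthesizes and picks) beacon TOFs, subtracts the homogeneous
#' background, inverts for the slowness deficit, assembles the SOS map and
#' evaluates regional statistics. Fully deterministic for a fixed seed.
#' When `out_dir` is given, reconstructed maps (TIFF), TOF tables and a
#' metrics CSV are written there.
#'
#' @param cfg an `experiment_config` (see [default_experiment_config()]).
#' @param out_dir optional output directory.
#' @return a tibble of regional statistics with columns `n_beacons`,
#'   `region`, `n_pixels`, `mean`, `sd`, `true`, `percent_error`, plus the
#'   reconstructed maps in the `"maps"` attribute (one per beacon count).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  validate_experiment_config(cfg)
  obj <- config_objects(cfg)
  sos_true <- config_phantom(cfg, obj$grid)
  true_speeds <- phantom_true_speeds(sos_true)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  maps <- list()
  for (N in cfg$scan$n_beacons) {
    scan <- beacon_scan(N, cfg$scan$scan_radius_mm * 1e-3,
                        cfg$scan$start_angle_deg)
    op <- build_path_operator(obj$grid, obj$geom, scan)
    t_b <- background_tof(obj$geom, scan, cfg$phantom$v_background)
    if (cfg$picking$enabled) {
      spec <- waveform_spec(cfg$waveform$center_frequency_hz,
                            cfg$waveform$beacon_amplitude,
                            cfg$waveform$target_amplitude,
                            cfg$waveform$noise_sigma, cfg$seed)
      sim <- simulate_prb_scan(sos_true, obj$geom, scan,
                               forward = cfg$forward$model, op = op,
                               solver_spacing =
                                 cfg$forward$solver_spacing_mm * 1e-3,
                               synthesize = TRUE, spec = spec, acq = obj$acq)
      # background scan through the homogeneous medium, same wavelet and
      # picking pipeline, so the envelope-peak bias cancels in the delta
      bg_sinos <- lapply(seq_len(N), function(n) {
        synthesize_beacon_sinogram(t_b$values[n, ], spec, obj$acq,
                                   beacon_index = n + 100000L)
      })
      pk <- cfg$picking
      t_meas <- pick_tof_table(sim$sinograms, obj$geom, scan,
                               v_min = pk$v_min, v_max = pk$v_max,
                               margin = pk$margin, jump_limit = pk$jump_limit,
                               smoothness_weight = pk$smoothness_weight,
                               refine = pk$refine)
      t_bg <- pick_tof_table(bg_sinos, obj$geom, scan,
                             v_min = pk$v_min, v_max = pk$v_max,
                             margin = pk$margin, jump_limit = pk$jump_limit,
                             smoothness_weight = pk$smoothness_weight,
                             refine = pk$refine)
      dt <- delta_tof(t_meas, t_bg)
    } else {
      sim <- simulate_prb_scan(sos_true, obj$geom, scan,
                               forward = cfg$forward$model, op = op,
                               solver_spacing =
                                 cfg$forward$solver_spacing_mm * 1e-3)
      dt <- delta_tof(sim$tof, t_b)
    }
    icfg <- inversion_config(lambda_reg = cfg$inversion$lambda_reg,
                             max_iterations = cfg$inversion$max_iterations,
                             tolerance = cfg$inversion$tolerance)
    z <- solve_deficit(op, dt, icfg)
    sos_rec <- assemble_sos(z, cfg$phantom$v_background)
    st <- region_stats(sos_rec, sos_true$masks, true_speeds)
    st <- tibble::add_column(st, n_beacons = N, .before = 1)
    results[[as.character(N)]] <- st
    maps[[as.character(N)]] <- sos_rec
    if (!is.null(out_dir)) {
      write_sos_tiff(sos_rec, file.path(out_dir,
                                        sprintf("sos_N%03d.tiff", N)))
      export_tof_csv(dt, file.path(out_dir, sprintf("delta_tof_N%03d.csv", N)))
    }
  }
  out <- do.call(rbind, results)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "region_stats.csv"),
                     row.names = FALSE)
    write_experiment_config(cfg, file.path(out_dir, "config.yaml"))
  }
  attr(out, "maps") <- maps
  out
}
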