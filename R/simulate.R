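#' Vertical wind-shear profile
#'
#' Horizontal wind speed as a function of altitude, used by the flight
#' simulator: a power-law or logarithmic boundary-layer profile, or no wind.
#'
#' @param model `"logistic"` (thin shear layer, the default for dynamic
#'   soaring: calm near the surface, the full wind change concentrated over a
#'   few meters, as in classic feasibility analyses), `"power_law"`,
#'   `"logarithmic"` or `"none"`.
#' @param W_ref reference wind speed, m/s: the speed at `z_ref` for the
#'   power-law/logarithmic models, the asymptotic free-stream speed for the
#'   logistic model.
#' @param z_ref reference altitude, m.
#' @param exponent power-law exponent (power_law).
#' @param z0 roughness length, m (logarithmic).
#' @param z_center altitude of the logistic shear-layer midpoint, m.
#' @param thickness logistic shear-layer scale, m.
#' @param direction direction the wind blows toward, degrees from east.
#' @return object of class `wind_profile`.
#' @export
wind_profile <- function(model = c("logistic", "power_law", "logarithmic",
                                   "none"),
                         W_ref = 12, z_ref = 50, exponent = 0.14,
                         z0 = 0.03, z_center = 6, thickness = 1.5,
                         direction = 0) {
  model <- match.arg(model)
  structure(list(model = model, W_ref = W_ref, z_ref = z_ref,
                 exponent = exponent, z0 = z0, z_center = z_center,
                 thickness = thickness, direction = direction),
            class = "wind_profile")
}

#' Evaluate a wind profile at altitude z (m/s). Altitudes below 0.5 m use
#' the 0.5 m value (the simulator never flies there in normal operation).
#' @param profile a [wind_profile()].
#' @param z altitude, m (vectorised).
#' @return wind speed, m/s.
#' @export
wind_speed_at <- function(profile, z) {
  if (profile$model == "logistic")
    return(profile$W_ref /
             (1 + exp(-(z - profile$z_center) / profile$thickness)))
  z <- pmax(z, 0.5)
  switch(profile$model,
         none = rep(0, length(z)),
         power_law = profile$W_ref * (z / profile$z_ref)^profile$exponent,
         logarithmic = profile$W_ref * log(pmax(z, profile$z0 * 1.01) /
                                             profile$z0) /
           log(profile$z_ref / profile$z0))
}

cohort_polar <- function(cohort) {
  switch(cohort,
    soaring   = glide_polar(),  # albatross-like defaults
    flap_glide = glide_polar(mass = 0.85, wing_area = 0.12, CD0 = 0.037,
                             k_induced = 0.055),
    flapping  = glide_polar(mass = 0.55, wing_area = 0.09, CD0 = 0.045,
                            k_induced = 0.06))
}

#' Simulation configuration for one bird
#'
#' Bundles cohort, glide polar, wind profile, control-schedule and flap-model
#' parameters, sensor rates and noise levels. Defaults encode the three study
#' cohorts: a shear-soaring specialist flying energy-harvesting cycles with
#' occasional corrective flapping in weak wind, a mixed flap-glider with a
#' tamer cyclic schedule and prescribed flapping duty, and a continuously
#' flapping cruiser with no shear exploitation.
#'
#' @param cohort `"soaring"`, `"flap_glide"` or `"flapping"`.
#' @param duration simulated time, seconds.
#' @param polar a [glide_polar()]; cohort-specific default.
#' @param wind a [wind_profile()]; canonical shear for the soaring cohorts,
#'   none for the flapping cohort.
#' @param seed integer RNG seed, recorded in the output.
#' @param segment_length length of constant-condition segments, s; per
#'   segment the wind scale (soaring), flapping duty (flap_glide) or target
#'   speed (flap_glide, flapping) is redrawn to give each bird a range of
#'   flight conditions.
#' @param wind_scale_range,duty_range,target_speed_range per-segment draws.
#' @param ... overrides for any control/noise field (see the returned list).
#' @return object of class `sim_config` (a fully materialised list).
#' @export
sim_config <- function(cohort = c("soaring", "flap_glide", "flapping"),
                       duration = 7200, polar = NULL, wind = NULL,
                       seed = 1L, segment_length = 600,
                       wind_scale_range = c(0.25, 1.15),
                       duty_range = c(0.3, 0.45),
                       target_speed_range = NULL, ...) {
  cohort <- match.arg(cohort)
  if (is.null(polar)) polar <- cohort_polar(cohort)
  if (is.null(wind))
    wind <- if (cohort == "flapping") wind_profile("none") else wind_profile()
  if (is.null(target_speed_range))
    target_speed_range <- switch(cohort, soaring = c(15, 17),
                                 flap_glide = c(10, 15),
                                 flapping = c(11, 18))
  base <- switch(cohort,
    soaring = list(
      cycle_period = 7, psi_amp = 2.2, psi_mean = pi / 2, gamma_amp = 0.4,
      z_amp = 5.5,
      phi_max = 0.85, k_psi = 1.2, k_gamma = 3, CL_min = -0.3, CL_max = 1.5,
      z_mid = 9.5, z_half = 10, k_alt = 0.6, z_floor = 2, z_ceil = 45,
      assist_tau = 0.8, assist_z_on = 8, assist_z_off = 4,
      bout_period = 10, flap_freq = 3, c_flap = 0.25, k_v = 0.3,
      n_cap = 1.35,
      V_floor = 14.5, V_hi = 17.5, thrust_max = 2, V_init = 18, z_init = 4.5,
      psi_init = pi / 2 + 1.1),
    flap_glide = list(
      cycle_period = 8, psi_amp = 0.6, psi_mean = pi / 2, gamma_amp = 0.3,
      z_amp = 2,
      phi_max = 0.8, k_psi = 1.6, k_gamma = 3, CL_min = -0.3, CL_max = 1.5,
      z_mid = 5, z_half = 6, k_alt = 0.6, z_floor = 2.5, z_ceil = 45,
      assist_tau = 0, assist_z_on = 8, assist_z_off = 4,
      bout_period = 10, flap_freq = 4, c_flap = 0.25, k_v = 1,
      n_cap = 1.5,
      V_floor = 9.5, V_hi = 18.5, thrust_max = 5, V_init = 12, z_init = 5,
      psi_init = pi / 2),
    flapping = list(
      cycle_period = 6, psi_amp = 0, psi_mean = pi / 2, gamma_amp = 0,
      z_amp = 0,
      phi_max = 0.8, k_psi = 1.6, k_gamma = 3, CL_min = -0.3, CL_max = 1.6,
      z_mid = 20, z_half = 10, k_alt = 0.5, z_floor = 3.5, z_ceil = 60,
      assist_tau = 0, assist_z_on = 8, assist_z_off = 4,
      bout_period = 10, flap_freq = 6, c_flap = 0.25, k_v = 0.4,
      n_cap = 1.5,
      V_floor = 8, V_hi = 18.5, thrust_max = 6, V_init = 13, z_init = 20,
      psi_init = pi / 2))
  cfg <- c(list(cohort = cohort, duration = duration, polar = polar,
                wind = wind, seed = as.integer(seed),
                segment_length = segment_length,
                wind_scale_range = wind_scale_range,
                duty_range = duty_range,
                target_speed_range = target_speed_range,
                dt = 0.04, gps_rate = 1, accel_rate = 25,
                sigma_gps_h = 3, sigma_gps_v = 5, sigma_accel = 0.05,
                shear_coupling = cohort != "flapping"),
           base)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "sim_config")
}

# draw per-segment conditions and run the compiled core; partial = TRUE
# returns whatever was integrated before a ground strike (debug aid)
run_sim <- function(config, bird_id, lat0, lon0, t0 = 1735689600,
                    partial = FALSE) {
  set.seed(config$seed)
  n_seg <- max(1L, ceiling(config$duration / config$segment_length))
  seg_start <- (seq_len(n_seg) - 1) * config$segment_length
  seg_scale <- if (config$cohort == "soaring")
    runif(n_seg, config$wind_scale_range[1], config$wind_scale_range[2])
  else rep(1, n_seg)
  seg_Vt <- runif(n_seg, config$target_speed_range[1],
                  config$target_speed_range[2])
  seg_duty <- if (config$cohort == "flap_glide") {
    # flapping duty rises with the commanded cruise speed (faster
    # flap-gliding needs proportionally more powered bouts)
    frac <- (seg_Vt - config$target_speed_range[1]) /
      max(1e-9, diff(config$target_speed_range))
    pmin(pmax(config$duty_range[1] + frac * diff(config$duty_range) +
                runif(n_seg, -0.08, 0.08) * (diff(config$duty_range) > 0),
              min(0.05, config$duty_range[1])), 0.95)
  } else rep(0, n_seg)

  par <- list(
    mode = switch(config$cohort, soaring = 0L, flap_glide = 1L,
                  flapping = 2L),
    mass = config$polar$mass, wing_area = config$polar$wing_area,
    CD0 = config$polar$CD0, k_induced = config$polar$k_induced,
    rho = config$polar$rho, g = config$polar$g,
    wind_model = switch(config$wind$model, none = 0L, power_law = 1L,
                        logarithmic = 2L, logistic = 3L),
    W_ref = config$wind$W_ref, z_ref = config$wind$z_ref,
    exponent = config$wind$exponent, z0 = config$wind$z0,
    z_center = config$wind$z_center, thickness = config$wind$thickness,
    wind_dir = config$wind$direction * pi / 180,
    shear_coupling = isTRUE(config$shear_coupling),
    duration = config$duration, dt = config$dt,
    cycle_period = config$cycle_period, psi_amp = config$psi_amp,
    z_amp = config$z_amp,
    psi_mean = config$psi_mean, gamma_amp = config$gamma_amp,
    phi_max = config$phi_max, k_psi = config$k_psi,
    k_gamma = config$k_gamma, n_cap = config$n_cap, CL_min = config$CL_min,
    CL_max = config$CL_max, z_mid = config$z_mid, z_half = config$z_half,
    k_alt = config$k_alt, z_floor = config$z_floor, z_ceil = config$z_ceil,
    V_floor = config$V_floor, V_hi = config$V_hi,
    assist_tau = config$assist_tau,
    assist_z_on = config$assist_z_on, assist_z_off = config$assist_z_off,
    bout_period = config$bout_period, flap_freq = config$flap_freq,
    c_flap = config$c_flap, k_v = config$k_v,
    thrust_max = config$thrust_max,
    seg_start = seg_start, seg_wind_scale = seg_scale,
    seg_target_speed = seg_Vt, seg_duty = seg_duty,
    gps_rate = config$gps_rate, accel_rate = config$accel_rate,
    sigma_gps_h = config$sigma_gps_h, sigma_gps_v = config$sigma_gps_v,
    sigma_accel = config$sigma_accel,
    z_init = config$z_init, V_init = config$V_init,
    psi_init = config$psi_init)

  res <- .sim_core(par)
  if (res$status != 0L && partial) {
    tru <- res$truth[seq_len(max(res$n_gps, 1)), , drop = FALSE]
    truth <- as.data.frame(tru)
    names(truth) <- c("t", "x", "y", "z", "V", "u", "E", "P_wind",
                      "P_thrust", "P_drag", "cum_wind", "cum_thrust",
                      "cum_drag", "gamma", "psi", "phase", "phi", "CL")
    return(list(track = NULL, truth = truth, status = res$status))
  }
  if (res$status == 1L)
    stop("schedule infeasible for wind profile: simulated bird ", bird_id,
         " hit the ground")
  if (res$status == 2L)
    stop("simulator diverged for bird ", bird_id)

  gps <- res$gps[seq_len(res$n_gps), , drop = FALSE]
  acc <- res$accel[seq_len(res$n_accel), , drop = FALSE]
  tru <- res$truth[seq_len(res$n_gps), , drop = FALSE]
  R <- 6371000
  lat <- lat0 + gps[, 3] / R * 180 / pi
  lon <- lon0 + gps[, 2] / (R * cos(lat0 * pi / 180)) * 180 / pi
  fixes <- data.frame(t = t0 + gps[, 1], lat = lat, lon = lon,
                      alt = gps[, 4])
  accel <- data.frame(t = t0 + acc[, 1], ax = acc[, 2], ay = acc[, 3],
                      az = acc[, 4])
  truth <- as.data.frame(tru)
  names(truth) <- c("t", "x", "y", "z", "V", "u", "E", "P_wind", "P_thrust",
                    "P_drag", "cum_wind", "cum_thrust", "cum_drag",
                    "gamma", "psi", "phase", "phi", "CL")
  truth$t <- truth$t + t0
  list(track = bird_track(bird_id, config$cohort, fixes, accel),
       truth = truth, seed = config$seed)
}

#' Simulate a dynamic-soaring bird
#'
#' Integrates 3-DOF point-mass flight dynamics (RK4, fixed step <= 0.05 s)
#' through vertically sheared wind under a closed-loop cyclic schedule that
#' climbs into the wind and descends downwind, the canonical shear-harvesting
#' cycle. Weak-wind segments trigger bouts of corrective flapping via a
#' slow altitude-hold assist. Emits noisy 1-Hz GPS fixes, 25-Hz body-frame
#' specific-force accelerometry, and an exact per-sample power bookkeeping
#' (`truth`): dE/dt = P_wind + P_thrust - P_drag holds to integrator
#' tolerance, making the energy-budget inference testable against ground
#' truth.
#'
#' @param config a [sim_config()] with `cohort = "soaring"`; a `"none"` wind
#'   profile is allowed for zero-wind drag audits (the glider then simply
#'   descends).
#' @param bird_id identifier for the generated track.
#' @param lat0,lon0 geographic anchor of the local simulation frame.
#' @return list with `track` (a [bird_track()]), `truth` (data.frame with
#'   true states, power terms and their cumulative integrals at the GPS
#'   rate) and `seed`.
#' @export
simulate_soaring <- function(config = sim_config("soaring"),
                             bird_id = "soar01", lat0 = -46, lon0 = 51) {
  stopifnot(config$cohort == "soaring")
  run_sim(config, bird_id, lat0, lon0)
}

#' Simulate a flap-gliding bird
#'
#' Alternates gliding (a tamer version of the soaring schedule, weaker shear
#' use) with flapping bouts at a prescribed duty cycle during which thrust
#' slightly exceeds drag and the accelerometer gains a wingbeat-frequency
#' dynamic component with amplitude proportional to mass-specific flapping
#' power.
#'
#' @inheritParams simulate_soaring
#' @export
simulate_flap_glide <- function(config = sim_config("flap_glide"),
                                bird_id = "fgl01", lat0 = 38, lon0 = -28) {
  stopifnot(config$cohort == "flap_glide")
  run_sim(config, bird_id, lat0, lon0)
}

#' Simulate a continuously flapping bird
#'
#' Level cruise at a commanded airspeed with continuous thrust balancing
#' drag and a continuous wingbeat signal in the accelerometer; wind (if any)
#' advects the bird but the shear-gradient coupling is disabled, so no
#' energy can be harvested.
#'
#' @inheritParams simulate_soaring
#' @export
simulate_flapping <- function(config = sim_config("flapping"),
                              bird_id = "flp01", lat0 = 53.5, lon0 = 5.5) {
  stopifnot(config$cohort == "flapping")
  run_sim(config, bird_id, lat0, lon0)
}

#' Generate a three-cohort synthetic study on disk
#'
#' Simulates `n_per_cohort` birds for each cohort (soaring, flap-gliding,
#' continuously flapping), writes Movebank-style per-bird GPS and
#' accelerometer CSVs readable by [read_tracks()] with the packaged reader
#' config, a `manifest.json` (bird ids, cohorts, per-bird seeds), and a
#' `truth.json` bundle with each bird's true cumulative wind, thrust and
#' drag work and energy-closure residual. Per-bird seeds derive
#' deterministically from `master_seed`, so the same seed reproduces the
#' files byte for byte.
#'
#' @param dir output directory.
#' @param n_per_cohort birds per cohort (default 5).
#' @param duration seconds of flight per bird (default 7200, i.e. 2 h).
#' @param master_seed integer master seed.
#' @return invisibly, a list with `tracks`, `truths`, `manifest`.
#' @export
make_cohort_study <- function(dir, n_per_cohort = 5, duration = 7200,
                              master_seed = 1L) {
  stopifnot(n_per_cohort >= 1)
  set.seed(master_seed)
  cohorts <- c("soaring", "flap_glide", "flapping")
  prefix <- c(soaring = "alb", flap_glide = "shw", flapping = "oyc")
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 3 * n_per_cohort),
                  nrow = 3, dimnames = list(cohorts, NULL))
  tracks <- list(); truths <- list(); rows <- list()
  for (ch in cohorts) {
    for (i in seq_len(n_per_cohort)) {
      id <- sprintf("%s%02d", prefix[[ch]], i)
      cfg <- sim_config(ch, duration = duration, seed = seeds[ch, i])
      sim <- run_sim(cfg, id,
                     lat0 = switch(ch, soaring = -46, flap_glide = 38,
                                   flapping = 53.5),
                     lon0 = switch(ch, soaring = 51, flap_glide = -28,
                                   flapping = 5.5))
      tracks[[id]] <- sim$track
      tr <- sim$truth
      n <- nrow(tr)
      closure <- (tr$E[n] - tr$E[1]) -
        (tr$cum_wind[n] + tr$cum_thrust[n] - tr$cum_drag[n])
      truths[[id]] <- list(
        bird_id = id, cohort = ch, seed = seeds[ch, i],
        cum_wind = tr$cum_wind[n], cum_thrust = tr$cum_thrust[n],
        cum_drag = tr$cum_drag[n], E_start = tr$E[1], E_end = tr$E[n],
        closure_residual = closure)
      rows[[id]] <- data.frame(bird_id = id, cohort = ch,
                               seed = seeds[ch, i])
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks(tracks, dir)
  manifest <- list(birds = do.call(rbind, c(rows, make.row.names = FALSE)),
                   n_per_cohort = n_per_cohort, duration = duration,
                   master_seed = master_seed,
                   created_by = paste0("dynsoar ",
                                       as.character(utils::packageVersion("dynsoar"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truths, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tracks = tracks, truths = truths, manifest = manifest))
}
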