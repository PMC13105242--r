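test_that("wind profiles have the right shapes", {
  lgs <- wind_profile("logistic", W_ref = 12, z_center = 6, thickness = 1.5)
  expect_lt(wind_speed_at(lgs, 0), 0.25)              # calm at the surface
  expect_equal(wind_speed_at(lgs, 6), 6)              # half speed mid-layer
  expect_equal(wind_speed_at(lgs, 40), 12, tolerance = 1e-6)
  pl <- wind_profile("power_law", W_ref = 12, z_ref = 50, exponent = 0.14)
  expect_equal(wind_speed_at(pl, 50), 12)
  z <- seq(1, 60, by = 0.5)
  for (p in list(lgs, pl, wind_profile("logarithmic")))
    expect_true(all(diff(wind_speed_at(p, z)) >= 0))  # monotone in z
  expect_equal(wind_speed_at(wind_profile("none"), z), rep(0, length(z)))
})

test_that("same seed gives bit-identical simulator output", {
  a <- simulate_soaring(sim_config("soaring", duration = 300, seed = 11))
  b <- simulate_soaring(sim_config("soaring", duration = 300, seed = 11))
  expect_identical(a$track$fixes, b$track$fixes)
  expect_identical(a$track$accel, b$track$accel)
  expect_identical(a$truth, b$truth)
  c <- simulate_soaring(sim_config("soaring", duration = 300, seed = 12))
  expect_false(identical(a$track$fixes, c$track$fixes))
})

test_that("zero-wind zero-thrust flight loses energy at the drag rate", {
  cfg <- sim_config("soaring", duration = 150, seed = 5,
                    segment_length = 150, wind = wind_profile("none"),
                    assist_tau = 0, psi_amp = 0, sigma_gps_h = 0,
                    sigma_gps_v = 0, sigma_accel = 0, V_init = 16,
                    z_init = 130, z_mid = 120, z_ceil = 150,
                    gamma_amp = 0.3)
  expect_error(sim <- simulate_soaring(cfg), NA)
  tt <- sim$truth
  expect_true(all(diff(tt$E) < 0))                    # strictly decreasing
  n <- nrow(tt)
  drop <- tt$E[n] - tt$E[1]
  expect_equal(drop, -(tt$cum_drag[n] - tt$cum_drag[1]),
               tolerance = 0.01 * abs(drop))
  expect_equal(max(abs(tt$cum_wind)), 0)
})

test_that("the default shear schedule sustains energy-neutral cycles", {
  cfg <- sim_config("soaring", duration = 420, seed = 5,
                    segment_length = 420, wind_scale_range = c(1, 1),
                    sigma_gps_h = 0, sigma_gps_v = 0, sigma_accel = 0,
                    assist_tau = 0)
  sim <- simulate_soaring(cfg)
  tt <- sim$truth
  expect_true(all(tt$z > 1.9 & tt$z < 60))            # working band held
  # cycle boundaries: dive-to-climb transitions of the control phase
  starts <- which(diff(tt$phase) == -1) + 1
  k <- length(starts)
  expect_gte(k, 20)
  E0 <- tt$E[starts]
  # at least one stretch of 10 consecutive cycles with non-negative
  # cycle-averaged dE/dt, and no secular decay over the whole run
  gains10 <- E0[11:k] - E0[1:(k - 10)]
  expect_true(any(gains10 >= 0))
  expect_gt(mean(E0[(k - 9):k]), 0.9 * mean(E0[1:10]))
})

test_that("simulator energy bookkeeping closes for every cohort", {
  for (ch in c("soaring", "flap_glide", "flapping")) {
    sim <- sim_quiet(ch, duration = 600, seed = 8)
    tt <- sim$truth
    n <- nrow(tt)
    resid <- (tt$E[n] - tt$E[1]) -
      (tt$cum_wind[n] + tt$cum_thrust[n] - tt$cum_drag[n])
    expect_lt(abs(resid) / max(1, tt$cum_drag[n]), 0.01)
  }
})

test_that("flap-gliding interpolates between gliding and flapping", {
  # high-altitude start: the duty-0 limit is an unpowered descending glide
  glide <- sim_quiet("flap_glide", duration = 120, seed = 6,
                     duty_range = c(0, 0), sigma_accel = 0.05, V_floor = 0,
                     z_init = 160, z_mid = 160, z_ceil = 220)
  flap <- sim_quiet("flap_glide", duration = 120, seed = 6,
                    duty_range = c(1, 1), sigma_accel = 0.05, V_floor = 0,
                    z_init = 160, z_mid = 160, z_ceil = 220)
  # duty 0 means no thrust: energy can only come from wind and gravity
  expect_equal(max(glide$truth$cum_thrust), 0)
  expect_gt(max(flap$truth$cum_thrust), 0)
  mv <- function(s) mean(vedba(s$track$accel, 2)$vedba)
  expect_gte(mv(flap), 3 * mv(glide))
})

test_that("continuous flappers cruise level at the commanded speed", {
  cfg <- sim_config("flapping", duration = 400, seed = 4,
                    segment_length = 400, target_speed_range = c(13, 13),
                    sigma_gps_h = 0, sigma_gps_v = 0, sigma_accel = 0.05)
  sim <- simulate_flapping(cfg)
  tt <- sim$truth
  settled <- tt[tt$t - tt$t[1] > 30, ]
  expect_true(all(abs(settled$u - 13) < 0.1))
  # specific-energy fluctuation within any 120-s window stays small
  tr <- derive_ground_speed(sim$track)
  w <- make_windows(tr, 120, 60)
  for (i in seq_len(nrow(w))) {
    eb <- energy_budget(w[i, ], tr)
    expect_lt(max(abs(eb$deltaE)), 2)
  }
})

test_that("flappers work harder than soarers on the effort proxy", {
  soar <- sim_quiet("soaring", duration = 400, seed = 6,
                    sigma_accel = 0.05)
  flap <- sim_quiet("flapping", duration = 400, seed = 6,
                    sigma_accel = 0.05)
  expect_gt(mean(vedba(flap$track$accel, 2)$vedba),
            mean(vedba(soar$track$accel, 2)$vedba))
})

test_that("make_cohort_study writes a complete, reproducible study", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  st <- make_cohort_study(d1, n_per_cohort = 2, duration = 600,
                          master_seed = 99)
  expect_length(Sys.glob(file.path(d1, "tracks", "*_gps.csv")), 6)
  expect_length(Sys.glob(file.path(d1, "accel", "*_acc.csv")), 6)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "truth.json")))
  # reading back reproduces the fix counts exactly
  tracks <- read_tracks(d1, reader_config())
  expect_length(tracks, 6)
  for (id in names(st$tracks))
    expect_equal(nrow(tracks[[id]]$fixes), nrow(st$tracks[[id]]$fixes))
  # determinism: same master seed twice gives hash-identical files
  make_cohort_study(d2, n_per_cohort = 2, duration = 600, master_seed = 99)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
})

test_that("an infeasible schedule reports a ground strike", {
  cfg <- sim_config("soaring", duration = 300, seed = 1,
                    segment_length = 300, wind_scale_range = c(0.01, 0.01),
                    assist_tau = 0)
  expect_error(simulate_soaring(cfg), "infeasible")
})
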