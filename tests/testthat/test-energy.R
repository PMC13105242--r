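test_that("specific and relative energy follow their definitions", {
  expect_equal(specific_energy(10, 0), 50)
  expect_equal(specific_energy(0, 100), 981)
  expect_equal(specific_energy(20, 10), 298.1)
  expect_error(specific_energy(-1, 0), "non-negative")

  expect_equal(relative_energy(c(7, 7, 7)), c(0, 0, 0))
  expect_equal(relative_energy(c(50, 60, 45)), c(0, 10, -5))
  ramp <- 3 * (0:10)
  expect_equal(relative_energy(100 + ramp), ramp)
  expect_error(relative_energy(numeric(0)), "empty")
})

test_that("drag power at best glide matches the closed form", {
  # closed-form polar algebra: p(V*) = g * V* / (L/D)max, checked for the
  # default polar and an alternative parameter set
  for (polar in list(glide_polar(),
                     glide_polar(CD0 = 0.033, k_induced = 0.05))) {
    Vstar <- best_glide_speed(polar)
    LDmax <- 1 / (2 * sqrt(polar$k_induced * polar$CD0))
    expect_equal(drag_power(Vstar, polar), polar$g * Vstar / LDmax,
                 tolerance = 1e-12)
    # cross-check against a numerical minimum of D(V)/ (m g) (max L/D at V*)
    Vgrid <- seq(5, 40, by = 0.001)
    Vnum <- Vgrid[which.min(drag_force(Vgrid, polar))]
    expect_equal(Vnum, Vstar, tolerance = 2e-3)
  }
})

test_that("cumulative drag work scales, clamps and stays non-increasing", {
  polar <- glide_polar()
  t1 <- 0:100; t2 <- 0:200
  u <- 15
  w1 <- drag_work(t1, rep(u, 101), polar)
  w2 <- drag_work(t2, rep(u, 201), polar)
  expect_equal(tail(w2, 1), 2 * tail(w1, 1), tolerance = 1e-12)
  expect_true(all(diff(w1) <= 0))
  expect_lte(max(w1), 0)
  # stall clamp: speeds below v_min evaluate the polar at v_min
  slow <- drag_work(0:10, rep(1, 11), polar, v_min = 5)
  ref <- drag_work(0:10, rep(5, 11), polar, v_min = 5)
  expect_equal(slow, ref)
  # random irregular samplings stay non-increasing
  set.seed(3)
  for (i in 1:10) {
    tt <- cumsum(runif(50, 0.2, 3))
    uu <- runif(50, 2, 30)
    expect_true(all(diff(drag_work(tt, uu, polar)) <= 0))
  }
})

test_that("harvest work is the defining elementwise difference", {
  expect_equal(harvest_work(5, -12), 17)
  dE <- c(0, 3, -2)
  expect_equal(harvest_work(dE, rep(0, 3)), dE)
  expect_equal(harvest_work(rep(0, 3), c(0, -10, -30))[3], 30)
  expect_error(harvest_work(1:3, 1:2), "equal length")
})

test_that("energy budget identity holds at every sample of every window", {
  sim <- sim_quiet("soaring", duration = 600)
  tr <- derive_ground_speed(sim$track)
  w <- make_windows(tr, 120, 60)
  for (i in seq_len(nrow(w))) {
    eb <- energy_budget(w[i, ], tr)
    expect_equal(eb$deltaE[1], 0)
    expect_true(all(diff(eb$W_drag) <= 0))
    resid <- abs(eb$W_harvest - (eb$deltaE - eb$W_drag))
    expect_lt(max(resid / pmax(abs(eb$deltaE), 1)), 1e-9)
  }
})

test_that("in calm air the drag model explains the glider's energy loss", {
  # zero wind, zero thrust, straight trimmed descent: the inferred
  # atmospheric input should be near zero when the drag model matches the
  # simulator's polar
  cfg <- sim_config("soaring", duration = 130, seed = 5,
                    segment_length = 130, wind = wind_profile("none"),
                    assist_tau = 0, psi_amp = 0, sigma_gps_h = 0,
                    sigma_gps_v = 0, sigma_accel = 0, V_init = 16,
                    z_init = 110, z_mid = 100, z_ceil = 130,
                    gamma_amp = 0.3)
  sim <- dynsoar:::run_sim(cfg, "calm", 0, 0)
  tr <- derive_ground_speed(sim$track)
  w <- make_windows(tr, 120, 60)
  expect_gte(nrow(w), 1)
  for (i in seq_len(nrow(w))) {
    eb <- energy_budget(w[i, ], tr)
    n <- nrow(eb)
    expect_lt(abs(eb$W_harvest[n]), 0.05 * abs(eb$W_drag[n]))
  }
})

test_that("in shear the inferred harvest tracks the true wind work", {
  # moderate shear (the approximation airspeed ~ ground speed biases the
  # estimate increasingly as wind approaches airspeed)
  sim <- sim_quiet("soaring", duration = 720, scale = 0.8)
  tr <- derive_ground_speed(sim$track)
  w <- make_windows(tr, 120, 60)
  tt <- sim$truth
  for (i in seq_len(nrow(w))) {
    eb <- energy_budget(w[i, ], tr)
    n <- nrow(eb)
    i0 <- which.min(abs(tt$t - w$t_start[i]))
    i1 <- which.min(abs(tt$t - w$t_end[i]))
    true_wind <- tt$cum_wind[i1] - tt$cum_wind[i0]
    expect_gt(eb$W_harvest[n], 0)
    expect_lt(abs(eb$W_harvest[n] - true_wind) / true_wind, 0.15)
  }
})
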