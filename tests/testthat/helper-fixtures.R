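# Small in-code fixtures shared across the suite.

# straight-line track at constant ground speed (m/s) heading east at the
# equator, 1 Hz; altitude optionally ramped at climb_rate m/s
make_straight_track <- function(n = 301, speed = 10, climb_rate = 0,
                                bird_id = "b1", cohort = "other",
                                lat0 = 0, lon0 = 0, alt0 = 10) {
  t <- as.numeric(seq(0, n - 1))
  R <- 6371000
  lon <- lon0 + (speed * t) / (R * cos(lat0 * pi / 180)) * 180 / pi
  bird_track(bird_id, cohort,
             data.frame(t = t, lat = lat0, lon = lon,
                        alt = alt0 + climb_rate * t))
}

# track standing still (for zero-speed checks)
make_stationary_track <- function(n = 200) {
  bird_track("still", "other",
             data.frame(t = as.numeric(seq_len(n) - 1), lat = 10, lon = 20,
                        alt = 50))
}

# accelerometer series at rate Hz for dur seconds, given axis functions
make_accel <- function(dur = 60, rate = 100, fx = function(t) 0 * t,
                       fy = function(t) 0 * t, fz = function(t) 9.81 + 0 * t) {
  t <- seq(0, dur, by = 1 / rate)
  data.frame(t = t, ax = fx(t), ay = fy(t), az = fz(t))
}

# independent haversine oracle, written directly from the formula
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# window-metrics table with prescribed speed/effort columns for one bird
fake_metrics <- function(v_net, mean_vedba, bird_id = "b1",
                         cohort = "soaring") {
  n <- length(v_net)
  data.frame(bird_id = bird_id, cohort = cohort,
             t_start = seq_len(n) * 60, t_end = seq_len(n) * 60 + 120,
             v_net = v_net, mean_vedba = mean_vedba,
             n_fixes = 121, gap_fraction = 0)
}

# quiet wrapper: simulate one bird of a cohort with fixed conditions and no
# sensor noise (used by energy/simulator tests)
sim_quiet <- function(cohort = "soaring", duration = 720, seed = 5,
                      scale = 1, ...) {
  cfg <- sim_config(cohort, duration = duration, seed = seed,
                    segment_length = duration,
                    wind_scale_range = c(scale, scale),
                    sigma_gps_h = 0, sigma_gps_v = 0, sigma_accel = 0,
                    assist_tau = 0, ...)
  dynsoar:::run_sim(cfg, paste0(cohort, seed), 0, 0)
}
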