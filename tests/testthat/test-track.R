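test_that("bird_track enforces its invariants", {
  fx <- data.frame(t = 1:3, lat = 0, lon = 0, alt = 0)
  expect_s3_class(bird_track("b", "soaring", fx), "bird_track")
  expect_error(bird_track("b", "soaring", fx[0, ]), "non-empty")
  expect_error(bird_track("b", "soaring",
                          data.frame(t = c(1, 1, 2), lat = 0, lon = 0,
                                     alt = 0)), "strictly increasing")
  expect_error(bird_track("b", "soaring",
                          data.frame(t = 1:2, lat = c(0, 95), lon = 0,
                                     alt = 0)), "out of range")
})

test_that("read_tracks parses, drops bad rows and splits by bird", {
  cfg <- reader_config(timestamp = "ts", lat = "lat", lon = "lon",
                       alt = "alt", bird_id = "id")
  f <- withr::local_tempfile(fileext = ".csv")
  # interleaved birds, one bad latitude row
  df <- data.frame(ts = c(3, 1, 2, 2, 1, 4),
                   id = c("a", "b", "a", "b", "a", "a"),
                   lat = c(10, 20, 10, 95, 10, 10),
                   lon = c(5, 6, 5, 6, 5, 5), alt = 0)
  write.csv(df, f, row.names = FALSE)
  tr <- read_tracks(f, cfg)
  expect_length(tr, 2)
  # time-sorted per bird (sort-then-group oracle on the same rows)
  expect_equal(tr[["a"]]$fixes$t, sort(df$ts[df$id == "a" & df$lat <= 90]))
  expect_equal(tr[["b"]]$fixes$t, 1)  # bad row dropped
  rep <- attr(tr, "drop_report")
  expect_equal(rep[["b"]]$n_dropped, 1)
  expect_equal(rep[["a"]]$n_dropped, 0)
})

test_that("read_tracks errors on missing mandatory columns, warns on empty", {
  cfg <- reader_config(timestamp = "ts", lat = "lat", lon = "lon",
                       alt = "alt", bird_id = "id")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ts = 1, lat = 0, lon = 0), f, row.names = FALSE)
  expect_error(read_tracks(f, cfg), "alt")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("ts,id,lat,lon,alt", f2)
  expect_warning(tr <- read_tracks(f2, cfg), "empty")
  expect_length(tr, 0)
})

test_that("write_tracks/read_tracks round-trips the retained fields", {
  tr <- make_straight_track(n = 50, speed = 12, climb_rate = 0.25,
                            bird_id = "rt01", cohort = "soaring")
  # values with short decimal forms survive the CSV round trip exactly
  tr$fixes$lat <- round(tr$fixes$lat, 6)
  tr$fixes$lon <- round(tr$fixes$lon, 6)
  tr$fixes$alt <- round(tr$fixes$alt, 3)
  tr$accel <- make_accel(20, 25,
                         fz = function(t) round(9.81 + 0.3 * sin(t), 4))
  d <- withr::local_tempdir()
  write_tracks(list(tr), d)
  back <- read_tracks(d, reader_config())
  expect_length(back, 1)
  b <- back[["rt01"]]
  expect_identical(b$fixes$t, tr$fixes$t)
  expect_identical(b$fixes$lat, tr$fixes$lat)
  expect_identical(b$fixes$lon, tr$fixes$lon)
  expect_identical(b$fixes$alt, tr$fixes$alt)
  expect_identical(b$cohort, "soaring")
  expect_identical(b$accel$az, tr$accel$az)
})

test_that("geodesic_distance matches the haversine closed form", {
  # 0.001 degree of latitude at the equator is about 111.19 m
  expect_equal(geodesic_distance(0, 0, 0.001, 0), 111.19, tolerance = 5e-4)
  expect_equal(geodesic_distance(10, 20, 10, 20), 0)
  set.seed(42)
  lat1 <- runif(1000, -80, 80); lon1 <- runif(1000, -179, 179)
  lat2 <- lat1 + runif(1000, -0.5, 0.5); lon2 <- lon1 + runif(1000, -0.5, 0.5)
  d1 <- geodesic_distance(lat1, lon1, lat2, lon2)
  d2 <- haversine_oracle(lat1, lon1, lat2, lon2)
  expect_equal(d1, d2, tolerance = 1e-6)
  # symmetry
  expect_equal(d1[1:100], geodesic_distance(lat2, lon2, lat1, lon1)[1:100])
})

test_that("derive_ground_speed fills 3-D finite-difference speeds", {
  tr <- derive_ground_speed(make_straight_track(n = 100, speed = 10))
  expect_true(all(abs(tr$fixes$ground_speed - 10) < 0.01))
  still <- derive_ground_speed(make_stationary_track())
  expect_true(all(still$fixes$ground_speed == 0))
  # pure vertical climb at 2 m/s
  climb <- bird_track("c", "other",
                      data.frame(t = 0:60, lat = 45, lon = 7,
                                 alt = 100 + 2 * (0:60)))
  climb <- derive_ground_speed(climb)
  expect_true(all(abs(climb$fixes$ground_speed - 2) < 0.01))
  # provided speeds are kept
  fx <- make_straight_track(n = 10)$fixes
  fx$ground_speed <- 99
  kept <- derive_ground_speed(bird_track("k", "other", fx))
  expect_true(all(kept$fixes$ground_speed == 99))
})

test_that("duplicate timestamps are a hard error naming the bird", {
  fx <- data.frame(t = c(0, 1, 1 + 1e-12, 2), lat = 0, lon = 0, alt = 0)
  tr <- bird_track("dup01", "other", fx)
  tr$fixes$t <- c(0, 1, 1, 2)  # force exact duplicate past the constructor
  expect_error(derive_ground_speed(tr), "dup01")
})

test_that("ground speed matches a generated constant-velocity track to 0.1%", {
  for (v in c(5, 12, 21)) {
    tr <- derive_ground_speed(make_straight_track(n = 200, speed = v))
    interior <- tr$fixes$ground_speed[2:199]
    expect_true(all(abs(interior - v) / v < 1e-3))
  }
})
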