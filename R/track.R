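#' Construct a bird track
#'
#' A `bird_track` carries one animal's GPS fixes and (optionally) its
#' tri-axial accelerometer series, together with a cohort tag used for the
#' cross-group comparison (soaring specialists, mixed flap-gliders,
#' continuous flappers).
#'
#' @param bird_id character scalar identifier.
#' @param cohort one of `"soaring"`, `"flap_glide"`, `"flapping"`, `"other"`.
#' @param fixes data.frame with columns `t` (seconds, strictly increasing),
#'   `lat`, `lon` (degrees), `alt` (m) and optionally `ground_speed` (m/s).
#' @param accel optional data.frame with columns `t`, `ax`, `ay`, `az`
#'   (m/s^2, `t` non-decreasing).
#' @return object of class `bird_track`.
#' @export
bird_track <- function(bird_id, cohort = "other", fixes, accel = NULL) {
  cohort <- match.arg(cohort, c("soaring", "flap_glide", "flapping", "other"))
  stopifnot(is.character(bird_id), length(bird_id) == 1L)
  fixes <- as.data.frame(fixes)
  req <- c("t", "lat", "lon", "alt")
  if (!all(req %in% names(fixes)))
    stop("fixes must have columns ", paste(req, collapse = ", "))
  if (nrow(fixes) == 0L) stop("bird_track requires non-empty fixes")
  if (any(diff(fixes$t) <= 0))
    stop("fix timestamps must be strictly increasing for bird ", bird_id)
  if (any(fixes$lat < -90 | fixes$lat > 90) ||
      any(fixes$lon < -180 | fixes$lon > 180))
    stop("fix coordinates out of range for bird ", bird_id)
  if (!"ground_speed" %in% names(fixes)) fixes$ground_speed <- NA_real_
  if (!is.null(accel)) {
    accel <- as.data.frame(accel)
    if (!all(c("t", "ax", "ay", "az") %in% names(accel)))
      stop("accel must have columns t, ax, ay, az")
    if (nrow(accel) && any(diff(accel$t) < 0))
      stop("accel timestamps must be non-decreasing for bird ", bird_id)
  }
  structure(list(bird_id = bird_id, cohort = cohort,
                 fixes = fixes, accel = accel),
            class = "bird_track")
}

#' @export
print.bird_track <- function(x, ...) {
  span <- diff(range(x$fixes$t))
  cat("<bird_track>", x$bird_id, sprintf("[%s]", x$cohort), "\n",
      " ", nrow(x$fixes), "fixes over", round(span, 1), "s;",
      if (is.null(x$accel)) "no accel" else
        paste(nrow(x$accel), "accel samples"), "\n")
  invisible(x)
}

#' Reader configuration for Movebank-style CSV
#'
#' Maps the columns of a tracking CSV onto the fields this package expects
#' and declares the accelerometer unit. A YAML file with the same keys can be
#' loaded with `read_reader_config()`; a ready-made config matching the
#' synthetic study layout ships in `inst/extdata/reader_config.yaml`.
#'
#' @param timestamp,lat,lon,alt,bird_id required column names.
#' @param speed,cohort optional column names (`NULL` if absent).
#' @param accel_t,accel_x,accel_y,accel_z accel column names (accel files).
#' @param accel_unit `"ms2"` or `"g"`; g-units are converted at 9.81 m/s^2.
#' @param gps_pattern,accel_pattern glob patterns pairing per-bird GPS and
#'   accel files when reading a directory.
#' @return object of class `reader_config`.
#' @export
reader_config <- function(timestamp = "timestamp", lat = "location_lat",
                          lon = "location_long", alt = "height_above_msl",
                          bird_id = "individual_local_identifier",
                          speed = NULL, cohort = "cohort",
                          accel_t = "timestamp", accel_x = "acc_x",
                          accel_y = "acc_y", accel_z = "acc_z",
                          accel_unit = c("ms2", "g"),
                          gps_pattern = "*_gps.csv",
                          accel_pattern = "*_acc.csv") {
  accel_unit <- match.arg(accel_unit)
  structure(list(timestamp = timestamp, lat = lat, lon = lon, alt = alt,
                 bird_id = bird_id, speed = speed, cohort = cohort,
                 accel_t = accel_t, accel_x = accel_x, accel_y = accel_y,
                 accel_z = accel_z, accel_unit = accel_unit,
                 gps_pattern = gps_pattern, accel_pattern = accel_pattern),
            class = "reader_config")
}

#' Load a reader configuration from YAML
#' @param path YAML file whose keys match the arguments of [reader_config()].
#' @return a `reader_config`.
#' @export
read_reader_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(reader_config, y)
}

parse_timestamps <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- is.na(t)
  if (any(bad))
    t[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  as.numeric(t)
}

#' Read Movebank-style tracks
#'
#' Reads one CSV file, or a study directory of per-bird GPS (and optional
#' accelerometer) CSVs, into a list of [bird_track()] objects. Rows with
#' unparseable timestamps or out-of-range coordinates are dropped and counted
#' in a drop report attached as attribute `"drop_report"`.
#'
#' @param path a CSV file or a directory. A directory is scanned with the
#'   config's `gps_pattern`/`accel_pattern`; a `manifest.json` written by
#'   [make_cohort_study()] supplies cohort labels if present.
#' @param config a [reader_config()].
#' @return list of `bird_track`, one per distinct bird id, each time-sorted;
#'   attribute `"drop_report"` is a list with per-bird dropped-row counts.
#' @export
read_tracks <- function(path, config = reader_config()) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (dir.exists(path)) return(read_track_dir(path, config))
  read_track_csv(path, config)
}

read_track_csv <- function(path, config, accel_by_bird = list(),
                           cohort_map = character()) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  if (nrow(df) == 0L) {
    warning("empty track file: ", path)
    out <- list()
    attr(out, "drop_report") <- list()
    return(out)
  }
  need <- c(timestamp = config$timestamp, lat = config$lat,
            lon = config$lon, alt = config$alt, bird_id = config$bird_id)
  miss <- need[!need %in% names(df)]
  if (length(miss))
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  t <- parse_timestamps(df[[config$timestamp]])
  lat <- as.numeric(df[[config$lat]])
  lon <- as.numeric(df[[config$lon]])
  alt <- as.numeric(df[[config$alt]])
  speed <- if (!is.null(config$speed) && config$speed %in% names(df))
    as.numeric(df[[config$speed]]) else rep(NA_real_, nrow(df))
  ids <- as.character(df[[config$bird_id]])
  cohorts <- if (!is.null(config$cohort) && config$cohort %in% names(df))
    as.character(df[[config$cohort]]) else rep(NA_character_, nrow(df))

  ok <- !is.na(t) & !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  drop_report <- list()
  tracks <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    n_drop <- sum(sel & !ok)
    keep <- which(sel & ok)
    keep <- keep[order(t[keep])]
    drop_report[[id]] <- list(n_dropped = n_drop, n_kept = length(keep))
    if (!length(keep)) next
    cohort <- cohort_map[id]
    if (is.na(cohort) || is.null(cohort))
      cohort <- cohorts[keep[1]]
    if (is.na(cohort) || !cohort %in%
          c("soaring", "flap_glide", "flapping")) cohort <- "other"
    fixes <- data.frame(t = t[keep], lat = lat[keep], lon = lon[keep],
                        alt = alt[keep], ground_speed = speed[keep])
    tracks[[id]] <- bird_track(id, cohort, fixes,
                               accel = accel_by_bird[[id]])
  }
  attr(tracks, "drop_report") <- drop_report
  tracks
}

read_accel_csv <- function(path, config) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- c(config$accel_t, config$accel_x, config$accel_y, config$accel_z)
  miss <- need[!need %in% names(df)]
  if (length(miss))
    stop("missing accel column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  fac <- if (config$accel_unit == "g") 9.81 else 1
  data.frame(t = parse_timestamps(df[[config$accel_t]]),
             ax = fac * as.numeric(df[[config$accel_x]]),
             ay = fac * as.numeric(df[[config$accel_y]]),
             az = fac * as.numeric(df[[config$accel_z]]))
}

read_track_dir <- function(path, config) {
  gps_files <- Sys.glob(file.path(path, "tracks", config$gps_pattern))
  if (!length(gps_files))
    gps_files <- Sys.glob(file.path(path, config$gps_pattern))
  if (!length(gps_files))
    stop("no track files matching '", config$gps_pattern, "' under ", path,
         "; expected <dir>/tracks/<bird>_gps.csv (+ optional accel/ and ",
         "manifest.json)")
  cohort_map <- character()
  manifest <- file.path(path, "manifest.json")
  if (file.exists(manifest)) {
    m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    if (!is.null(m$birds))
      cohort_map <- stats::setNames(as.character(m$birds$cohort),
                                    as.character(m$birds$bird_id))
  }
  out <- list()
  drops <- list()
  for (f in gps_files) {
    stem <- sub("_gps\\.csv$", "", basename(f))
    acc_f <- file.path(dirname(dirname(f)), "accel",
                       paste0(stem, "_acc.csv"))
    if (!file.exists(acc_f))
      acc_f <- file.path(dirname(f), paste0(stem, "_acc.csv"))
    accel <- if (file.exists(acc_f))
      stats::setNames(list(read_accel_csv(acc_f, config)), stem) else list()
    tr <- read_track_csv(f, config, accel_by_bird = accel,
                         cohort_map = cohort_map)
    drops <- c(drops, attr(tr, "drop_report"))
    out <- c(out, tr)
  }
  attr(out, "drop_report") <- drops
  out
}

#' Write tracks back to Movebank-style CSV
#'
#' Inverse of [read_tracks()] for the retained fields; one GPS file (and one
#' accel file when present) per bird, in the dialect described by `config`.
#'
#' @param tracks list of [bird_track()].
#' @param dir output directory (created if needed).
#' @param config a [reader_config()].
#' @return invisibly, the paths written.
#' @export
write_tracks <- function(tracks, dir, config = reader_config()) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tr in tracks) {
    df <- data.frame(tr$fixes$t, tr$bird_id, tr$fixes$lat, tr$fixes$lon,
                     tr$fixes$alt, tr$cohort)
    names(df) <- c(config$timestamp, config$bird_id, config$lat, config$lon,
                   config$alt, if (is.null(config$cohort)) "cohort" else
                     config$cohort)
    if (!is.null(config$speed) && !all(is.na(tr$fixes$ground_speed)))
      df[[config$speed]] <- tr$fixes$ground_speed
    f <- file.path(dir, "tracks", paste0(tr$bird_id, "_gps.csv"))
    data.table::fwrite(df, f)
    paths <- c(paths, f)
    if (!is.null(tr$accel) && nrow(tr$accel)) {
      dir.create(file.path(dir, "accel"), showWarnings = FALSE)
      fac <- if (config$accel_unit == "g") 1 / 9.81 else 1
      adf <- data.frame(tr$accel$t, fac * tr$accel$ax, fac * tr$accel$ay,
                        fac * tr$accel$az)
      names(adf) <- c(config$accel_t, config$accel_x, config$accel_y,
                      config$accel_z)
      fa <- file.path(dir, "accel", paste0(tr$bird_id, "_acc.csv"))
      data.table::fwrite(adf, fa)
      paths <- c(paths, fa)
    }
  }
  invisible(paths)
}

#' Great-circle distance between fixes
#'
#' Haversine distance on a sphere of radius 6,371,000 m (WGS-84 treated as
#' spherical: the error is far below GPS noise at soaring scales).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @return horizontal distance in meters.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000)
}

#' Fill missing ground speeds by finite differences
#'
#' Where `ground_speed` is missing, computes the 3-D speed (horizontal
#' great-circle displacement combined with altitude change) by centered
#' finite differences; the endpoints use one-sided differences. Speeds
#' already present in the data are kept.
#'
#' @param track a [bird_track()] with at least 2 fixes.
#' @return the track with `ground_speed` filled.
#' @export
derive_ground_speed <- function(track) {
  fx <- track$fixes
  n <- nrow(fx)
  if (n < 2L) stop("derive_ground_speed needs at least 2 fixes")
  if (any(diff(fx$t) == 0))
    stop("duplicate timestamp in bird ", track$bird_id, " at t = ",
         fx$t[which(diff(fx$t) == 0)[1]])
  i0 <- c(1L, seq_len(n - 2L), n - 1L)       # earlier fix per sample
  i1 <- c(2L, seq_len(n - 2L) + 2L, n)       # later fix per sample
  dh <- geodesic_distance(fx$lat[i0], fx$lon[i0], fx$lat[i1], fx$lon[i1])
  dv <- fx$alt[i1] - fx$alt[i0]
  v <- sqrt(dh^2 + dv^2) / (fx$t[i1] - fx$t[i0])
  miss <- is.na(fx$ground_speed)
  fx$ground_speed[miss] <- v[miss]
  track$fixes <- fx
  track
}
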