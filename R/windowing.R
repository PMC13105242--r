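#' Partition a track into fixed-duration overlapping windows
#'
#' Windows are anchored to the track's first timestamp and advance by
#' `stride` seconds; each spans `[t_start, t_start + duration]`. A window is
#' emitted only if it holds at least `min_fixes` fixes and its gap fraction
#' (1 - observed/expected fixes at the track's median sampling interval) is
#' at most `max_gap`. On a gap-free track the number of windows is
#' `floor((span - duration)/stride) + 1`.
#'
#' @param track a [bird_track()].
#' @param duration window length, seconds (120 by default, the windowing used
#'   throughout the transport-effort analysis).
#' @param stride window start spacing, seconds; default 60 (50% overlap).
#' @param min_fixes minimum fixes per window; default 80% of the expected
#'   count at the observed median sampling interval.
#' @param max_gap maximum tolerated gap fraction, default 0.2.
#' @return data.frame of class `window_set`: `bird_id`, `t_start`, `t_end`,
#'   `i_start`, `i_end` (fix index range), `n_fixes`, `gap_fraction`.
#' @export
make_windows <- function(track, duration = 120, stride = 60,
                         min_fixes = NULL, max_gap = 0.2) {
  stopifnot(duration > 0, stride > 0, stride <= duration)
  t <- track$fixes$t
  span <- t[length(t)] - t[1]
  if (span < duration) {
    warning("track ", track$bird_id, " span (", round(span, 1),
            " s) shorter than window duration; no windows")
    return(empty_window_set())
  }
  dt_med <- median(diff(t))
  expected <- floor(duration / dt_med) + 1
  if (is.null(min_fixes)) min_fixes <- ceiling(0.8 * duration / dt_med)
  starts <- seq(t[1], t[1] + span - duration, by = stride)
  i0 <- findInterval(starts, t, left.open = FALSE)
  # first fix with time >= t_start
  i0 <- ifelse(t[pmax(i0, 1)] >= starts, pmax(i0, 1), pmin(i0 + 1, length(t)))
  i1 <- findInterval(starts + duration, t)
  n_fix <- i1 - i0 + 1L
  gap <- pmax(0, 1 - n_fix / expected)
  keep <- n_fix >= min_fixes & gap <= max_gap & n_fix >= 2L
  out <- data.frame(bird_id = track$bird_id, t_start = starts,
                    t_end = starts + duration, i_start = i0, i_end = i1,
                    n_fixes = n_fix, gap_fraction = gap)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_set", "data.frame")
  out
}

empty_window_set <- function() {
  out <- data.frame(bird_id = character(), t_start = numeric(),
                    t_end = numeric(), i_start = integer(),
                    i_end = integer(), n_fixes = integer(),
                    gap_fraction = numeric())
  class(out) <- c("window_set", "data.frame")
  out
}

#' Net transport speed of a window
#'
#' Straight-line 3-D displacement between the first and last fix of the
#' window divided by their time separation. Looping flight therefore scores
#' below its along-path speed.
#'
#' @param window one row of a [make_windows()] result.
#' @param track the corresponding [bird_track()].
#' @return net transport speed, m/s.
#' @export
net_transport_speed <- function(window, track) {
  fx <- track$fixes
  i0 <- window$i_start; i1 <- window$i_end
  if (i1 <= i0) stop("window must span at least two fixes")
  dh <- geodesic_distance(fx$lat[i0], fx$lon[i0], fx$lat[i1], fx$lon[i1])
  dv <- fx$alt[i1] - fx$alt[i0]
  sqrt(dh^2 + dv^2) / (fx$t[i1] - fx$t[i0])
}

#' Window-level transport and effort metrics
#'
#' Computes, for every window of a track, the net transport speed and (when
#' an accelerometer series is present) the mean VeDBA effort proxy. Windows
#' with insufficient VeDBA coverage get `NA` effort and are excluded from
#' the speed-effort plane downstream.
#'
#' @param track a [bird_track()].
#' @param windows result of [make_windows()]; computed if `NULL`.
#' @param vedba optional precomputed [vedba()] series for the track's accel.
#' @param duration,stride passed to [make_windows()] when `windows` is NULL.
#' @param smoothing_window VeDBA smoothing window, seconds.
#' @param min_coverage minimum fraction of the window covered by VeDBA
#'   samples, default 0.5.
#' @return data.frame: `bird_id`, `cohort`, `t_start`, `t_end`, `v_net`,
#'   `mean_vedba`, `n_fixes`, `gap_fraction`.
#' @export
window_metrics <- function(track, windows = NULL, vedba = NULL,
                           duration = 120, stride = 60,
                           smoothing_window = 2, min_coverage = 0.5) {
  if (is.null(windows)) windows <- make_windows(track, duration, stride)
  if (nrow(windows) == 0L)
    return(cbind(windows[, c("bird_id", "t_start", "t_end")],
                 v_net = numeric(0), mean_vedba = numeric(0),
                 cohort = character(0)))
  v_net <- vapply(seq_len(nrow(windows)), function(i)
    net_transport_speed(windows[i, ], track), numeric(1))
  mv <- rep(NA_real_, nrow(windows))
  if (is.null(vedba) && !is.null(track$accel) && nrow(track$accel) > 0)
    vedba <- dynsoar::vedba(track$accel, smoothing_window)
  if (!is.null(vedba)) {
    mv <- vapply(seq_len(nrow(windows)), function(i)
      window_mean_vedba(windows[i, ], vedba, min_coverage), numeric(1))
  }
  data.frame(bird_id = windows$bird_id, cohort = track$cohort,
             t_start = windows$t_start, t_end = windows$t_end,
             v_net = v_net, mean_vedba = mv, n_fixes = windows$n_fixes,
             gap_fraction = windows$gap_fraction)
}
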