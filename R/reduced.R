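#' Per-bird low-effort baselines
#'
#' Estimates, for one bird, the low-effort reference speed `V_base` and the
#' low-effort effort baseline `E0` used to map windows into the reduced
#' speed-effort plane. The low-effort window subset is the lowest
#' `q_low`-quantile of mean VeDBA; `V_base` is the median net transport
#' speed over that subset; `E0` is the `q_eff` quantile of mean VeDBA over
#' all retained windows (floored at `eps_E`). All quantiles are type-7.
#'
#' @param metrics window-metrics rows for one bird (see [window_metrics()]);
#'   rows with `NA` effort are ignored.
#' @param q_low low-effort subset quantile, default 0.2.
#' @param q_eff effort-baseline quantile, default 0.10.
#' @param min_windows minimum retained windows, default 30; fewer is an
#'   error (the caller excludes the bird).
#' @param eps_E floor for `E0` to avoid division blow-up, m/s^2.
#' @return data.frame row: `bird_id`, `V_base`, `E0`, `n_baseline_windows`.
#' @export
estimate_baselines <- function(metrics, q_low = 0.2, q_eff = 0.10,
                               min_windows = 30, eps_E = 1e-3) {
  ok <- !is.na(metrics$mean_vedba) & !is.na(metrics$v_net)
  m <- metrics[ok, ]
  if (nrow(m) < min_windows)
    stop("bird ", metrics$bird_id[1], " has ", nrow(m),
         " retained windows (< ", min_windows, "); excluded")
  thr <- quantile(m$mean_vedba, q_low, type = 7, names = FALSE)
  low <- m[m$mean_vedba <= thr, ]
  V_base <- median(low$v_net)
  E0 <- max(eps_E, quantile(m$mean_vedba, q_eff, type = 7, names = FALSE))
  if (V_base <= 0) stop("non-positive V_base for bird ", m$bird_id[1])
  data.frame(bird_id = m$bird_id[1], V_base = V_base, E0 = E0,
             n_baseline_windows = nrow(low))
}

#' Map window metrics into reduced coordinates
#'
#' X = v_net / V_base and Y = (mean_vedba - E0) / E0: dimensionless transport
#' speed and normalized excess effort relative to the bird's own low-effort
#' baselines. The normalisation is applied bird by bird, making cohorts with
#' different absolute speeds and effort scales comparable.
#'
#' @param metrics window-metrics rows for one bird.
#' @param baseline the bird's [estimate_baselines()] row.
#' @return data.frame: `bird_id`, `cohort`, `X`, `Y`.
#' @export
to_reduced <- function(metrics, baseline) {
  ok <- !is.na(metrics$mean_vedba) & !is.na(metrics$v_net)
  m <- metrics[ok, ]
  data.frame(bird_id = m$bird_id,
             cohort = if ("cohort" %in% names(m)) m$cohort else "other",
             X = m$v_net / baseline$V_base,
             Y = (m$mean_vedba - baseline$E0) / baseline$E0)
}

#' Reduce a whole metrics table bird by bird
#'
#' Convenience wrapper: estimates baselines per bird, drops birds with too
#' few retained windows (with a message), and returns pooled reduced points
#' plus the baselines table.
#'
#' @inheritParams estimate_baselines
#' @param metrics window-metrics table for any number of birds.
#' @return list with `points` (reduced points) and `baselines`.
#' @export
reduce_metrics <- function(metrics, q_low = 0.2, q_eff = 0.10,
                           min_windows = 30, eps_E = 1e-3) {
  pts <- list(); bls <- list()
  for (id in unique(metrics$bird_id)) {
    m <- metrics[metrics$bird_id == id, ]
    bl <- tryCatch(
      estimate_baselines(m, q_low, q_eff, min_windows, eps_E),
      error = function(e) { message(conditionMessage(e)); NULL })
    if (is.null(bl)) next
    bls[[id]] <- bl
    pts[[id]] <- to_reduced(m, bl)
  }
  list(points = do.call(rbind, c(pts, list(make.row.names = FALSE))),
       baselines = do.call(rbind, c(bls, list(make.row.names = FALSE))))
}
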