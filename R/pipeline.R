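#' Fully materialised pipeline configuration
#'
#' Every tunable of the end-to-end analysis in one place, with the defaults
#' used throughout the package; no stage applies hidden defaults of its own.
#'
#' @param duration,stride windowing, seconds.
#' @param smoothing_window VeDBA static-estimation window, seconds.
#' @param min_coverage minimum VeDBA coverage of a window.
#' @param q_low,q_eff,min_windows,eps_E baseline estimation (see
#'   [estimate_baselines()]).
#' @param percentile,bin_width,min_bin_count frontier estimation.
#' @param polar a [glide_polar()] for the drag model.
#' @param v_min stall floor for the drag model, m/s.
#' @param fit_grid,fit_tau bound-fitting controls (see [fit_hjb()]).
#' @param seed recorded in manifests and passed to [fit_hjb()].
#' @return object of class `run_config`.
#' @export
run_config <- function(duration = 120, stride = 60, smoothing_window = 2,
                       min_coverage = 0.5, q_low = 0.2, q_eff = 0.10,
                       min_windows = 30, eps_E = 1e-3, percentile = 0.10,
                       bin_width = 0.1, min_bin_count = 25,
                       polar = glide_polar(), v_min = 5,
                       fit_grid = list(from = -2, to = 1, n = 5),
                       fit_tau = 1e-3, seed = 1L) {
  structure(list(duration = duration, stride = stride,
                 smoothing_window = smoothing_window,
                 min_coverage = min_coverage, q_low = q_low, q_eff = q_eff,
                 min_windows = min_windows, eps_E = eps_E,
                 percentile = percentile, bin_width = bin_width,
                 min_bin_count = min_bin_count, polar = polar,
                 v_min = v_min, fit_grid = fit_grid, fit_tau = fit_tau,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Window-level transport-effort analysis of a track set
#'
#' Stage one of the pipeline: derives ground speeds, windows every track,
#' computes net transport speed and mean VeDBA per window, optionally the
#' per-window energy budgets, and the global lower frontier in the raw
#' (net transport speed, mean VeDBA) plane.
#'
#' @param tracks a list of [bird_track()] (e.g. from [read_tracks()]), or a
#'   path accepted by `read_tracks()`.
#' @param config a [run_config()].
#' @param energy_budgets also compute per-window energy budgets (list of
#'   data.frames, one per window)? Default FALSE (they are large).
#' @param out_dir optional directory: writes `window_metrics.csv`,
#'   `frontier_raw.csv` and a `run_manifest.json`.
#' @return list with `metrics` (window-metrics table), `frontier` (raw-plane
#'   [lower_frontier()]), and optionally `budgets`.
#' @export
run_frontier_pipeline <- function(tracks, config = run_config(),
                                  energy_budgets = FALSE, out_dir = NULL) {
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  if (!length(tracks)) stop("no input tracks")
  metrics <- list(); budgets <- list()
  for (tr in tracks) {
    res <- tryCatch({
      tr <- derive_ground_speed(tr)
      w <- make_windows(tr, config$duration, config$stride)
      m <- window_metrics(tr, w, duration = config$duration,
                          stride = config$stride,
                          smoothing_window = config$smoothing_window,
                          min_coverage = config$min_coverage)
      if (energy_budgets && nrow(w))
        budgets[[tr$bird_id]] <- lapply(seq_len(nrow(w)), function(i)
          energy_budget(w[i, ], tr, config$polar, config$v_min))
      m
    }, error = function(e)
      stop("stage failure for bird ", tr$bird_id, ": ",
           conditionMessage(e), call. = FALSE))
    metrics[[tr$bird_id]] <- res
  }
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  ok <- !is.na(metrics$mean_vedba)
  frontier <- lower_frontier(metrics$v_net[ok], metrics$mean_vedba[ok],
                             percentile = config$percentile,
                             bin_width = max(0.5, 5 * config$bin_width),
                             min_bin_count = config$min_bin_count)
  out <- list(metrics = metrics, frontier = frontier)
  if (energy_budgets) out$budgets <- budgets
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(metrics, file.path(out_dir, "window_metrics.csv"))
    data.table::fwrite(as.data.frame(frontier),
                       file.path(out_dir, "frontier_raw.csv"))
    write_run_manifest(out_dir, config, length(tracks))
  }
  out
}

#' Reduced-plane benchmark analysis
#'
#' Stage two: maps window metrics into per-bird reduced coordinates,
#' estimates each cohort's lower frontier, fits the reduced bound to the
#' soaring cohort's frontier (the bound is always anchored there), and
#' profiles every cohort's residual offset against that single fitted bound.
#'
#' @param metrics a window-metrics table from [run_frontier_pipeline()].
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list: `points` (reduced points), `baselines`, `frontiers` (named
#'   list of per-cohort [lower_frontier()]), `fit` (the [fit_hjb()] object),
#'   `residuals` (named list of [frontier_residual()]), `summary`
#'   (data.frame of per-cohort mean/median deltaY).
#' @export
run_benchmark_pipeline <- function(metrics, config = run_config(),
                                   out_dir = NULL) {
  known <- c("soaring", "flap_glide", "flapping", "other")
  bad <- setdiff(unique(metrics$cohort), known)
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  red <- reduce_metrics(metrics, config$q_low, config$q_eff,
                        config$min_windows, config$eps_E)
  pts <- red$points
  if (is.null(pts) || !nrow(pts)) stop("no birds survived baseline estimation")
  if (!any(pts$cohort == "soaring"))
    stop("soaring cohort absent: the reduced bound must be anchored to it")
  cohorts <- intersect(c("soaring", "flap_glide", "flapping"),
                       unique(pts$cohort))
  frontiers <- lapply(stats::setNames(cohorts, cohorts), function(ch) {
    p <- pts[pts$cohort == ch, ]
    lower_frontier(p$X, p$Y, config$percentile, config$bin_width,
                   config$min_bin_count)
  })
  fit <- fit_hjb(frontiers$soaring, grid = config$fit_grid,
                 tau = config$fit_tau, seed = config$seed)
  residuals <- lapply(frontiers, frontier_residual, params = fit)
  summary <- do.call(rbind, lapply(cohorts, function(ch) {
    s <- attr(residuals[[ch]], "summary")
    data.frame(cohort = ch, n_bins = nrow(residuals[[ch]]),
               mean_delta_y = s[["mean"]], median_delta_y = s[["median"]])
  }))
  out <- list(points = pts, baselines = red$baselines,
              frontiers = frontiers, fit = fit, residuals = residuals,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(pts, file.path(out_dir, "reduced_points.csv"))
    data.table::fwrite(red$baselines, file.path(out_dir, "baselines.csv"))
    for (ch in cohorts) {
      data.table::fwrite(as.data.frame(frontiers[[ch]]),
                         file.path(out_dir, paste0("frontier_", ch, ".csv")))
      data.table::fwrite(as.data.frame(residuals[[ch]]),
                         file.path(out_dir, paste0("residual_", ch, ".csv")))
    }
    jsonlite::write_json(
      list(a = fit$a, b = fit$b, W = fit$W, fit_loss = fit$fit_loss,
           converged = fit$converged, seed = fit$seed,
           summary = summary),
      file.path(out_dir, "benchmark_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_run_manifest(out_dir, config, length(unique(metrics$bird_id)))
  }
  out
}

write_run_manifest <- function(out_dir, config, n_tracks) {
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "polar")],
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dynsoar")),
    r_version = as.character(getRversion()),
    n_tracks = n_tracks, seed = config$seed,
    polar = unclass(config$polar),
    config = jsonlite::fromJSON(cfg_json),
    config_hash = unname(tools::md5sum(tf)))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
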