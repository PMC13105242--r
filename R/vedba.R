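#' Vectorial dynamic body acceleration
#'
#' Per axis, the quasi-static (gravity/orientation) component is estimated by
#' a centered running mean over `smoothing_window` seconds (truncated at the
#' series edges); the dynamic component is the raw signal minus that static
#' estimate; VeDBA is the Euclidean norm of the three dynamic components.
#' The result is non-negative by construction, invariant to constant offset
#' vectors, and scales linearly with the input.
#'
#' @param accel data.frame with columns `t` (s, near-uniform sampling),
#'   `ax`, `ay`, `az` (m/s^2).
#' @param smoothing_window static-estimation window, seconds (default 2).
#' @return data.frame of class `vedba_series`: `t`, `vedba` (m/s^2), with
#'   attribute `smoothing_window`.
#' @export
vedba <- function(accel, smoothing_window = 2) {
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(accel)))
  n <- nrow(accel)
  if (n < 2L) stop("accel series too short for VeDBA")
  dt <- diff(accel$t)
  dt_med <- median(dt)
  if (any(dt > 2 * dt_med + 1e-9))
    warning("accel series has gaps > 2x median sampling interval")
  if ((accel$t[n] - accel$t[1]) < 2 * smoothing_window)
    stop("accel series shorter than twice the smoothing window")
  h <- max(1L, round(smoothing_window / dt_med / 2))
  # centering on the first sample keeps the running-mean subtraction exact
  # for constant inputs and well-conditioned for gravity-dominated ones
  dyn <- function(x) { xc <- x - x[1]; xc - running_mean(xc, h) }
  v <- sqrt(dyn(accel$ax)^2 + dyn(accel$ay)^2 + dyn(accel$az)^2)
  out <- data.frame(t = accel$t, vedba = v)
  attr(out, "smoothing_window") <- smoothing_window
  class(out) <- c("vedba_series", "data.frame")
  out
}

# centered running mean over indices [i-h, i+h], truncated at the edges
running_mean <- function(x, h) {
  n <- length(x)
  cs <- cumsum(x)
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Mean VeDBA of a window
#'
#' Arithmetic mean of VeDBA samples with `t` in `[t_start, t_end)` (half-open
#' so overlapping windows never double-count a boundary sample). Returns `NA`
#' when the samples cover less than `min_coverage` of the window.
#'
#' @param window one row of [make_windows()].
#' @param vedba a [vedba()] series.
#' @param min_coverage minimum covered fraction, default 0.5.
#' @return mean VeDBA (m/s^2) or `NA` if coverage is insufficient.
#' @export
window_mean_vedba <- function(window, vedba, min_coverage = 0.5) {
  sel <- vedba$t >= window$t_start & vedba$t < window$t_end
  if (!any(sel)) return(NA_real_)
  dt_med <- median(diff(vedba$t))
  coverage <- sum(sel) * dt_med / (window$t_end - window$t_start)
  if (coverage < min_coverage) return(NA_real_)
  mean(vedba$vedba[sel])
}
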