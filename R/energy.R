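#' Ground-frame specific mechanical energy
#'
#' E = 0.5*u^2 + g*z per unit mass (J/kg), with u the ground speed and z the
#' altitude.
#'
#' @param u ground speed, m/s (vectorised).
#' @param z altitude, m.
#' @param g gravitational acceleration, m/s^2.
#' @return specific energy, J/kg.
#' @export
specific_energy <- function(u, z, g = 9.81) {
  if (any(u < 0, na.rm = TRUE)) stop("ground speed must be non-negative")
  0.5 * u^2 + g * z
}

#' Energy relative to the window start
#'
#' deltaE(t) = E(t) - E(t_start); the first element is exactly zero.
#'
#' @param E numeric energy series (J/kg), non-empty.
#' @return series of the same length.
#' @export
relative_energy <- function(E) {
  if (!length(E)) stop("empty energy series")
  E - E[1]
}

#' Cumulative quasi-steady drag work over a window
#'
#' Mass-specific drag power p(V) = D(V)*V/m is evaluated on the window's
#' speed samples using a trimmed glide polar, with airspeed approximated by
#' ground speed (the ambient wind field is not reconstructed pointwise, so
#' the result is an effective, not exact, dissipation). Speeds below the
#' stall floor `v_min` are clamped for the polar evaluation, since the
#' induced term diverges as V -> 0. The power is integrated by the
#' trapezoidal rule on the native timestamps and negated, so the returned
#' cumulative series starts at 0, is non-increasing and is everywhere <= 0.
#'
#' @param t timestamps, seconds.
#' @param u ground speeds, m/s.
#' @param polar a [glide_polar()].
#' @param v_min stall floor, m/s (default 5).
#' @return cumulative drag work series, J/kg (<= 0).
#' @export
drag_work <- function(t, u, polar, v_min = 5) {
  stopifnot(length(t) == length(u), length(t) >= 1)
  p <- drag_power(pmax(u, v_min), polar)
  -cumtrapz(t, p)
}

cumtrapz <- function(t, y) {
  n <- length(t)
  if (n == 1L) return(0)
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(t)))
}

#' Inferred atmospheric-input work
#'
#' W_harvest(t) = deltaE(t) - W_drag(t): the part of the window's energy
#' fluctuation not explained by quasi-steady drag, interpreted as an
#' effective atmospheric (wind-shear) input over gliding-dominated windows
#' where sustained muscular input is small.
#'
#' @param deltaE relative-energy series, J/kg.
#' @param W_drag cumulative drag-work series, J/kg (same length).
#' @return W_harvest series, J/kg.
#' @export
harvest_work <- function(deltaE, W_drag) {
  if (length(deltaE) != length(W_drag))
    stop("deltaE and W_drag must have equal length")
  deltaE - W_drag
}

#' Window energy budget
#'
#' Assembles the full per-window budget: E, deltaE, cumulative drag work and
#' the inferred harvest term, on the window's fix timestamps.
#'
#' @param window one row of [make_windows()].
#' @param track a [bird_track()] with ground speeds available (see
#'   [derive_ground_speed()]).
#' @param polar a [glide_polar()].
#' @param v_min stall floor for the drag model, m/s.
#' @return data.frame `t`, `E`, `deltaE`, `W_drag`, `W_harvest`.
#' @export
energy_budget <- function(window, track, polar = glide_polar(), v_min = 5) {
  idx <- window$i_start:window$i_end
  fx <- track$fixes[idx, ]
  if (anyNA(fx$ground_speed))
    stop("ground speeds missing; run derive_ground_speed() first")
  E <- specific_energy(pmax(fx$ground_speed, 0), fx$alt, polar$g)
  dE <- relative_energy(E)
  Wd <- drag_work(fx$t, fx$ground_speed, polar, v_min)
  data.frame(t = fx$t, E = E, deltaE = dE, W_drag = Wd,
             W_harvest = harvest_work(dE, Wd))
}
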