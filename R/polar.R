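#' Quasi-steady glide polar
#'
#' Bundles the aerodynamic parameters of a fixed-wing glider used by the
#' quasi-steady drag model and the flight simulator. Defaults are
#' albatross-like order-of-magnitude values (a large procellariiform with
#' high-aspect wings); they are assumptions of this package, exposed here so
#' every analysis records them.
#'
#' @param mass body mass, kg.
#' @param wing_area reference wing area S, m^2.
#' @param CD0 parasite (zero-lift) drag coefficient.
#' @param k_induced induced-drag factor, so CD = CD0 + k_induced * CL^2.
#' @param rho air density, kg/m^3.
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `glide_polar` (a named list).
#' @examples
#' p <- glide_polar()
#' best_glide_speed(p)      # airspeed of maximum lift-to-drag ratio
#' @export
glide_polar <- function(mass = 8.5, wing_area = 0.65, CD0 = 0.033,
                        k_induced = 0.02, rho = 1.225, g = 9.81) {
  vals <- c(mass = mass, wing_area = wing_area, CD0 = CD0,
            k_induced = k_induced, rho = rho, g = g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("glide_polar parameters must be positive and finite: ",
         paste(bad, collapse = ", "))
  }
  structure(as.list(vals), class = "glide_polar")
}

#' @export
print.glide_polar <- function(x, ...) {
  cat("Glide polar: mass", x$mass, "kg, S", x$wing_area, "m^2, CD0", x$CD0,
      ", k", x$k_induced, ", rho", x$rho, "kg/m^3\n")
  cat("  (L/D)max =", round(1 / (2 * sqrt(x$k_induced * x$CD0)), 2),
      " best-glide speed =", round(best_glide_speed(x), 2), "m/s\n")
  invisible(x)
}

#' Trimmed drag force of a glide polar
#'
#' Drag at airspeed V for level-trimmed flight:
#' D(V) = 0.5*rho*V^2*S*CD0 + 2*k_induced*(m*g)^2 / (rho*V^2*S).
#'
#' @param V airspeed, m/s (vectorised).
#' @param polar a [glide_polar()].
#' @return drag force, N.
#' @export
drag_force <- function(V, polar) {
  qS <- 0.5 * polar$rho * V^2 * polar$wing_area
  qS * polar$CD0 +
    2 * polar$k_induced * (polar$mass * polar$g)^2 /
      (polar$rho * V^2 * polar$wing_area)
}

#' Mass-specific drag power p(V) = D(V) * V / m, W/kg.
#' @inheritParams drag_force
#' @return specific drag power, W/kg.
#' @export
drag_power <- function(V, polar) drag_force(V, polar) * V / polar$mass

#' Airspeed of maximum lift-to-drag ratio.
#' @param polar a [glide_polar()].
#' @return best-glide airspeed, m/s.
#' @export
best_glide_speed <- function(polar) {
  ((4 * polar$k_induced * (polar$mass * polar$g)^2) /
     (polar$rho^2 * polar$wing_area^2 * polar$CD0))^(1 / 4)
}
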