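# Analytic water-hammer scaling law, reference grid, and damage threshold.
# All internal computation is in SI units (m, Pa, N/m); nm/GPa conveniences
# are converted on entry.

#' Unit-prefixed constants used by the scaling interface
#' @keywords internal
.NM  <- 1e-9   # metres per nanometre
.GPA <- 1e9    # pascals per gigapascal

#' Validate a scaling input (bubble diameter, gap, post-shock pressure)
#'
#' @param D bubble diameter in metres (> 0).
#' @param d bubble-to-polymer gap in metres (>= 0).
#' @param p_p post-shock pressure in pascals (>= 0).
#' @return invisibly TRUE; stops with a message naming the offending field.
#' @keywords internal
validate_scaling_input <- function(D, d, p_p) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0))
    stop("scaling input: D (bubble diameter) must be finite and > 0", call. = FALSE)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("scaling input: d (bubble-polymer gap) must be finite and >= 0", call. = FALSE)
  if (!is.numeric(p_p) || any(!is.finite(p_p)) || any(p_p < 0))
    stop("scaling input: p_p (post-shock pressure) must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Water-hammer kinetic energy per frontal area
#'
#' The total kinetic energy of the jet produced by the asymmetric collapse of
#' a bubble of diameter \eqn{D} under post-shock pressure \eqn{p_p} scales as
#' \eqn{E_k \propto D^3 p_p} (the proportionality constant is fixed at 1 and
#' the result is a scale, not an absolute energy). After impact the energy
#' disperses radially, so the averaged kinetic energy per frontal area acting
#' on a polymer a distance \eqn{d} downstream is
#' \deqn{E_k/(D+2d)^2 = D^3/(D+2d)^2 \, p_p}
#' with units of N/m. Rupture of the hyaluronan stand-in is predicted above
#' about 40 N/m (see [classify_damage()]).
#'
#' @param D bubble diameter. Metres by default; nanometres with
#'   `units = "nm_gpa"`. Vectorised (recycled against `d`, `p_p`).
#' @param d gap between bubble surface and polymer. Same length unit as `D`.
#' @param p_p post-shock pressure. Pascals by default; gigapascals with
#'   `units = "nm_gpa"`.
#' @param units `"si"` (m, Pa) or `"nm_gpa"` (nm, GPa) for the *inputs*;
#'   outputs are always SI (N/m).
#' @return object of class `"scaling_result"`: a list with `energy_per_area`
#'   (N/m), `total_energy_scale` (the value of \eqn{D^3 p_p}, prefactor 1),
#'   and the SI inputs.
#' @examples
#' # 5 nm bubble, 1 nm gap, 2.65 GPa post-shock pressure -> 6.76 N/m
#' energy_per_area(5, 1, 2.65, units = "nm_gpa")$energy_per_area
#' @export
energy_per_area <- function(D, d, p_p, units = c("si", "nm_gpa")) {
  units <- match.arg(units)
  if (units == "nm_gpa") {
    D <- D * .NM; d <- d * .NM; p_p <- p_p * .GPA
  }
  validate_scaling_input(D, d, p_p)
  res <- list(
    energy_per_area    = D^3 / (D + 2 * d)^2 * p_p,
    total_energy_scale = D^3 * p_p,
    D = D, d = d, p_p = p_p
  )
  class(res) <- "scaling_result"
  res
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("Water-hammer scaling result\n")
  cat(sprintf("  D = %g nm, d = %g nm, p_p = %g GPa\n",
              x$D / .NM, x$d / .NM, x$p_p / .GPA))
  cat(sprintf("  energy per frontal area: %g N/m\n", x$energy_per_area))
  cat(sprintf("  total energy scale (D^3 p_p, prefactor 1): %g J-scale\n",
              x$total_energy_scale))
  invisible(x)
}

#' Reference nine-case energy-per-area grid
#'
#' Evaluates the energy-per-frontal-area scaling over the nine simulated
#' bubble cases: post-shock pressures 2.65, 7.97 and 16.2 GPa (the pressures
#' behind shocks of speed 3.60, 5.35 and 7.20 km/s in water, carried here as
#' fixed reference constants) crossed with bubble diameters 5, 8 and 10 nm,
#' at a fixed bubble-to-polymer gap.
#'
#' @param d_nm gap distance in nanometres (default 1).
#' @return object of class `"energy_grid"`: list with `values` (3x3 matrix,
#'   N/m; rows = pressures, columns = diameters), `pressures_GPa`,
#'   `diameters_nm`, `shock_velocities_km_s`, `d_nm`, and (after
#'   [classify_damage()]) `threshold` and `exceed_mask`.
#' @examples
#' generate_table1()
#' @export
generate_table1 <- function(d_nm = 1) {
  if (!is.numeric(d_nm) || length(d_nm) != 1L || !is.finite(d_nm) || d_nm < 0)
    stop("scaling input: d (gap distance) must be a single finite value >= 0",
         call. = FALSE)
  p_GPa <- c(2.65, 7.97, 16.2)
  v_s   <- c(3.60, 5.35, 7.20)
  D_nm  <- c(5, 8, 10)
  vals <- outer(p_GPa, D_nm, function(p, D) {
    energy_per_area(D, d_nm, p, units = "nm_gpa")$energy_per_area
  })
  dimnames(vals) <- list(sprintf("v_s=%.2f km/s", v_s),
                         sprintf("D=%g nm", D_nm))
  grid <- list(values = vals,
               pressures_GPa = p_GPa,
               diameters_nm = D_nm,
               shock_velocities_km_s = v_s,
               d_nm = d_nm,
               threshold = NULL,
               exceed_mask = NULL)
  class(grid) <- "energy_grid"
  grid
}

#' Classify grid cells against the rupture threshold
#'
#' Cells whose energy per frontal area strictly exceeds the threshold are
#' flagged as predicted ruptures. The default 40 N/m is the first-order
#' rupture threshold for the hyaluronan stand-in.
#'
#' @param grid an `"energy_grid"` from [generate_table1()].
#' @param threshold rupture threshold in N/m (>= 0); comparison is strict (>).
#' @return the grid with `threshold`, logical `exceed_mask`, and integer
#'   `n_exceed` filled in.
#' @examples
#' classify_damage(generate_table1())$n_exceed  # 5 predicted ruptures
#' @export
classify_damage <- function(grid, threshold = 40) {
  if (!inherits(grid, "energy_grid")) stop("grid must be an 'energy_grid'", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0)
    stop("threshold must be a single finite value >= 0 (N/m)", call. = FALSE)
  grid$threshold <- threshold
  grid$exceed_mask <- grid$values > threshold
  grid$n_exceed <- sum(grid$exceed_mask)
  grid
}

#' @export
print.energy_grid <- function(x, digits = 3, ...) {
  cat(sprintf("Water-hammer kinetic energy per frontal area (N/m), d = %g nm\n",
              x$d_nm))
  print(signif(x$values, digits))
  if (!is.null(x$threshold)) {
    cat(sprintf("Cells exceeding %g N/m (predicted rupture): %d\n",
                x$threshold, x$n_exceed))
    print(x$exceed_mask)
  }
  invisible(x)
}

#' Young-Laplace pressure of a bubble
#'
#' The excess pressure sustained by surface tension across a spherical
#' interface, \eqn{\Delta p = 2\gamma/r}. It scales inversely with bubble
#' size, which is why nanoscale cavitation bubbles are intrinsically
#' unstable.
#'
#' @param gamma surface tension in N/m (>= 0).
#' @param r bubble radius in metres (> 0).
#' @return pressure in pascals.
#' @examples
#' laplace_pressure(0.072, 2.5e-9)  # ~5.76e7 Pa for a 5 nm water bubble
#' @export
laplace_pressure <- function(gamma, r) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma < 0))
    stop("laplace input: gamma (surface tension) must be finite and >= 0", call. = FALSE)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("laplace input: r (bubble radius) must be finite and > 0", call. = FALSE)
  2 * gamma / r
}
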