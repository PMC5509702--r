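# Reduced-unit <-> SI mapping. The engine itself works purely in reduced
# Lennard-Jones units; the map is used only for reporting (logs, manifests).

#' Reduced-unit to SI mapping
#'
#' Defines the SI meaning of one reduced length (sigma), energy (epsilon) and
#' mass unit, and derives the time, velocity and pressure conversion factors.
#' The defaults map one reduced length unit to 1 nm (so the reference bubble
#' diameters 5/8/10 read directly in nm), one reduced velocity unit to
#' 1 km/s, and pressure to epsilon/sigma^dim.
#'
#' @param sigma_SI metres per reduced length (default 1e-9).
#' @param epsilon_SI joules per reduced energy. Default chosen so that the
#'   derived velocity unit sqrt(epsilon/mass) is 1 km/s with the default mass.
#' @param mass_SI kg per reduced mass (default 3e-26, of the order of a water
#'   molecule).
#' @param dim spatial dimensionality used for the pressure factor (2 or 3).
#' @return object of class `"units_map"` with fields `sigma_SI`, `epsilon_SI`,
#'   `mass_SI`, `time_SI` (s), `velocity_SI` (m/s), `pressure_SI`
#'   (Pa for dim = 3; N/m for dim = 2).
#' @examples
#' units_map()$velocity_SI  # 1000 m/s per reduced velocity unit
#' @export
units_map <- function(sigma_SI = 1e-9, epsilon_SI = 3e-20, mass_SI = 3e-26,
                      dim = 2) {
  stopifnot(sigma_SI > 0, epsilon_SI > 0, mass_SI > 0, dim %in% c(2L, 3L))
  velocity_SI <- sqrt(epsilon_SI / mass_SI)
  um <- list(
    sigma_SI    = sigma_SI,
    epsilon_SI  = epsilon_SI,
    mass_SI     = mass_SI,
    dim         = as.integer(dim),
    velocity_SI = velocity_SI,
    time_SI     = sigma_SI / velocity_SI,
    pressure_SI = epsilon_SI / sigma_SI^dim
  )
  class(um) <- "units_map"
  um
}

#' @export
print.units_map <- function(x, ...) {
  cat("Reduced-unit map:\n")
  cat(sprintf("  length   : %g m\n", x$sigma_SI))
  cat(sprintf("  energy   : %g J\n", x$epsilon_SI))
  cat(sprintf("  mass     : %g kg\n", x$mass_SI))
  cat(sprintf("  velocity : %g m/s\n", x$velocity_SI))
  cat(sprintf("  time     : %g s\n", x$time_SI))
  cat(sprintf("  pressure : %g %s\n", x$pressure_SI,
              if (x$dim == 3L) "Pa" else "N/m"))
  invisible(x)
}
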