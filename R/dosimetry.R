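#' Volume-averaged irradiance in a flat plate
#'
#' For a well-mixed flat plate the volume average of the local intensity
#' reduces to a depth average,
#' \deqn{I_{av} = \frac{1}{L}\int_0^L I(z)\,dz,}
#' evaluated by fixed 64-node Gauss-Legendre quadrature on \code{[0, L]}.
#' The integrand is a smooth decaying exponential-type profile, so the
#' quadrature is accurate to near machine precision. Because transmittance
#' does not depend on the incident flux, \code{average_irradiance} is exactly
#' proportional to \code{incident}.
#'
#' @param coeffs attenuation coefficients (\code{lambert_beer} or
#'   \code{cornet}).
#' @param incident incident photon flux I0, umol photons m^-2 s^-1.
#' @param biomass biomass concentration, g/L.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param nodes number of quadrature nodes (default 64).
#' @return average irradiance, umol photons m^-2 s^-1; always <= incident.
#' @examples
#' geom <- reactor_geometry(0.025, 0.051)
#' lb <- lambert_beer_coefficients(0.08, 1.28)
#' average_irradiance(lb, incident = 400, biomass = 0.5, geometry = geom)
#' @export
average_irradiance <- function(coeffs, incident, biomass, geometry, nodes = 64) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  check_nonneg(incident, "incident")
  check_nonneg(biomass, "biomass")
  L <- geometry$light_path
  gl <- pracma::gaussLegendre(nodes, 0, L)
  tau <- transmittance(coeffs, biomass, gl$x)
  incident * sum(gl$w * tau) / L
}

#' Average photons received per cell (APRPC)
#'
#' The photon-dose metric for carotenogenesis induction:
#' \deqn{APRPC = I_{av} \cdot T \cdot S \cdot L \cdot 1000 / C}
#' with the average irradiance \code{iav} (umol photons m^-2 s^-1), induction
#' time \code{duration} in seconds, illuminated area S (m^2), light path L
#' (m) and cell concentration C (cells/L). The formula is implemented
#' verbatim as published; see the package vignette for a note on its
#' dimensional bookkeeping.
#'
#' @param iav average irradiance, umol photons m^-2 s^-1.
#' @param duration induction time, s.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param cells cell concentration, cells/L.
#' @return photon dose, umol photons per cell.
#' @examples
#' geom <- reactor_geometry(0.025, 0.051)
#' aprpc(400, duration = 12 * 3600, geometry = geom, cells = 4.0058e7)
#' @export
aprpc <- function(iav, duration, geometry, cells) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  check_nonneg(iav, "iav")
  check_nonneg(duration, "duration")
  check_pos(cells, "cells")
  iav * duration * geometry$illuminated_area * geometry$light_path * 1000 / cells
}

#' Cell concentration implied by a photon dose
#'
#' Algebraic inversion of the APRPC formula; round-trips with
#' \code{\link{aprpc}} exactly. Useful to recover the cell concentration
#' behind a published dose table.
#'
#' @param dose photon dose, umol photons per cell. Must be > 0.
#' @param iav average irradiance, umol photons m^-2 s^-1.
#' @param duration induction time, s.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @return cell concentration, cells/L.
#' @export
implied_cell_concentration <- function(dose, iav, duration, geometry) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  check_pos(dose, "dose")
  iav * duration * geometry$illuminated_area * geometry$light_path * 1000 / dose
}

#' Photon-dose grid over irradiances and durations
#'
#' @param iav_levels average irradiances, umol photons m^-2 s^-1.
#' @param hours induction times, h.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param cells cell concentration, cells/L.
#' @param digits if non-NULL, round half-up to this many decimals (the
#'   published table prints two).
#' @return matrix of doses, rows = irradiance levels, columns = durations,
#'   dimnames set from the inputs.
#' @examples
#' geom <- reactor_geometry(0.025, 0.051)
#' aprpc_grid(c(100, 400, 1600), c(2, 8, 24), geom, 4.0058e7, digits = 2)
#' @export
aprpc_grid <- function(iav_levels, hours, geometry, cells, digits = NULL) {
  if (!length(iav_levels) || !length(hours)) stop_domain("empty grid axes")
  g <- outer(iav_levels, hours * 3600,
             function(i, t) aprpc(i, t, geometry, cells))
  if (!is.null(digits)) g <- round_half_up(g, digits)
  dimnames(g) <- list(iav = as.character(iav_levels), hours = as.character(hours))
  g
}
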