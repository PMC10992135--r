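#' Flat-plate photobioreactor geometry
#'
#' The reactor is a stirred flat plate illuminated on one face: light enters
#' through an area \code{illuminated_area} (m^2) and traverses a depth
#' \code{light_path} (m). The culture volume in litres follows as
#' \code{area x path x 1000}.
#'
#' @param light_path depth of the plate along the illumination axis, m.
#' @param illuminated_area illuminated surface area, m^2.
#' @return an object of class \code{reactor_geometry} with fields
#'   \code{light_path}, \code{illuminated_area} and \code{culture_volume}
#'   (litres).
#' @examples
#' reactor_geometry(0.025, 0.051)  # 1.275 L plate
#' @export
reactor_geometry <- function(light_path = 0.025, illuminated_area = 0.051) {
  check_pos(light_path, "light_path")
  check_pos(illuminated_area, "illuminated_area")
  structure(
    list(
      light_path = light_path,
      illuminated_area = illuminated_area,
      culture_volume = illuminated_area * light_path * 1000
    ),
    class = "reactor_geometry"
  )
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf(
    "Flat-plate reactor: light path %g m, area %g m^2, volume %g L\n",
    x$light_path, x$illuminated_area, x$culture_volume
  ))
  invisible(x)
}

#' Lambert-Beer attenuation coefficients
#'
#' Lumped exponential attenuation: transmittance
#' \code{exp(-L * (Ka * X * 1000 + b))} for biomass X in g/L and path L in m.
#' \code{extinction} is the mass extinction coefficient Ka (m^2/g) and
#' \code{background} the fitting constant b (1/m) absorbing medium and wall
#' losses.
#'
#' @param extinction mass extinction coefficient, m^2/g. Must be >= 0.
#' @param background background attenuation constant, 1/m. Must be >= 0.
#' @return object of class \code{lambert_beer}.
#' @export
lambert_beer_coefficients <- function(extinction, background = 0) {
  check_nonneg(extinction, "extinction")
  check_nonneg(background, "background")
  structure(list(extinction = extinction, background = background),
            class = c("lambert_beer", "optical_coefficients"))
}

#' Cornet two-flux attenuation coefficients
#'
#' The two-flux (Schuster) approximation of radiative transfer separates a
#' mass absorption coefficient Ea from a mass scattering coefficient Es
#' (both m^2/g). Scattering matters for Dunaliella salina because its cells
#' are large (15-20 um) during carotenogenesis.
#'
#' @param absorption mass absorption coefficient Ea, m^2/g. Must be > 0.
#' @param scattering mass scattering coefficient Es, m^2/g. Must be >= 0.
#' @return object of class \code{cornet}.
#' @export
cornet_coefficients <- function(absorption, scattering = 0) {
  check_pos(absorption, "absorption")
  check_nonneg(scattering, "scattering")
  structure(list(absorption = absorption, scattering = scattering),
            class = c("cornet", "optical_coefficients"))
}

# biomass g/L -> g/m^3 so that m^2/g coefficients and m paths combine
# dimensionlessly
.BIOMASS_TO_M3 <- 1000

#' Lambert-Beer transmittance
#'
#' Fraction of the incident photon flux remaining after traversing
#' \code{depth} metres of a well-mixed culture at biomass \code{biomass}
#' g/L: \code{exp(-depth * (Ka * X * 1000 + b))}.
#'
#' @param coeffs a \code{\link{lambert_beer_coefficients}} object.
#' @param biomass biomass concentration, g/L (dry weight). Vectorised.
#' @param depth optical path, m. Vectorised.
#' @return transmittance in (0, 1].
#' @examples
#' lb <- lambert_beer_coefficients(0.08, 1.28)
#' lambert_beer_transmittance(lb, biomass = 0.5, depth = 0.025)
#' @export
lambert_beer_transmittance <- function(coeffs, biomass, depth) {
  stopifnot(inherits(coeffs, "lambert_beer"))
  check_nonneg(biomass, "biomass")
  check_nonneg(depth, "depth")
  exp(-depth * (coeffs$extinction * biomass * .BIOMASS_TO_M3 + coeffs$background))
}

#' Cornet two-flux transmittance
#'
#' Transmittance of a flat slab under the two-flux model,
#' \deqn{I/I_0 = 4\alpha_1 / ((1+\alpha_1)^2 e^{\alpha_2} -
#'       (1-\alpha_1)^2 e^{-\alpha_2})}
#' with \eqn{\alpha_1 = \sqrt{Ea/(Ea+Es)}} and
#' \eqn{\alpha_2 = (Ea+Es)\,\alpha_1 X L} (biomass converted g/L to g/m^3).
#' Evaluated in the overflow-safe form
#' \code{4*a1*exp(-a2) / ((1+a1)^2 - (1-a1)^2*exp(-2*a2))}, stable for
#' optically thick cultures (a2 of several hundred).
#'
#' @inheritParams lambert_beer_transmittance
#' @param coeffs a \code{\link{cornet_coefficients}} object.
#' @return transmittance in (0, 1].
#' @examples
#' cn <- cornet_coefficients(0.023, 0.749)
#' cornet_transmittance(cn, biomass = 0.25, depth = 0.025)
#' @export
cornet_transmittance <- function(coeffs, biomass, depth) {
  stopifnot(inherits(coeffs, "cornet"))
  check_nonneg(biomass, "biomass")
  check_nonneg(depth, "depth")
  ea <- coeffs$absorption
  es <- coeffs$scattering
  a1 <- sqrt(ea / (ea + es))
  a2 <- (ea + es) * a1 * biomass * .BIOMASS_TO_M3 * depth
  tau <- 4 * a1 * exp(-a2) / ((1 + a1)^2 - (1 - a1)^2 * exp(-2 * a2))
  # depth = 0 (or biomass = 0) gives a2 = 0 and the expression reduces to 1
  # algebraically; force exactness against rounding
  tau[a2 == 0] <- 1
  tau
}

#' Transmittance under either attenuation model
#'
#' @param coeffs \code{lambert_beer} or \code{cornet} coefficients; the model
#'   is dispatched on the class.
#' @param biomass biomass concentration, g/L.
#' @param depth optical path, m.
#' @return transmittance in (0, 1].
#' @export
transmittance <- function(coeffs, biomass, depth) {
  if (inherits(coeffs, "lambert_beer")) {
    lambert_beer_transmittance(coeffs, biomass, depth)
  } else if (inherits(coeffs, "cornet")) {
    cornet_transmittance(coeffs, biomass, depth)
  } else {
    stop_domain("`coeffs` must be lambert_beer or cornet coefficients")
  }
}

#' Local light intensity profile with depth
#'
#' @param coeffs attenuation coefficients (either model).
#' @param incident incident photon flux I0, umol photons m^-2 s^-1.
#' @param biomass biomass concentration, g/L.
#' @param depths sorted non-negative depths, m.
#' @return numeric vector of local intensities, one per depth.
#' @examples
#' lb <- lambert_beer_coefficients(0.08, 1.28)
#' intensity_profile(lb, incident = 400, biomass = 0.5,
#'                   depths = c(0, 0.025, 0.05, 0.1))
#' @export
intensity_profile <- function(coeffs, incident, biomass, depths) {
  check_nonneg(incident, "incident")
  if (is.unsorted(depths)) stop_domain("`depths` must be sorted ascending")
  incident * transmittance(coeffs, biomass, depths)
}

#' Read attenuation observations from CSV
#'
#' Expects a header with columns \code{biomass_g_per_L, depth_m,
#' incident_umol_m2_s, local_umol_m2_s}; lines starting with \code{#} are
#' treated as comments.
#'
#' @param path file path.
#' @return data.frame of observations, validated (non-negative biomass,
#'   positive depth, 0 <= local <= incident).
#' @export
read_attenuation_csv <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("input file not found: %s", path))
  obs <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  needed <- c("biomass_g_per_L", "depth_m", "incident_umol_m2_s", "local_umol_m2_s")
  missing <- setdiff(needed, names(obs))
  if (length(missing)) {
    stop_domain(paste("attenuation CSV lacks columns:", paste(missing, collapse = ", ")))
  }
  check_nonneg(obs$biomass_g_per_L, "biomass_g_per_L")
  check_pos(obs$depth_m, "depth_m")
  if (any(obs$local_umol_m2_s < 0) || any(obs$local_umol_m2_s > obs$incident_umol_m2_s)) {
    stop_domain("local intensity must lie in [0, incident]")
  }
  obs
}
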