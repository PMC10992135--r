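.extdata <- function(name) {
  path <- system.file("extdata", name, package = "photodose")
  if (!nzchar(path)) stop_domain(sprintf("bundled fixture %s not found", name))
  path
}

#' Bundled optical-coefficient-versus-pigment table
#'
#' Lambert-Beer extinction (Ka) and Cornet absorption/scattering (Ea, Es)
#' coefficients of Dunaliella salina suspensions at six cellular
#' beta-carotene contents, with standard deviations (n = 3).
#'
#' @return data.frame with columns \code{bcar_content_pct, ka, ka_sd, ea,
#'   ea_sd, es, es_sd}.
#' @export
table1_fixture <- function() {
  utils::read.csv(.extdata("table1.csv"), comment.char = "#")
}

#' Bundled APRPC dose table
#'
#' Published photon doses (umol photons per cell) for six constant average
#' irradiances by six induction times, with standard deviations (n = 3).
#'
#' @return long data.frame with columns \code{iav, hours, aprpc, sd}.
#' @export
table2_fixture <- function() {
  utils::read.csv(.extdata("table2.csv"), comment.char = "#")
}

#' Bundled attenuation observations
#'
#' Nine measured local light intensities at incident flux 400
#' umol photons m^-2 s^-1 (biomass 0.25, 0.50, 1.50 g/L by light paths
#' 0.025, 0.05, 0.10 m), reconstructed from the reported percentage
#' reductions and direct intensities.
#'
#' @return data.frame in the attenuation-CSV layout
#'   (\code{biomass_g_per_L, depth_m, incident_umol_m2_s, local_umol_m2_s}).
#' @export
attenuation_fixture <- function() {
  utils::read.csv(.extdata("attenuation_points.csv"), comment.char = "#")
}
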