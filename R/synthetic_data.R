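#' Calibrate a Hill-type photon-dose response for beta-carotene content
#'
#' Carotenogenesis in Dunaliella salina saturates with cumulative photon
#' dose. The generator models cellular beta-carotene content (percent of dry
#' weight) as a Hill curve of the dose d,
#' \deqn{content(d) = \beta_0 + (\beta_{max}-\beta_0)\,
#'       \frac{d^n}{d^n + K^n},}
#' and solves (n, K) so that two anchor points hold exactly: the content
#' doubles at the trigger dose, and reaches 95 % of the plateau rise at the
#' saturation dose. The closed-form solution comes from inverting
#' \eqn{f(d) = 1/(1 + (K/d)^n)} at the two anchors.
#'
#' Defaults are the study conditions: baseline 0.70 %, plateau 7.24 %,
#' trigger 0.7 and saturation 9.9 umol photons per cell.
#'
#' @param baseline initial beta-carotene content, percent DW.
#' @param plateau asymptotic content, percent DW; must exceed 2*baseline.
#' @param trigger_dose dose at which content = 2*baseline, umol photons/cell.
#' @param saturation_dose dose at which content = baseline + 0.95 * rise;
#'   must exceed \code{trigger_dose}.
#' @return object of class \code{response_law} with fields \code{baseline},
#'   \code{plateau}, \code{hill_n}, \code{hill_k}, \code{trigger_dose},
#'   \code{saturation_dose}.
#' @examples
#' law <- calibrate_response()
#' response_content(law, c(0, 0.7, 9.9))
#' @export
calibrate_response <- function(baseline = 0.70, plateau = 7.24,
                               trigger_dose = 0.7, saturation_dose = 9.9) {
  check_pos(baseline, "baseline")
  check_pos(trigger_dose, "trigger_dose")
  if (plateau <= 2 * baseline) {
    stop_domain("`plateau` must exceed twice `baseline` for a doubling point to exist")
  }
  if (saturation_dose <= trigger_dose) {
    stop_domain("`saturation_dose` must exceed `trigger_dose`")
  }
  rise <- plateau - baseline
  f_trig <- baseline / rise          # fractional rise at the trigger dose
  f_sat <- 0.95
  if (f_trig >= f_sat) stop_domain("anchor fractions out of order; infeasible calibration")
  # f(d) = 1/(1+(K/d)^n)  =>  n*(log K - log d) = log(1/f - 1)
  g1 <- log(1 / f_trig - 1)
  g2 <- log(1 / f_sat - 1)
  n <- (g1 - g2) / (log(saturation_dose) - log(trigger_dose))
  K <- exp(log(trigger_dose) + g1 / n)
  structure(list(
    baseline = baseline, plateau = plateau, hill_n = n, hill_k = K,
    trigger_dose = trigger_dose, saturation_dose = saturation_dose
  ), class = "response_law")
}

#' Evaluate a dose-response law
#'
#' @param law a \code{\link{calibrate_response}} object.
#' @param dose cumulative photon dose, umol photons per cell (>= 0,
#'   vectorised).
#' @return beta-carotene content, percent of dry weight; strictly
#'   increasing in dose, \code{baseline} at zero, bounded by \code{plateau}.
#' @export
response_content <- function(law, dose) {
  stopifnot(inherits(law, "response_law"))
  check_nonneg(dose, "dose")
  frac <- ifelse(dose == 0, 0,
                 1 / (1 + (law$hill_k / dose)^law$hill_n))
  law$baseline + (law$plateau - law$baseline) * frac
}

#' @export
print.response_law <- function(x, ...) {
  cat(sprintf(
    "Hill dose-response: baseline %.2f%%, plateau %.2f%%, n = %.3f, K = %.3f\n",
    x$baseline, x$plateau, x$hill_n, x$hill_k
  ))
  cat(sprintf("  doubling at %.2f, 95%% rise at %.2f umol photons/cell\n",
              x$trigger_dose, x$saturation_dose))
  invisible(x)
}

# mean-one lognormal multiplier with coefficient of variation cv
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate a synthetic light-attenuation dataset
#'
#' Emulates the attenuation measurements: for every combination of biomass
#' level and light path the local intensity is the model prediction times a
#' mean-one lognormal error of coefficient of variation \code{cv},
#' replicated \code{replicates} times (the study measured in triplicate).
#' Defaults mirror the measurement design: incident flux 400
#' umol photons m^-2 s^-1, biomass 0.10-1.5 g/L, paths 0.025/0.05/0.10 m.
#'
#' @param coeffs attenuation coefficients (\code{lambert_beer} or
#'   \code{cornet}).
#' @param biomass_levels biomass concentrations, g/L.
#' @param depths light paths, m.
#' @param incident incident photon flux, umol photons m^-2 s^-1.
#' @param cv multiplicative noise coefficient of variation (0 = noiseless).
#' @param replicates replicates per condition.
#' @param seed integer seed; generation is reproducible given the seed.
#' @return data.frame in the attenuation-CSV column layout.
#' @export
generate_attenuation_dataset <- function(coeffs,
                                         biomass_levels = c(0.10, 0.25, 0.50, 0.75, 1.0, 1.5),
                                         depths = c(0.025, 0.05, 0.10),
                                         incident = 400,
                                         cv = 0.05, replicates = 3, seed = 1) {
  check_nonneg(cv, "cv")
  grid <- expand.grid(biomass_g_per_L = biomass_levels, depth_m = depths,
                      rep = seq_len(replicates), KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(seed, {
    tau <- transmittance(coeffs, grid$biomass_g_per_L, grid$depth_m)
    eps <- .lognormal_noise(nrow(grid), cv)
    data.frame(
      biomass_g_per_L = grid$biomass_g_per_L,
      depth_m = grid$depth_m,
      incident_umol_m2_s = incident,
      local_umol_m2_s = pmin(incident * tau * eps, incident),
      replicate = grid$rep
    )
  })
}

#' Generate a synthetic induction dose-response experiment
#'
#' Emulates the constant-average-irradiance induction experiments: each
#' (average irradiance, duration) condition receives the photon dose given
#' by the APRPC formula at a fixed cell concentration, and the measured
#' beta-carotene content is the response law at that dose times mean-one
#' lognormal noise, in triplicate. The default grid is the short-term
#' design: irradiances 100-1600 umol photons m^-2 s^-1 and 2-24 h.
#'
#' @param law a \code{\link{calibrate_response}} response law.
#' @param iav_levels average irradiances, umol photons m^-2 s^-1.
#' @param hours induction durations, h.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param cells cell concentration, cells/L (constant over the experiment).
#' @param cv content noise coefficient of variation.
#' @param replicates replicates per condition.
#' @param seed integer seed.
#' @return tidy data.frame with columns \code{iav, hours, replicate, dose,
#'   bcar_pct}.
#' @export
generate_induction_experiment <- function(law,
                                          iav_levels = c(100, 200, 400, 800, 1200, 1600),
                                          hours = c(2, 4, 8, 12, 16, 24),
                                          geometry = reactor_geometry(),
                                          cells = 4.0058e7,
                                          cv = 0.05, replicates = 3, seed = 1) {
  stopifnot(inherits(law, "response_law"))
  check_nonneg(cv, "cv")
  grid <- expand.grid(iav = iav_levels, hours = hours,
                      replicate = seq_len(replicates), KEEP.OUT.ATTRS = FALSE)
  dose <- aprpc(grid$iav, grid$hours * 3600, geometry, cells)
  withr::with_seed(seed, {
    eps <- .lognormal_noise(nrow(grid), cv)
    out <- data.frame(
      iav = grid$iav, hours = grid$hours, replicate = grid$replicate,
      dose = dose, bcar_pct = response_content(law, dose) * eps
    )
    out[order(out$dose, out$replicate), , drop = FALSE]
  })
}

#' Generate the full induction study (short- plus long-term designs)
#'
#' Combines the two experimental designs of the study: the short-term grid
#' (average irradiances 100-1600 umol photons m^-2 s^-1 by 2-24 h) and the
#' long-term grid (50-1200 by 24-144 h), each in triplicate. The long-term
#' conditions reach photon doses of ~20 umol photons/cell and are what
#' makes the saturation of the dose-response observable; the short-term
#' grid alone stops at 4.4, well below the saturation dose.
#'
#' @inheritParams generate_induction_experiment
#' @return tidy data.frame as \code{\link{generate_induction_experiment}},
#'   with an extra column \code{design} ("short" or "long"), sorted by
#'   dose.
#' @export
generate_induction_study <- function(law, geometry = reactor_geometry(),
                                     cells = 4.0058e7, cv = 0.05,
                                     replicates = 3, seed = 1) {
  short <- generate_induction_experiment(
    law, geometry = geometry, cells = cells, cv = cv,
    replicates = replicates, seed = seed)
  long <- generate_induction_experiment(
    law, iav_levels = c(50, 100, 400, 800, 1200),
    hours = c(24, 48, 72, 96, 120, 144),
    geometry = geometry, cells = cells, cv = cv,
    replicates = replicates, seed = seed + 500000L)
  short$design <- "short"
  long$design <- "long"
  out <- rbind(short, long)
  out[order(out$dose, out$replicate), , drop = FALSE]
}
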