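.coeffs_for <- function(model, bcar_content, laws) {
  k <- coefficient_at_content(bcar_content, laws)
  switch(model,
    lambert_beer = lambert_beer_coefficients(k[["ka"]], 0),
    cornet = cornet_coefficients(k[["ea"]], k[["es"]]),
    stop_domain(sprintf("unknown attenuation model '%s'", model))
  )
}

#' Incident intensity required to hold an average-irradiance setpoint
#'
#' The average irradiance is exactly proportional to the incident flux (the
#' transmittance profile does not depend on I0), so the feedback controller
#' needs no iteration: \code{I0 = setpoint / Iav(I0 = 1)}. Coefficients are
#' taken from the pigment-dependence laws at the current beta-carotene
#' content, so the demanded I0 rises as the culture darkens with
#' carotenoids and biomass.
#'
#' @param iav_target average-irradiance setpoint, umol photons m^-2 s^-1.
#' @param biomass biomass concentration, g/L.
#' @param bcar_content beta-carotene content, percent DW.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param model "cornet" (default) or "lambert_beer".
#' @param laws coefficient laws (default \code{default_coefficient_laws()}).
#' @param i0_max lamp ceiling, umol photons m^-2 s^-1; demands above it are
#'   clamped, with attribute \code{clamped = TRUE} on the result.
#' @return required incident intensity, umol photons m^-2 s^-1.
#' @examples
#' required_incident_intensity(400, biomass = 0, bcar_content = 0,
#'                             geometry = reactor_geometry())
#' @export
required_incident_intensity <- function(iav_target, biomass, bcar_content,
                                        geometry, model = "cornet",
                                        laws = default_coefficient_laws(),
                                        i0_max = 2000) {
  check_pos(iav_target, "iav_target")
  coeffs <- .coeffs_for(model, bcar_content, laws)
  per_unit <- average_irradiance(coeffs, 1, biomass, geometry)
  if (per_unit <= 0 || !is.finite(per_unit)) {
    stop_domain("culture is numerically opaque: setpoint infeasible at any incident flux")
  }
  i0 <- iav_target / per_unit
  clamped <- i0 > i0_max
  if (clamped) i0 <- i0_max
  structure(i0, clamped = clamped)
}

#' Control configuration for a constant-dose induction run
#'
#' @param iav_setpoint average-irradiance setpoint, umol photons m^-2 s^-1.
#' @param duration run length, h.
#' @param geometry a \code{\link{reactor_geometry}}.
#' @param model "cornet" or "lambert_beer".
#' @param laws coefficient-versus-content laws.
#' @param law beta-carotene dose-response law
#'   (\code{\link{calibrate_response}}).
#' @param i0_max lamp ceiling, umol photons m^-2 s^-1.
#' @param dt simulation step, h.
#' @param growth_rate specific biomass growth rate, 1/h.
#' @param cell_growth_rate specific cell-number growth rate, 1/h.
#' @return list of class \code{control_config}.
#' @export
control_config <- function(iav_setpoint, duration,
                           geometry = reactor_geometry(),
                           model = "cornet",
                           laws = default_coefficient_laws(),
                           law = calibrate_response(),
                           i0_max = 2000, dt = 0.1,
                           growth_rate = 0, cell_growth_rate = 0) {
  check_pos(iav_setpoint, "iav_setpoint")
  check_pos(dt, "dt")
  check_pos(i0_max, "i0_max")
  if (duration < dt) stop_domain("`duration` must be at least one step `dt`")
  structure(list(
    iav_setpoint = iav_setpoint, duration = duration, geometry = geometry,
    model = model, laws = laws, law = law, i0_max = i0_max, dt = dt,
    growth_rate = growth_rate, cell_growth_rate = cell_growth_rate
  ), class = "control_config")
}

#' Simulate a feedback-controlled beta-carotene induction run
#'
#' Explicit-Euler closed loop over steps of \code{dt} hours. Each step:
#' (1) the optical coefficients are refreshed from the current
#' beta-carotene content via the pigment-dependence laws; (2) the incident
#' intensity required to hold the average-irradiance setpoint is computed
#' (clamped at the lamp ceiling and flagged); (3) the photon dose accrues
#' incrementally, \code{dAPRPC = Iav * dt * 3600 * S * L * 1000 / C(t)};
#' (4) the beta-carotene content follows the dose-response law at the
#' cumulative dose; (5) biomass and cell number grow exponentially at their
#' configured specific rates. With zero growth and constant cells the final
#' cumulative dose equals the closed-form APRPC exactly.
#'
#' @param config a \code{\link{control_config}}.
#' @param initial list with \code{biomass} (g/L), \code{cells} (cells/L)
#'   and optionally \code{bcar_content} (percent DW; default the response
#'   law baseline) and \code{cumulative_dose} (default 0).
#' @return data.frame of class \code{induction_trace} with one row per step
#'   boundary and columns \code{t_h, X, C, bcar_pct, I0, Iav, aprpc,
#'   clamped}. \code{I0}/\code{Iav} in a row are the values applied over
#'   the step starting there (NA in the final row). The number of clamped
#'   steps is reported via \code{attr(, "n_clamped")}.
#' @examples
#' cfg <- control_config(iav_setpoint = 400, duration = 24)
#' tr <- simulate_induction(cfg, list(biomass = 0.5, cells = 4.0058e7))
#' tail(tr, 1)$aprpc  # 1.10 umol photons/cell
#' @export
simulate_induction <- function(config, initial) {
  stopifnot(inherits(config, "control_config"))
  check_nonneg(initial$biomass, "initial$biomass")
  check_pos(initial$cells, "initial$cells")
  law <- config$law
  bcar <- if (!is.null(initial$bcar_content)) initial$bcar_content else law$baseline
  dose <- if (!is.null(initial$cumulative_dose)) initial$cumulative_dose else 0
  geom <- config$geometry
  n_steps <- floor(config$duration / config$dt + 1e-9)
  times <- seq(0, by = config$dt, length.out = n_steps + 1)
  X <- initial$biomass
  C <- initial$cells
  rows <- vector("list", n_steps + 1)
  n_clamped <- 0L
  for (i in seq_len(n_steps + 1)) {
    if (i <= n_steps) {
      i0 <- required_incident_intensity(config$iav_setpoint, X, bcar, geom,
                                        config$model, config$laws,
                                        config$i0_max)
      clamped <- isTRUE(attr(i0, "clamped"))
      coeffs <- .coeffs_for(config$model, bcar, config$laws)
      iav <- if (clamped) {
        average_irradiance(coeffs, as.numeric(i0), X, geom)
      } else {
        config$iav_setpoint
      }
      if (clamped) n_clamped <- n_clamped + 1L
    } else {
      i0 <- NA_real_; iav <- NA_real_; clamped <- NA
    }
    rows[[i]] <- data.frame(t_h = times[i], X = X, C = C, bcar_pct = bcar,
                            I0 = as.numeric(i0), Iav = iav, aprpc = dose,
                            clamped = clamped)
    if (i <= n_steps) {
      dose <- dose + aprpc(iav, config$dt * 3600, geom, C)
      bcar <- response_content(law, dose)
      X <- X * exp(config$growth_rate * config$dt)
      C <- C * exp(config$cell_growth_rate * config$dt)
    }
  }
  trace <- do.call(rbind, rows)
  attr(trace, "n_clamped") <- n_clamped
  if (n_clamped > 0) {
    warning(sprintf("lamp ceiling reached on %d of %d steps; setpoint not held there",
                    n_clamped, n_steps))
  }
  class(trace) <- c("induction_trace", class(trace))
  trace
}

.aggregate_response <- function(doses, contents) {
  if (length(doses) != length(contents)) stop_domain("doses and contents lengths differ")
  if (length(doses) < 2) stop_domain("need at least 2 dose levels")
  if (is.unsorted(doses)) stop_domain("`doses` must be sorted ascending")
  agg <- tapply(contents, doses, mean)
  list(dose = as.numeric(names(agg)), content = as.numeric(agg))
}

#' Photon dose at which beta-carotene content doubles
#'
#' Scans a dose-response table (replicates at tied doses are averaged) for
#' the smallest dose at which content reaches twice the baseline, linearly
#' interpolating between the bracketing dose levels. This operationalises
#' the study's criterion for "significant" accumulation.
#'
#' @param doses photon doses, umol photons per cell, sorted ascending.
#' @param contents beta-carotene contents, percent DW, same length.
#' @param baseline initial content, percent DW (default 0.70).
#' @return trigger dose, or \code{NA_real_} if the doubling level is never
#'   reached.
#' @export
detect_trigger_threshold <- function(doses, contents, baseline = 0.70) {
  check_pos(baseline, "baseline")
  r <- .aggregate_response(doses, contents)
  target <- 2 * baseline
  hit <- which(r$content >= target)
  if (!length(hit)) return(NA_real_)
  j <- hit[1]
  if (j == 1) return(r$dose[1])
  d0 <- r$dose[j - 1]; d1 <- r$dose[j]
  c0 <- r$content[j - 1]; c1 <- r$content[j]
  d0 + (target - c0) / (c1 - c0) * (d1 - d0)
}

#' Fit a Hill dose-response to observed contents
#'
#' Bounded nonlinear least squares for
#' \code{content = baseline + (plateau - baseline) * d^n / (d^n + K^n)},
#' multi-started over plausible (n, K). Used by the saturation detector and
#' available directly for dose-response analysis.
#'
#' @param doses photon doses, umol photons per cell.
#' @param contents beta-carotene contents, percent DW.
#' @return a \code{photodose_fit} with parameters \code{baseline, plateau,
#'   hill_n, hill_k} and a \code{law} element (a \code{response_law}-shaped
#'   list evaluable by \code{\link{response_content}}).
#' @export
fit_hill_response <- function(doses, contents) {
  if (length(doses) != length(contents)) stop_domain("doses and contents lengths differ")
  if (length(unique(doses)) < 4) stop_domain("need >= 4 distinct dose levels")
  check_nonneg(doses, "doses")
  d <- doses; y <- contents
  hill <- function(p) {
    frac <- ifelse(d == 0, 0, 1 / (1 + (p[4] / d)^p[3]))
    p[1] + (p[2] - p[1]) * frac
  }
  resid_fn <- function(p) y - hill(p)
  ylo <- max(min(y), 1e-6); yhi <- max(y)
  starts <- list()
  for (n0 in c(1, 2, 4)) {
    for (k0 in c(median(d[d > 0]), max(d) / 2, max(d))) {
      starts[[length(starts) + 1]] <-
        c(baseline = ylo, plateau = yhi * 1.1, n = n0, K = k0)
    }
  }
  fit <- .multi_start_lm(resid_fn, starts,
                         lower = c(1e-8, 1e-8, 0.05, 1e-6),
                         upper = c(yhi, 10 * yhi, 20, 1e4))
  p <- setNames(fit$par, c("baseline", "plateau", "hill_n", "hill_k"))
  law <- structure(list(baseline = p[["baseline"]], plateau = p[["plateau"]],
                        hill_n = p[["hill_n"]], hill_k = p[["hill_k"]],
                        trigger_dose = NA_real_, saturation_dose = NA_real_),
                   class = "response_law")
  new_fit_report("Hill dose-response", p,
                 se = setNames(.lm_se(fit), names(p)),
                 observed = y, fitted = y - resid_fn(fit$par),
                 extra = list(law = law))
}

#' Photon dose at which beta-carotene accumulation saturates
#'
#' Fits the Hill dose-response and returns the smallest dose reaching 95 %
#' of the fitted plateau rise, \code{K * 19^(1/n)} in closed form (95 % is
#' the package's operational definition of saturation; configurable via
#' \code{rise_fraction}). Returns the not-reached sentinel \code{NA_real_}
#' when the response does not saturate: fit failure, or a fitted saturation
#' dose implausibly far (more than \code{extrapolation_limit} times) beyond
#' the largest observed dose, as happens for linear dose-response data.
#'
#' @inheritParams detect_trigger_threshold
#' @param rise_fraction fraction of the fitted plateau rise defining
#'   saturation (default 0.95).
#' @param extrapolation_limit saturation doses beyond this multiple of
#'   \code{max(doses)} are treated as not reached (default 10).
#' @return saturation dose, umol photons per cell, or \code{NA_real_}.
#' @export
detect_saturation_threshold <- function(doses, contents, rise_fraction = 0.95,
                                        extrapolation_limit = 10) {
  if (is.unsorted(doses)) stop_domain("`doses` must be sorted ascending")
  if (rise_fraction <= 0 || rise_fraction >= 1) {
    stop_domain("`rise_fraction` must be in (0, 1)")
  }
  fit <- tryCatch(fit_hill_response(doses, contents), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  n <- fit$parameters[["hill_n"]]; K <- fit$parameters[["hill_k"]]
  d_sat <- K * (rise_fraction / (1 - rise_fraction))^(1 / n)
  if (!is.finite(d_sat) || d_sat > extrapolation_limit * max(doses)) {
    return(NA_real_)
  }
  d_sat
}
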