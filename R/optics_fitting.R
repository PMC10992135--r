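#' @importFrom stats lm coef cor var sd median setNames uniroot vcov
NULL

new_fit_report <- function(model, parameters, se = NULL, observed = NULL,
                           fitted = NULL, extra = list()) {
  residuals <- if (!is.null(observed)) observed - fitted else NULL
  sst <- if (!is.null(observed)) sum((observed - mean(observed))^2) else NA_real_
  sse <- if (!is.null(residuals)) sum(residuals^2) else NA_real_
  r2 <- if (is.finite(sst) && sst > 0) 1 - sse / sst else NA_real_
  rep <- c(list(
    model = model,
    parameters = parameters,
    se = se,
    r_squared = r2,
    pearson = if (!is.null(observed) && sd(observed) > 0 && sd(fitted) > 0)
      cor(observed, fitted) else NA_real_,
    spearman = if (!is.null(observed) && sd(observed) > 0 && sd(fitted) > 0)
      cor(observed, fitted, method = "spearman") else NA_real_,
    residuals = residuals,
    fitted = fitted,
    sse = sse
  ), extra)
  structure(rep, class = "photodose_fit")
}

#' @export
print.photodose_fit <- function(x, ...) {
  cat(sprintf("%s fit\n", x$model))
  p <- x$parameters
  se <- if (is.null(x$se)) rep(NA_real_, length(p)) else x$se
  for (i in seq_along(p)) {
    cat(sprintf("  %-10s %.6g", names(p)[i], p[i]))
    if (is.finite(se[i])) cat(sprintf("  (SE %.3g)", se[i]))
    cat("\n")
  }
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

# bounded Levenberg-Marquardt with multi-start; returns best nls.lm fit
.multi_start_lm <- function(resid_fn, starts, lower, upper = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop_domain("nonlinear fit failed to converge from any start")
  best
}

.lm_se <- function(fit) {
  out <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) NULL)
  if (is.null(out)) rep(NA_real_, length(fit$par)) else unname(out)
}

.check_attenuation_design <- function(obs) {
  stopifnot(is.data.frame(obs))
  if (nrow(obs) < 3) stop_domain("need at least 3 attenuation observations")
  design <- unique(obs[, c("biomass_g_per_L", "depth_m")])
  if (nrow(design) < 2 || length(unique(obs$biomass_g_per_L)) < 2) {
    stop_domain("degenerate design: need >= 2 distinct biomass levels")
  }
}

#' Fit the Lambert-Beer attenuation model
#'
#' Bounded least squares of local intensity on the Lambert-Beer prediction
#' \code{I0 * exp(-L*(Ka*X*1000 + b))}, minimising the intensity-scale sum
#' of squares (matching how such fits are usually reported, with R^2 on I).
#' A log-linear regression of \code{log(I/I0)} provides the starting point.
#'
#' @param obs data.frame of attenuation observations with columns
#'   \code{biomass_g_per_L, depth_m, incident_umol_m2_s, local_umol_m2_s}
#'   (see \code{\link{read_attenuation_csv}}).
#' @param log_space if TRUE, minimise residuals of log intensities instead
#'   (observations with zero local intensity are dropped with a warning).
#' @return a \code{photodose_fit} with parameters \code{extinction} (Ka,
#'   m^2/g) and \code{background} (b, 1/m), asymptotic SEs, R^2 on
#'   intensities, and residuals.
#' @export
fit_lambert_beer <- function(obs, log_space = FALSE) {
  .check_attenuation_design(obs)
  X <- obs$biomass_g_per_L; L <- obs$depth_m
  I0 <- obs$incident_umol_m2_s; I <- obs$local_umol_m2_s
  # log-linear seed: -log(I/I0) = L*(1000*Ka*X + b)
  keep <- I > 0
  seed <- c(extinction = 0.05, background = 0.5)
  if (sum(keep) >= 3) {
    y <- -log(I[keep] / I0[keep])
    sfit <- tryCatch(lm(y ~ 0 + I(L[keep] * X[keep] * 1000) + L[keep]),
                     error = function(e) NULL)
    if (!is.null(sfit)) {
      cf <- pmax(coef(sfit), 0)
      seed <- c(extinction = unname(cf[1]), background = unname(cf[2]))
    }
  }
  if (log_space) {
    if (any(!keep)) {
      warning("dropping observations with zero local intensity for log-space fit")
      X <- X[keep]; L <- L[keep]; I0 <- I0[keep]; I <- I[keep]
    }
    resid_fn <- function(p) log(I) - log(I0) + L * (p[1] * X * 1000 + p[2])
  } else {
    resid_fn <- function(p) I - I0 * exp(-L * (p[1] * X * 1000 + p[2]))
  }
  fit <- .multi_start_lm(resid_fn,
                         starts = list(seed, c(extinction = 0.08, background = 1.0)),
                         lower = c(0, 0))
  p <- setNames(fit$par, c("extinction", "background"))
  cf <- lambert_beer_coefficients(p[["extinction"]], p[["background"]])
  fitted <- obs$incident_umol_m2_s *
    lambert_beer_transmittance(cf, obs$biomass_g_per_L, obs$depth_m)
  new_fit_report("Lambert-Beer", p, se = setNames(.lm_se(fit), names(p)),
                 observed = obs$local_umol_m2_s, fitted = fitted,
                 extra = list(coefficients = cf))
}

#' Fit the Cornet two-flux attenuation model
#'
#' Bounded least squares of local intensity on the two-flux transmittance.
#' The SSE surface can be nearly flat in the scattering coefficient at low
#' optical depth, so the optimiser is multi-started from a coarse
#' (Ea, Es) grid plus a pure-absorption seed taken from a log-linear
#' regression, keeping the best deviance.
#'
#' @inheritParams fit_lambert_beer
#' @return a \code{photodose_fit} with parameters \code{absorption} (Ea)
#'   and \code{scattering} (Es), both m^2/g.
#' @export
fit_cornet <- function(obs) {
  .check_attenuation_design(obs)
  if (all(obs$local_umol_m2_s == 0)) {
    stop_domain("all local intensities are zero: transmittance uninformative")
  }
  X <- obs$biomass_g_per_L; L <- obs$depth_m
  I0 <- obs$incident_umol_m2_s; I <- obs$local_umol_m2_s
  resid_fn <- function(p) {
    cf <- list(absorption = p[1], scattering = p[2])
    class(cf) <- c("cornet", "optical_coefficients")
    I - I0 * cornet_transmittance(cf, X, L)
  }
  starts <- list()
  for (ea in c(0.01, 0.05, 0.2)) {
    for (es in c(0.1, 0.5, 1.0)) {
      starts[[length(starts) + 1]] <- c(absorption = ea, scattering = es)
    }
  }
  keep <- I > 0
  if (sum(keep) >= 3) {
    y <- -log(I[keep] / I0[keep])
    sfit <- tryCatch(lm(y ~ 0 + I(L[keep] * X[keep] * 1000)),
                     error = function(e) NULL)
    if (!is.null(sfit)) {
      starts[[length(starts) + 1]] <-
        c(absorption = max(coef(sfit)[[1]], 1e-4), scattering = 1e-3)
    }
  }
  fit <- .multi_start_lm(resid_fn, starts, lower = c(1e-8, 0))
  p <- setNames(fit$par, c("absorption", "scattering"))
  cf <- cornet_coefficients(p[["absorption"]], p[["scattering"]])
  fitted <- I0 * cornet_transmittance(cf, X, L)
  new_fit_report("Cornet two-flux", p, se = setNames(.lm_se(fit), names(p)),
                 observed = I, fitted = fitted,
                 extra = list(coefficients = cf))
}

#' Ordinary least-squares line with correlation statistics
#'
#' Simple linear regression \code{y = intercept + slope * x} via
#' \code{stats::lm}, reporting R^2 and both Pearson and Spearman
#' correlations of y with x. Used for the linear pigment-dependence laws of
#' the extinction and scattering coefficients.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return a \code{photodose_fit} with parameters \code{intercept} and
#'   \code{slope}; \code{pearson}/\code{spearman} are the correlations of y
#'   with x (signed, unlike the generic observed-vs-fitted report).
#' @examples
#' t1 <- table1_fixture()
#' fit_linear(t1$bcar_content_pct, t1$ka)
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (length(x) < 3) stop_domain("need n >= 3")
  if (var(x) == 0) stop_domain("zero variance in x")
  m <- lm(y ~ x)
  p <- c(intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]))
  se <- suppressWarnings(sqrt(diag(vcov(m))))  # silences the perfect-fit note
  rep <- new_fit_report("linear (OLS)", p, se = setNames(se, names(p)),
                        observed = y, fitted = unname(m$fitted.values))
  # for a straight line report the signed x-y correlations, which is what
  # the coefficient-vs-pigment laws quote
  rep$pearson <- correlation(x, y, "pearson")
  rep$spearman <- correlation(x, y, "spearman")
  rep
}

#' Fit a shifted exponential decay
#'
#' Bounded nonlinear least squares for \code{y = a + b * exp(-c * x)} with
#' a, b, c >= 0, the form of the absorption-coefficient dependence on
#' beta-carotene content. Multi-started around \code{init} and a
#' data-driven seed (a = min(y), b = range, c = 1/mean(x)).
#'
#' @param x,y numeric vectors, length >= 4.
#' @param init optional named start, c(a=, b=, c=).
#' @return a \code{photodose_fit} with parameters a, b, c.
#' @export
fit_exp_decay <- function(x, y, init = NULL) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (length(x) < 4) stop_domain("need n >= 4")
  resid_fn <- function(p) y - (p[1] + p[2] * exp(-p[3] * x))
  starts <- list(
    c(a = max(min(y), 1e-6), b = max(diff(range(y)), 1e-6),
      c = 1 / max(mean(x), 1e-6)),
    c(a = 0.5 * mean(y), b = 0.5 * mean(y), c = 1),
    c(a = 1e-3, b = max(y), c = 0.1)
  )
  if (!is.null(init)) starts <- c(list(setNames(as.numeric(init), NULL)), starts)
  fit <- .multi_start_lm(resid_fn, starts, lower = c(0, 0, 0))
  p <- setNames(fit$par, c("a", "b", "c"))
  new_fit_report("exponential decay", p, se = setNames(.lm_se(fit), names(p)),
                 observed = y, fitted = y - resid_fn(fit$par))
}

#' Pearson or Spearman correlation
#'
#' Thin wrapper over \code{stats::cor} that signals constant input instead
#' of returning NA.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param method "pearson" or "spearman".
#' @return correlation coefficient in [-1, 1].
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (length(x) < 3) stop_domain("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop_domain("correlation undefined for constant input")
  cor(x, y, method = method)
}

#' Default pigment-dependence laws for the optical coefficients
#'
#' The package default coefficient laws, as fitted to the published
#' coefficient-versus-content table:
#' \itemize{
#'   \item \code{Ka = 0.0466 + 0.0029 * x} (extinction, m^2/g)
#'   \item \code{Es = 0.70 + 0.06 * x} (scattering, m^2/g)
#'   \item \code{Ea = 0.02 + 0.05 * exp(-2.62 * x)} (absorption, m^2/g)
#' }
#' with x the cellular beta-carotene content in percent of dry weight.
#' Extinction and scattering rise with carotenoid load while absorption
#' falls, so optically the induced culture scatters ever more strongly.
#'
#' @return a list of class \code{coefficient_laws} with components
#'   \code{ka = c(intercept, slope)}, \code{es = c(intercept, slope)} and
#'   \code{ea = c(a, b, c)} for \code{a + b*exp(-c*x)}.
#' @export
default_coefficient_laws <- function() {
  structure(list(
    ka = c(intercept = 0.0466, slope = 0.0029),
    es = c(intercept = 0.70, slope = 0.06),
    ea = c(a = 0.02, b = 0.05, c = 2.62)
  ), class = "coefficient_laws")
}

#' Optical coefficients at a given beta-carotene content
#'
#' Evaluates the pigment-dependence laws (defaults from
#' \code{\link{default_coefficient_laws}}, or refit values of the same
#' shape) at a cellular beta-carotene content.
#'
#' @param bcar_content beta-carotene content, percent of dry weight (>= 0).
#' @param laws a \code{coefficient_laws} list.
#' @return named numeric vector \code{c(ka, ea, es)}, m^2/g.
#' @examples
#' coefficient_at_content(0)      # intercepts: Ka 0.0466, Ea 0.07, Es 0.70
#' coefficient_at_content(4.26)
#' @export
coefficient_at_content <- function(bcar_content, laws = default_coefficient_laws()) {
  check_nonneg(bcar_content, "bcar_content")
  c(
    ka = unname(laws$ka[1] + laws$ka[2] * bcar_content),
    ea = unname(laws$ea[1] + laws$ea[2] * exp(-laws$ea[3] * bcar_content)),
    es = unname(laws$es[1] + laws$es[2] * bcar_content)
  )
}

#' Refit the three coefficient laws from a coefficient table
#'
#' Given per-content estimates of Ka, Ea and Es (such as the bundled
#' \code{\link{table1_fixture}}), refits the linear laws for Ka and Es and
#' the exponential-decay law for Ea, returning both the fit reports and a
#' \code{coefficient_laws} object usable wherever the defaults are.
#'
#' @param tab data.frame with columns \code{bcar_content_pct, ka, ea, es}.
#' @return list with elements \code{ka_fit}, \code{es_fit}, \code{ea_fit}
#'   (\code{photodose_fit}s) and \code{laws} (\code{coefficient_laws}).
#' @export
fit_coefficient_laws <- function(tab) {
  needed <- c("bcar_content_pct", "ka", "ea", "es")
  if (!all(needed %in% names(tab))) {
    stop_domain(paste("coefficient table needs columns:", paste(needed, collapse = ", ")))
  }
  x <- tab$bcar_content_pct
  ka_fit <- fit_linear(x, tab$ka)
  es_fit <- fit_linear(x, tab$es)
  ea_fit <- fit_exp_decay(x, tab$ea, init = c(a = 0.02, b = 0.05, c = 2.62))
  laws <- structure(list(
    ka = c(intercept = unname(ka_fit$parameters["intercept"]),
           slope = unname(ka_fit$parameters["slope"])),
    es = c(intercept = unname(es_fit$parameters["intercept"]),
           slope = unname(es_fit$parameters["slope"])),
    ea = c(a = unname(ea_fit$parameters["a"]), b = unname(ea_fit$parameters["b"]),
           c = unname(ea_fit$parameters["c"]))
  ), class = "coefficient_laws")
  list(ka_fit = ka_fit, es_fit = es_fit, ea_fit = ea_fit, laws = laws)
}
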