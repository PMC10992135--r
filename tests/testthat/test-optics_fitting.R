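table1 <- table1_fixture()

test_that("OLS line equals the textbook closed form and the published regressions", {
  x <- table1$bcar_content_pct
  for (col in c("ka", "es")) {
    y <- table1[[col]]
    fit <- fit_linear(x, y)
    # closed-form oracle: slope = Sxy/Sxx, intercept = ybar - slope*xbar
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(unname(fit$parameters["slope"]), slope, tolerance = 1e-12)
    expect_equal(unname(fit$parameters["intercept"]), intercept, tolerance = 1e-12)
    # Pearson^2 equals R^2 for a simple linear fit
    expect_equal(fit$pearson^2, fit$r_squared, tolerance = 1e-12)
  }
  ka_fit <- fit_linear(x, table1$ka)
  expect_equal(unname(ka_fit$parameters["slope"]), 0.0029, tolerance = 0.02)
  expect_equal(unname(ka_fit$parameters["intercept"]), 0.0466, tolerance = 1e-3)
  expect_equal(ka_fit$r_squared, 0.98, tolerance = 0.01)
  expect_equal(ka_fit$pearson, 0.99, tolerance = 0.005)
  es_fit <- fit_linear(x, table1$es)
  expect_equal(unname(es_fit$parameters["intercept"]), 0.697, tolerance = 1e-3)
  expect_equal(es_fit$pearson, 0.981, tolerance = 1e-3)
  expect_equal(fit_linear(1:5, 2 * (1:5))$parameters,
               c(intercept = 0, slope = 2), tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 4), 1:4), "variance")
})

test_that("correlations reproduce the published values and obvious limits", {
  x <- table1$bcar_content_pct
  expect_equal(correlation(x, table1$ea, "pearson"), -0.820, tolerance = 1e-3)
  # Ka rises strictly with content, so its rank correlation is exactly one
  expect_equal(correlation(x, table1$ka, "spearman"), 1, tolerance = 1e-12)
  expect_equal(correlation(1:10, -(1:10), "pearson"), -1, tolerance = 1e-12)
  expect_error(correlation(rep(1, 5), 1:5), "constant")
})

test_that("exponential-decay fit recovers exact data and describes the absorption trend", {
  x <- table1$bcar_content_pct
  y_exact <- 0.02 + 0.05 * exp(-2.62 * x)
  fit <- fit_exp_decay(x, y_exact)
  expect_equal(unname(fit$parameters), c(0.02, 0.05, 2.62), tolerance = 1e-6)
  # observed absorption coefficients: fitted curve passes near the first row
  ea_fit <- fit_exp_decay(x, table1$ea, init = c(a = 0.02, b = 0.05, c = 2.62))
  at_056 <- ea_fit$parameters["a"] +
    ea_fit$parameters["b"] * exp(-ea_fit$parameters["c"] * 0.56)
  expect_equal(unname(at_056), 0.0316, tolerance = 0.01)
  # constant data: decay amplitude collapses, offset takes the mean
  cfit <- fit_exp_decay(1:6, rep(3, 6))
  expect_lt(unname(cfit$parameters["b"]) *
              exp(-unname(cfit$parameters["c"])), 1e-4)
  expect_equal(mean(cfit$fitted), 3, tolerance = 1e-6)
  expect_error(fit_exp_decay(1:3, 1:3), "n >= 4")
})

test_that("coefficient laws evaluate the published dependences on carotene content", {
  k0 <- coefficient_at_content(0)
  expect_equal(unname(k0), c(0.0466, 0.07, 0.70), tolerance = 1e-12)
  k4 <- coefficient_at_content(4.26)
  expect_equal(unname(k4["ka"]), 0.0466 + 0.0029 * 4.26, tolerance = 1e-12)
  expect_equal(unname(k4["es"]), 0.9556, tolerance = 1e-4)
  expect_equal(unname(k4["ea"]), 0.02 + 0.05 * exp(-2.62 * 4.26), tolerance = 1e-12)
  expect_equal(unname(coefficient_at_content(1.93)["ka"]), 0.0522,
               tolerance = 1e-3)  # observed 0.0519 at that content
  # monotonicity over the induction range: Ka, Es rise, Ea falls
  grid <- t(sapply(seq(0, 10, by = 0.5), coefficient_at_content))
  expect_true(all(diff(grid[, "ka"]) > 0))
  expect_true(all(diff(grid[, "es"]) > 0))
  expect_true(all(diff(grid[, "ea"]) < 0))
  expect_error(coefficient_at_content(-1), "non-negative")
})

test_that("refitting the three laws from the coefficient table matches the defaults' shape", {
  fits <- fit_coefficient_laws(table1)
  expect_equal(unname(fits$laws$ka), c(0.0466, 0.0029), tolerance = 0.02)
  expect_equal(unname(fits$laws$es["intercept"]), 0.70, tolerance = 0.01)
  expect_gt(fits$ka_fit$r_squared, 0.95)
  k <- coefficient_at_content(1.0, laws = fits$laws)
  expect_true(all(k > 0))
  expect_error(fit_coefficient_laws(table1[, 1:2]), "columns")
})

test_that("Lambert-Beer fitting round-trips noiseless data and matches a log-space oracle", {
  d <- generate_attenuation_dataset(lb_printed, cv = 0, seed = 1)
  fit <- fit_lambert_beer(d)
  expect_equal(unname(fit$parameters), c(0.08, 1.28), tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # b = 0 single exponential: extinction equals the log-linear slope / 1000L
  d0 <- generate_attenuation_dataset(lambert_beer_coefficients(0.05, 0),
                                     cv = 0, seed = 1)
  fit0 <- fit_lambert_beer(d0)
  slope <- coef(lm(-log(d0$local_umol_m2_s / d0$incident_umol_m2_s) ~
                     0 + I(d0$biomass_g_per_L * d0$depth_m)))[[1]]
  expect_equal(unname(fit0$parameters["extinction"]), slope / 1000,
               tolerance = 1e-6)
  expect_lt(unname(fit0$parameters["background"]), 1e-6)
  one <- d[d$biomass_g_per_L == 0.5 & d$depth_m == 0.025, ]
  expect_error(fit_lambert_beer(one), "degenerate")
})

test_that("Cornet fitting round-trips noiseless data and detects the Beer limit", {
  d <- generate_attenuation_dataset(cornet_printed, cv = 0, seed = 1)
  fit <- fit_cornet(d)
  expect_equal(unname(fit$parameters), c(0.023, 0.749), tolerance = 1e-5)
  # pure absorption: scattering pinned at its boundary
  d0 <- generate_attenuation_dataset(cornet_coefficients(0.05, 0), cv = 0,
                                     seed = 1)
  fit0 <- fit_cornet(d0)
  expect_equal(unname(fit0$parameters["absorption"]), 0.05, tolerance = 1e-3)
  expect_lt(unname(fit0$parameters["scattering"]), 1e-4)
  dz <- d; dz$local_umol_m2_s <- 0
  expect_error(fit_cornet(dz), "zero")
})

test_that("Cornet estimates stay accurate under measurement noise", {
  # triplicate full-design study, 5 % multiplicative noise, 50 seeds
  errs <- sapply(1:50, function(s) {
    d <- generate_attenuation_dataset(cornet_printed, cv = 0.05, seed = s)
    f <- fit_cornet(d)
    abs(f$parameters - c(0.023, 0.749)) / c(0.023, 0.749)
  })
  med <- apply(errs, 1, median)
  expect_lt(med[["absorption"]], 0.10)
  expect_lt(med[["scattering"]], 0.10)
})

test_that("fits on the nine published attenuation points describe them well", {
  fix <- attenuation_fixture()
  flb <- fit_lambert_beer(fix)
  fcn <- fit_cornet(fix)
  expect_gt(flb$r_squared, 0.9)
  expect_gt(fcn$r_squared, 0.9)
  expect_true(all(flb$parameters >= 0))
  expect_true(all(fcn$parameters > 0))
  # the published parameters themselves also describe these points
  pred <- fix$incident_umol_m2_s *
    lambert_beer_transmittance(lb_printed, fix$biomass_g_per_L, fix$depth_m)
  expect_gt(r_squared(fix$local_umol_m2_s, pred), 0.9)
})
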