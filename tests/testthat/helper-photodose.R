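# Shared fixtures: the study geometry and the published model parameters.
geom_study <- reactor_geometry(light_path = 0.025, illuminated_area = 0.051)
lb_printed <- lambert_beer_coefficients(extinction = 0.08, background = 1.28)
cornet_printed <- cornet_coefficients(absorption = 0.023, scattering = 0.749)
cells_study <- 4.0058e7  # cells/L consistent with the published dose table

# Plain two-flux transmittance, written from the defining equations without
# the overflow-safe rearrangement; oracle for cornet_transmittance().
cornet_naive <- function(ea, es, biomass, depth) {
  a1 <- sqrt(ea / (ea + es))
  a2 <- (ea + es) * a1 * biomass * 1000 * depth
  4 * a1 / ((1 + a1)^2 * exp(a2) - (1 - a1)^2 * exp(-a2))
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}
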