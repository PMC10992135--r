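# photodose

Photon-dose modelling of light-induced β-carotene accumulation in the
halotolerant green alga *Dunaliella salina*.

During the "red" induction stage, *D. salina* turns excess light into
β-carotene. How much light a cell has actually received, however, is hard to
state from the incident flux alone: light decays steeply with depth and the
decay itself changes as biomass and pigment build up. `photodose` implements
the quantitative chain that links lamp settings to the photon dose a cell
experiences in a flat-plate photobioreactor (PBR):

1. **Radiative transfer.** Local intensity `I(z)` from either the
   Lambert–Beer law, `I/I₀ = exp(−L·(Kₐ·X·1000 + b))`, or the Cornet
   two-flux model,
   `I/I₀ = 4α₁ / ((1+α₁)²·e^{α₂} − (1−α₁)²·e^{−α₂})` with
   `α₁ = √(Eₐ/(Eₐ+Eₛ))` and `α₂ = (Eₐ+Eₛ)·α₁·X·L`, where `X` is biomass
   (g·L⁻¹, converted to g·m⁻³ internally), `L` the light path (m) and the
   coefficients are in m²·g⁻¹. Scattering matters for *D. salina*: its
   cells are large (15–20 µm) during carotenogenesis.
2. **Pigment-dependent optics.** The coefficients drift with cellular
   β-carotene content `x` (% of dry weight):
   `Kₐ = 0.0466 + 0.0029·x`, `Eₛ = 0.70 + 0.06·x`,
   `Eₐ = 0.02 + 0.05·exp(−2.62·x)` — refittable from data with
   `fit_coefficient_laws()`.
3. **Dosimetry.** Volume-averaged irradiance
   `I_av = (1/L)·∫₀ᴸ I(z) dz` (64-node Gauss–Legendre), and the dose metric
   **APRPC** — average number of photons received per cell —
   `APRPC = I_av·T·S·L·1000/C` (µmol photons·cell⁻¹) for induction time `T`
   (s), illuminated area `S` (m²) and cell concentration `C` (cells·L⁻¹).
4. **Closed-loop induction.** A feedback controller that holds `I_av` at a
   setpoint by raising the incident flux as the culture grows and darkens,
   accruing APRPC incrementally while β-carotene follows a saturating
   (Hill) dose–response.
5. **Threshold recovery.** Detectors for the *trigger dose* (smallest
   APRPC at which content doubles) and the *saturation dose* (95 % of the
   fitted plateau rise), plus a synthetic-data generator for attenuation
   and induction experiments to validate the whole loop.

The package is aimed at algal bioprocess engineers and modellers who want
to design induction protocols (lamp schedules, culture densities, light
paths) on a per-cell photon budget rather than on incident intensity.

## Worked example

```r
library(photodose)

geom <- reactor_geometry(light_path = 0.025, illuminated_area = 0.051)
cn   <- cornet_coefficients(absorption = 0.023, scattering = 0.749)

cornet_transmittance(cn, biomass = 0.25, depth = 0.025)
#> [1] 0.2410218
average_irradiance(cn, incident = 400, biomass = 0.25, geometry = geom)
#> [1] 191.864
aprpc(400, duration = 12 * 3600, geometry = geom, cells = 4.0058e7)
#> [1] 0.5500025
```

A quarter gram per litre of culture already removes three quarters of the
incident light within the first 25 mm, the volume-averaged irradiance is
about half the incident 400 µmol photons·m⁻²·s⁻¹, and holding 400 for 12 h
delivers 0.55 µmol photons to each of the 4.0 × 10⁷ cells per litre.

```r
law <- calibrate_response()
law
#> Hill dose-response: baseline 0.70%, plateau 7.24%, n = 1.912, K = 2.123
#>   doubling at 0.70, 95% rise at 9.90 umol photons/cell

st <- generate_induction_study(law, cv = 0.05, seed = 1)
detect_trigger_threshold(st$dose, st$bcar_pct, baseline = 0.70)
#> [1] 0.7014395
detect_saturation_threshold(st$dose, st$bcar_pct)
#> [1] 9.496045
```

The generator simulates a noisy (5 % CV) constant-irradiance induction
study; the detectors recover the doubling point near 0.70 and the
saturation dose near 9.9 µmol photons·cell⁻¹ from the noisy table alone.

```r
t1 <- table1_fixture()
fit_linear(t1$bcar_content_pct, t1$ka)
#> linear (OLS) fit
#>   intercept  0.0466143  (SE 0.0004)
#>   slope      0.00292928  (SE 0.000172)
#>   R^2 = 0.9865
```

A command-line front end is included as `inst/scripts/photodose`
(subcommands `fit-attenuation`, `fit-coefficients`, `aprpc-table`,
`simulate-induction`, `recover-thresholds`, `make-synthetic`, `pigments`).

## A note on unit conventions

Biomass in g·L⁻¹ is multiplied by 1000 (to g·m⁻³) wherever it meets
m²·g⁻¹ coefficients and metre paths; this is the only convention under
which the published Lambert–Beer fit (`Kₐ = 0.08`, `b = 1.280`) produces
attenuation of the observed magnitude (e.g. a 65 % reduction at 0.5 g·L⁻¹
over 0.025 m). Without the factor the same coefficients would predict
near-transparency. The APRPC formula itself is implemented verbatim, with
the `S·L·1000` product as printed; see the vignette for its dimensional
bookkeeping.

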