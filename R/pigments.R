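#' Chlorophyll a concentration from acetone-extract absorbances
#'
#' \code{11.75 * A665 - 2.35 * A645}, mg/L in the 90 % acetone extract.
#'
#' @param a665,a645 absorbances at 665 and 645 nm (dimensionless, >= 0).
#' @param clip if TRUE, negative results (possible with strongly
#'   chlorophyll-b-dominated extracts) are clipped to zero; by default they
#'   are returned raw with a warning.
#' @return chlorophyll a concentration, mg/L.
#' @export
chlorophyll_a <- function(a665, a645, clip = FALSE) {
  check_nonneg(a665, "a665"); check_nonneg(a645, "a645")
  .maybe_clip(11.75 * a665 - 2.35 * a645, clip, "chlorophyll a")
}

#' Chlorophyll b concentration from acetone-extract absorbances
#'
#' \code{18.61 * A645 - 3.96 * A665}, mg/L in the extract.
#'
#' @inheritParams chlorophyll_a
#' @return chlorophyll b concentration, mg/L.
#' @export
chlorophyll_b <- function(a645, a665, clip = FALSE) {
  check_nonneg(a665, "a665"); check_nonneg(a645, "a645")
  .maybe_clip(18.61 * a645 - 3.96 * a665, clip, "chlorophyll b")
}

#' Total carotenoid concentration
#'
#' \code{(1000*A470 - 2.270*Chla - 81.4*Chlb) / 198}, mg/L, correcting the
#' 470 nm absorbance for chlorophyll overlap.
#'
#' @param a470 absorbance at 470 nm.
#' @param chla,chlb chlorophyll a and b concentrations, mg/L.
#' @inheritParams chlorophyll_a
#' @return total carotenoids, mg/L.
#' @export
total_carotenoids <- function(a470, chla, chlb, clip = FALSE) {
  check_nonneg(a470, "a470")
  .maybe_clip((1000 * a470 - 2.270 * chla - 81.4 * chlb) / 198, clip,
              "total carotenoids")
}

#' Pigment content as percent of dry weight
#'
#' Converts an extract concentration to cellular content:
#' \code{conc * volume_ml * 0.001 * 100 / biomass_mg}. The extract volume
#' defaults to 5 mL.
#'
#' @param conc pigment concentration in the extract, mg/L.
#' @param extract_volume_ml extract volume, mL.
#' @param biomass_mg dry biomass extracted, mg. Must be > 0.
#' @return pigment content, percent of dry weight.
#' @export
pigment_content_percent <- function(conc, extract_volume_ml = 5, biomass_mg) {
  check_pos(biomass_mg, "biomass_mg")
  check_pos(extract_volume_ml, "extract_volume_ml")
  conc * extract_volume_ml * 0.001 * 100 / biomass_mg
}

#' Beta-carotene concentration from the dodecane-phase absorbances
#'
#' \code{(A453 - A665/3.91) * 3.657 * 3 * dilution}, mg/L. The 665 nm term
#' corrects for chlorophyll carry-over into the dodecane phase, 3.657 is an
#' HPLC-derived calibration factor and 3 the millilitres of dodecane used
#' in the extraction.
#'
#' @param a453,a665 absorbances of the dodecane phase at 453 and 665 nm.
#' @param dilution dilution factor applied before reading absorbance (>= 1).
#' @return beta-carotene concentration, mg/L.
#' @export
beta_carotene_concentration <- function(a453, a665, dilution = 1) {
  check_nonneg(a453, "a453"); check_nonneg(a665, "a665")
  if (any(dilution < 1)) stop_domain("`dilution` must be >= 1")
  (a453 - a665 / 3.91) * 3.657 * 3 * dilution
}

#' Beta-carotene content as percent of dry weight
#'
#' Default form \code{cbcar / (10 * dry_weight)}: a concentration in mg/L
#' over a dry weight in g/L (= 1000 mg/L) times 100 is a true percentage.
#' The literal printed form \code{cbcar * 10 / dry_weight} is available via
#' \code{literal = TRUE} for comparison; it differs by a factor of 100 and
#' is dimensionally a per-mille-of-percent hybrid (see the vignette).
#'
#' @param cbcar beta-carotene concentration, mg/L.
#' @param dry_weight culture dry weight, g/L. Must be > 0.
#' @param literal use the published x10 form instead of the dimensional one.
#' @return beta-carotene content, percent of dry weight.
#' @examples
#' beta_carotene_content_percent(72.4, 1.0)  # 7.24 %
#' @export
beta_carotene_content_percent <- function(cbcar, dry_weight, literal = FALSE) {
  check_pos(dry_weight, "dry_weight")
  if (literal) cbcar * 10 / dry_weight else cbcar / (10 * dry_weight)
}

#' Full pigment panel for a table of absorbance records
#'
#' @param records data.frame with columns \code{a665, a645, a470, a453,
#'   dilution, extract_ml, biomass_mg, dw_g_per_L} (extra columns such as
#'   \code{sample_id} are carried through).
#' @inheritParams chlorophyll_a
#' @return the input with six derived columns appended: \code{chla_mg_L,
#'   chlb_mg_L, carotenoids_mg_L, carotenoids_pct_dw, bcar_mg_L,
#'   bcar_pct_dw}.
#' @export
pigment_panel <- function(records, clip = FALSE) {
  needed <- c("a665", "a645", "a470", "a453", "dilution", "extract_ml",
              "biomass_mg", "dw_g_per_L")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_domain(paste("absorbance table lacks columns:",
                      paste(missing, collapse = ", ")))
  }
  chla <- chlorophyll_a(records$a665, records$a645, clip)
  chlb <- chlorophyll_b(records$a645, records$a665, clip)
  car <- total_carotenoids(records$a470, chla, chlb, clip)
  bcar <- beta_carotene_concentration(records$a453, records$a665,
                                      records$dilution)
  records$chla_mg_L <- chla
  records$chlb_mg_L <- chlb
  records$carotenoids_mg_L <- car
  records$carotenoids_pct_dw <-
    pigment_content_percent(car, records$extract_ml, records$biomass_mg)
  records$bcar_mg_L <- bcar
  records$bcar_pct_dw <- beta_carotene_content_percent(bcar, records$dw_g_per_L)
  records
}

.maybe_clip <- function(x, clip, what) {
  if (any(x < 0)) {
    if (clip) {
      x <- pmax(x, 0)
    } else {
      warning(sprintf("negative %s concentration computed; returning raw value", what))
    }
  }
  x
}
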