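#' Total land-use niche
#'
#' The total niche of a land-use class is a weighted sum of its natural
#' niche (land quality, utilization intensity, food security), economic
#' niche (economic benefit) and social niche (policy and regulation), all
#' expressed in CNY per hectare. Default weights are 0.4 / 0.4 / 0.2.
#'
#' @param natural,economic,social Niche components, CNY/hm2; vectors are
#'   combined elementwise.
#' @param weights Numeric length-3 weights summing to 1.
#' @return Total niche, CNY/hm2.
#' @export
total_niche <- function(natural, economic, social,
                        weights = c(0.4, 0.4, 0.2)) {
  stopifnot(length(weights) == 3, all(is.finite(weights)))
  if (abs(sum(weights) - 1) > 1e-9) stop("niche weights must sum to 1")
  if (any(!is.finite(natural) | !is.finite(economic) | !is.finite(social))) {
    stop("niche components must be finite")
  }
  weights[1] * natural + weights[2] * economic + weights[3] * social
}

#' Niche coefficient table for the eight land-use classes
#'
#' Natural, economic and social niche components (CNY/hm2) per class, with
#' the total niche computed from them by \code{\link{total_niche}}.
#'
#' @param weights Weights passed to \code{\link{total_niche}}.
#' @return Data frame with columns class, code, natural, economic, social,
#'   total.
#' @export
niche_table <- function(weights = c(0.4, 0.4, 0.2)) {
  d <- data.frame(
    class = names(landuse_classes()),
    code = unname(landuse_classes()),
    natural = c(16453, 17082, 30011, 19110, 0, 0, 12803, 11906),
    economic = c(6250, 8630, 430, 330, 1000, 0, 68880, 0),
    social = c(10000, 0, 1650, 1650, 58594, 0, 1600, 0)
  )
  d$total <- total_niche(d$natural, d$economic, d$social, weights)
  d
}

#' Garden-land ecosystem service value from cultivated and forest values
#'
#' The reference ESV coefficient scheme assigns no value to garden land;
#' it is estimated as the midpoint of the cultivated-land and forest-land
#' coefficients, rounded to 2 decimals (half away from zero).
#'
#' @param cultivated_esv,forest_esv ESV coefficients, CNY/hm2.
#' @return Garden-land ESV, CNY/hm2.
#' @export
garden_esv <- function(cultivated_esv, forest_esv) {
  round_half_up((cultivated_esv + forest_esv) / 2, 2)
}

#' Ecosystem service value coefficients for the eight land-use classes
#'
#' Per-hectare ESV coefficients (CNY/hm2). Construction land and AML carry
#' zero value; garden land is derived by \code{\link{garden_esv}}.
#'
#' @return Data frame with columns class, code, esv.
#' @export
esv_table <- function() {
  esv <- c(cultivated = 3296.98,
           garden = NA,
           forest = 11735.57,
           grassland = 4870.35,
           construction = 0,
           aml = 0,
           water = 18926.32,
           unutilized = 580.10)
  esv["garden"] <- garden_esv(esv[["cultivated"]], esv[["forest"]])
  data.frame(class = names(landuse_classes()),
             code = unname(landuse_classes()),
             esv = unname(esv))
}

#' Reclaimable-area caps from the mined-land suitability assessment
#'
#' Upper bounds (hm2) on the AML area reclaimable to each target use,
#' i.e. the caps on the reclamation decision variables of the demand LP.
#' These are the study-area values; project-specific caps come from
#' \code{\link{aggregate_bounds}} on an assessed patch set.
#'
#' @return Named numeric vector over the four target uses.
#' @export
mls_caps_default <- function() {
  c(cultivated = 85.3, garden = 176.1, forest = 1729.0,
    construction = 1081.5)
}

#' Planning floors for the 2020 land-use structure
#'
#' Minimum class areas (hm2, including reclaimed AML) that the general
#' land-use plan requires at the planning horizon.
#'
#' @return Named numeric vector over the four constrained classes.
#' @export
plan_floors <- function() {
  c(cultivated = 1656, garden = 1678, forest = 29738, construction = 6688)
}

#' Demand constants of the study landscape
#'
#' Total landscape area, total AML reclamation between base and horizon
#' year, and residual (unreclaimed) AML at the horizon, all in hm2.
#'
#' @return Named list with \code{total_area}, \code{reclamation_total},
#'   \code{residual_aml}.
#' @export
demand_constants <- function() {
  list(total_area = 46634, reclamation_total = 3072, residual_aml = 501)
}

#' Per-class planning caps closing the scenario LPs
#'
#' The printed constraint set of the demand LP bounds only the reclamation
#' variables and four planning floors; without additional per-class caps
#' the niche and ESV objectives would park all free area in the
#' highest-valued class. These shipped caps (hm2, per final class area
#' including reclamation) close the problem; they are a calibration fixture
#' of the study landscape, not an output of the package.
#'
#' @param scenario 2 (niche objective) or 3 (ESV objective).
#' @return Named numeric vector of per-class caps; \code{NA} = uncapped.
#' @export
scenario_caps <- function(scenario) {
  if (scenario == 2) {
    c(cultivated = 1656, garden = 1678, forest = 31035, grassland = 1692,
      construction = 6689, aml = NA, water = 1691, unutilized = NA)
  } else if (scenario == 3) {
    c(cultivated = 1656, garden = 1678, forest = 32784, grassland = 1109,
      construction = 6688, aml = NA, water = 1109, unutilized = NA)
  } else {
    stop("scenario caps are defined for scenarios 2 and 3")
  }
}

#' Horizon-year demand of the planning scenario
#'
#' Class areas (hm2) prescribed by the general land-use plan for the
#' horizon year (scenario 1); no optimization is involved.
#'
#' @return Named numeric vector over the eight classes, summing to the
#'   landscape total.
#' @export
planning_demand <- function() {
  stats::setNames(c(1656, 1678, 29738, 2643, 6688, 501, 955, 2775),
                  names(landuse_classes()))
}
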