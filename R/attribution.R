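#' Event scenario for counterfactual attribution
#'
#' Bundles the inputs of the attribution arithmetic: the event-year
#' detrended exposure anomaly (degC), a per-degC effect coefficient (in
#' sigma units for z-score outcomes or probability units for threshold
#' outcomes), the under-5 population of the sample countries, and a
#' baseline prevalence.
#'
#' @param anomaly event anomaly in degC (e.g. 1.92 for a very strong
#'   El Nino year).
#' @param coefficient effect per degC (signed).
#' @param population children under 5 (>= 0).
#' @param baseline_prevalence baseline outcome prevalence in \[0, 1\]
#'   (optional, used for context in reports).
#' @return list of class `event_scenario`.
#' @export
event_scenario <- function(anomaly, coefficient, population = NA_real_,
                           baseline_prevalence = NA_real_) {
  if (!is.na(population) && population < 0) stop("population must be >= 0")
  if (!is.na(baseline_prevalence) &&
      (baseline_prevalence < 0 || baseline_prevalence > 1))
    stop("baseline prevalence must be in [0, 1]")
  structure(list(anomaly = anomaly, coefficient = coefficient,
                 population = population,
                 baseline_prevalence = baseline_prevalence),
            class = "event_scenario")
}

#' Per-child effect of an event
#'
#' The signed per-child shift implied by an event anomaly and a per-degC
#' coefficient: `shift = anomaly x coefficient`. For a z-score coefficient
#' the shift is in sigma units; for a probability coefficient it is a
#' probability change.
#'
#' @param scenario an [event_scenario()], or a numeric anomaly if
#'   `coefficient` is given.
#' @param coefficient per-degC coefficient (when `scenario` is numeric).
#' @return signed per-child shift.
#' @export
event_effect <- function(scenario, coefficient = NULL) {
  if (inherits(scenario, "event_scenario"))
    return(scenario$anomaly * scenario$coefficient)
  scenario * coefficient
}

#' Children pushed across a threshold by a probability shift
#'
#' `count = shift x population`: the number of children driven into (or,
#' for negative shifts, out of) the outcome state.
#'
#' @param shift probability change, |shift| <= 1.
#' @param population children under 5.
#' @return signed count of children.
#' @export
affected_children <- function(shift, population) {
  if (any(abs(shift) > 1)) stop("|shift| must be <= 1 (a probability change)")
  shift * population
}

#' Intervention-equivalent child counts
#'
#' Converts an event's total z-score deficit (|per-child shift| x
#' population) into the number of children who would need to receive each
#' nutrition intervention to offset it: `children = deficit / effect_size`.
#' Confidence bounds divide by the effect-size CI bounds, so the count
#' interval is order-reversed (a larger per-child effect means fewer
#' children needed).
#'
#' @param scenario an [event_scenario()] with a sigma-unit coefficient and
#'   a population.
#' @param interventions `data.table`/data.frame with columns `name`,
#'   `effect` (sigma per child, > 0), `effect_lo`, `effect_hi`.
#' @return `data.table` (`name`, `children`, `children_lo`, `children_hi`,
#'   `effect`, `effect_lo`, `effect_hi`).
#' @export
intervention_equivalence <- function(scenario, interventions) {
  iv <- data.table::as.data.table(interventions)
  if (!all(c("name", "effect", "effect_lo", "effect_hi") %in% names(iv)))
    stop("interventions need columns name, effect, effect_lo, effect_hi")
  if (any(iv$effect <= 0 | iv$effect_lo <= 0 | iv$effect_hi <= 0))
    stop("intervention effect sizes must be positive")
  deficit <- abs(event_effect(scenario)) * scenario$population
  iv[, `:=`(children = deficit / effect,
            children_lo = deficit / effect_hi,
            children_hi = deficit / effect_lo)]
  iv[, .(name, children, children_lo, children_hi,
         effect, effect_lo, effect_hi)]
}

#' Required pace toward a zero-hunger target
#'
#' Percentage points of prevalence reduction per year needed to reach zero
#' by the target year: `100 x prevalence / (target_year - base_year)`.
#'
#' @param prevalence baseline prevalence as a fraction in \[0, 1\].
#' @param base_year starting year.
#' @param target_year target year (default 2030).
#' @return percentage points per year.
#' @export
sdg_pace <- function(prevalence, base_year, target_year = 2030L) {
  if (target_year <= base_year) stop("target year must be after base year")
  100 * prevalence / (target_year - base_year)
}

#' Read an intervention effect-size configuration
#'
#' Loads a CSV of per-child WAZ effect sizes (columns `name`, `effect`,
#' `effect_lo`, `effect_hi`). The packaged default
#' (`intervention_effects.csv`) carries effect sizes after the Bhutta et
#' al. (2008) nutrition-intervention meta-analysis; the file is a config
#' input, deliberately never hard-coded.
#'
#' @param path CSV path; default is the packaged configuration.
#' @return `data.table` of intervention effect sizes.
#' @export
read_interventions <- function(path = system.file("extdata",
                                                  "intervention_effects.csv",
                                                  package = "ensoanthro")) {
  iv <- data.table::fread(path)
  if (any(iv$effect <= 0)) stop("intervention effect sizes must be positive")
  iv[]
}

#' Round to a number of significant figures (reporting convention)
#'
#' Attribution outputs are reported at two significant figures (e.g. 5.9
#' million, 1.9 percentage points) alongside the full-precision values.
#'
#' @param x numeric.
#' @param digits significant figures (default 2).
#' @return rounded numeric.
#' @export
report_signif <- function(x, digits = 2L) signif(x, digits)
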