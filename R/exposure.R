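# Exposure scenario and permitted-dose table.
#
# Concentrations are carried in ug/L (the surface-water monitoring
# convention); permitted doses in mg/kg/day. The 1e-3 unit factor lives in
# dose_from_concentration() and nowhere else, so it cannot be applied
# twice.

#' Generic drinking-water exposure scenario
#'
#' The conservative screening scenario: the measured water is assumed to be
#' a drinking-water supply consumed at a fixed daily rate by an adult of
#' fixed body weight, with concentrations constant over time (so chronic
#' permitted doses apply). Defaults: 2 L/day and 60 kg.
#'
#' @param ingestion_rate daily water intake in L/day (> 0, default 2).
#' @param body_weight body weight in kg (> 0, default 60).
#' @return an object of class `exposure_scenario`.
#' @examples
#' exposure_scenario()
#' exposure_scenario(ingestion_rate = 1, body_weight = 70)
#' @export
exposure_scenario <- function(ingestion_rate = 2, body_weight = 60) {
  check_positive_scalar(ingestion_rate, "ingestion_rate (L/day)")
  check_positive_scalar(body_weight, "body_weight (kg)")
  structure(list(ingestion_rate = ingestion_rate, body_weight = body_weight),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario: %g L/day, %g kg body weight\n",
              x$ingestion_rate, x$body_weight))
  invisible(x)
}

#' Convert a water concentration to a daily dose
#'
#' dose (mg/kg/day) = concentration (ug/L) x 1e-3 (mg/ug) x ingestion rate
#' (L/day) / body weight (kg). Linear in the concentration and ingestion
#' rate, inverse in body weight.
#'
#' @param conc numeric vector of concentrations in ug/L (>= 0).
#' @param scenario an [exposure_scenario()].
#' @return numeric vector of doses in mg/kg/day.
#' @examples
#' dose_from_concentration(30) # 0.001 mg/kg/day under the default scenario
#' @export
dose_from_concentration <- function(conc, scenario = exposure_scenario()) {
  if (!inherits(scenario, "exposure_scenario"))
    abort("scenario must be created with exposure_scenario()")
  if (!is.numeric(conc) || any(!is.na(conc) & (conc < 0 | !is.finite(conc))))
    abort("concentrations must be non-negative finite numbers (ug/L)")
  conc * 1e-3 * scenario$ingestion_rate / scenario$body_weight
}

#' Hazard quotient of a dose against a permitted dose
#'
#' HQ = dose / PD, dimensionless. The permitted dose PD is a chronic
#' regulatory guidance value (Reference Dose, Population Adjusted Dose,
#' ...) in mg/kg/day and must be strictly positive.
#'
#' @param dose numeric vector, mg/kg/day (>= 0).
#' @param pd numeric vector, permitted doses in mg/kg/day (> 0).
#' @return numeric vector of hazard quotients.
#' @examples
#' hazard_quotient(0.0019, 0.0019) # 1
#' @export
hazard_quotient <- function(dose, pd) {
  if (!is.numeric(dose) || any(!is.na(dose) & (dose < 0 | !is.finite(dose))))
    abort("doses must be non-negative finite numbers (mg/kg/day)")
  if (!is.numeric(pd) || any(!is.na(pd) & pd <= 0))
    abort("permitted doses must be strictly positive (mg/kg/day)")
  dose / pd
}

#' Load a permitted-dose table
#'
#' Reads a table of chronic permitted doses, one row per chemical, with
#' columns `chemical`, `pd_mg_kg_day` (> 0) and `source_code` (integer key
#' into the source-of-toxicity-data legend); an optional logical
#' `molar_basis` column flags degradates whose PD was derived from the
#' parent compound on a molar basis (the printed PD values are used
#' verbatim; no molar arithmetic is performed here). With no argument the
#' packaged table of 81 pesticides and degradates measured in U.S. surface
#' water is loaded. Two analytes of that survey (Fenuron and Neburon) have
#' no identified PD and are deliberately absent: [resolve_pd()] excludes
#' them from cumulative metrics.
#'
#' @param x path to a CSV file, or a data.frame with the columns above;
#'   `NULL` (default) loads the packaged table.
#' @return a data.frame of class `pd_table`.
#' @examples
#' pd <- load_permitted_doses()
#' nrow(pd) # 81
#' @export
load_permitted_doses <- function(x = NULL) {
  if (is.null(x))
    x <- system.file("extdata", "permitted_doses.csv", package = "mcrscreen",
                     mustWork = TRUE)
  if (is.character(x)) {
    if (!file.exists(x)) abort("permitted-dose file not found: %s", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x))
    abort("permitted doses must be a CSV path or a data.frame")
  need <- c("chemical", "pd_mg_kg_day", "source_code")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort("permitted-dose table lacks column(s): %s", paste(miss, collapse = ", "))
  x$chemical <- as.character(x$chemical)
  x$pd_mg_kg_day <- as.numeric(x$pd_mg_kg_day)
  if (is.null(x$molar_basis)) x$molar_basis <- FALSE
  bad <- !is.finite(x$pd_mg_kg_day) | x$pd_mg_kg_day <= 0
  if (any(bad))
    abort("non-positive or missing permitted dose for: %s",
          paste(x$chemical[bad], collapse = ", "))
  key <- normalize_chemical(x$chemical)
  dup <- duplicated(key)
  if (any(dup))
    abort("duplicated chemical in permitted-dose table: %s",
          paste(unique(x$chemical[dup]), collapse = ", "))
  out <- x[c("chemical", "pd_mg_kg_day", "source_code", "molar_basis")]
  attr(out, "key") <- key
  class(out) <- c("pd_table", "data.frame")
  out
}

#' Look up permitted doses, excluding chemicals without one
#'
#' Matches chemical names against a permitted-dose table
#' (case-insensitively, after whitespace normalization). Chemicals without
#' a PD are not an error: they return `NA_real_` (an exclusion marker) and
#' a single warning counts the occurrences. Downstream, excluded chemicals
#' contribute nothing to HI, MHQ or n under either non-detect policy.
#'
#' @param chemical character vector of chemical names.
#' @param table a `pd_table` from [load_permitted_doses()].
#' @param warn warn about chemicals without a PD (default TRUE).
#' @return numeric vector of PDs (mg/kg/day), `NA` where no PD exists.
#' @examples
#' resolve_pd("Atrazine") # 0.0019
#' @export
resolve_pd <- function(chemical, table = load_permitted_doses(), warn = TRUE) {
  if (!inherits(table, "pd_table")) table <- load_permitted_doses(table)
  idx <- match(normalize_chemical(chemical), attr(table, "key"))
  pd <- table$pd_mg_kg_day[idx]
  if (warn && anyNA(pd)) {
    cnt <- table(chemical[is.na(pd)])
    warnf("no permitted dose for %d occurrence(s) of %d chemical(s); excluded from cumulative metrics: %s",
          sum(cnt), length(cnt),
          paste(sprintf("%s (%d)", names(cnt), cnt), collapse = ", "))
  }
  pd
}
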