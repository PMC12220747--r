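#' Cost categories and their fixed/variable classification
#'
#' The ten cost categories of the delivery cost table, in report row order,
#' each mapped to its cost class. The first five scale with service volume
#' (variable); the last five do not (fixed).
#'
#' @return Named character vector mapping category to `"variable"` or
#'   `"fixed"`, in canonical row order.
#' @export
#' @examples
#' cost_categories()
cost_categories <- function() {
  c(
    personnel_clinical   = "variable",
    prep_drugs           = "variable",
    laboratory           = "variable",
    recurrent_training   = "variable",
    supplies             = "variable",
    startup_microplanning = "fixed",
    personnel_supervision = "fixed",
    capital              = "fixed",
    overhead             = "fixed",
    startup_training     = "fixed"
  )
}

#' @rdname cost_categories
#' @export
variable_categories <- function() {
  names(cost_categories())[cost_categories() == "variable"]
}

#' @rdname cost_categories
#' @export
fixed_categories <- function() {
  names(cost_categories())[cost_categories() == "fixed"]
}

# Display labels used when rendering report tables.
category_labels <- c(
  personnel_clinical    = "Personnel (clinical)",
  prep_drugs            = "PrEP drugs",
  laboratory            = "Laboratory testing",
  recurrent_training    = "Recurrent training",
  supplies              = "Supplies",
  startup_microplanning = "Start-up microplanning",
  personnel_supervision = "Personnel (supervision)",
  capital               = "Capital",
  overhead              = "Overhead",
  startup_training      = "Start-up training"
)

#' Enumerations used by the cost data model
#'
#' Valid study arms, provider cadres, priced commodities, visit activities,
#' visit types and cost bases.
#'
#' @name enums
#' @export
arms <- function() c("soc", "intervention")

#' @rdname enums
#' @export
cadres <- function() {
  c("hiv_testing_counsellor", "clinical_officer", "nurse", "pharmacy_technologist")
}

#' @rdname enums
#' @export
price_items <- function() {
  c("prep_30day", "oraquick_hivst", "atomo_hivst", "determine_rapid_test",
    "creatinine_test")
}

#' @rdname enums
#' @export
activities <- function() {
  c("counselling_hiv_testing", "clinical_examination", "laboratory_testing",
    "prep_dispensing", "waiting")
}

#' @rdname enums
#' @export
visit_types <- function() c("enrollment", "refill")

#' @rdname enums
#' @export
cost_bases <- function() c("per_year", "per_visit", "per_client_month", "one_off")

#' Default mapping from visit activity to provider cadre
#'
#' Each timed (non-waiting) visit activity is performed by one cadre:
#' counselling and HIV testing by the HIV testing counsellor, clinical
#' examination by the clinical officer, point-of-care laboratory work by the
#' nurse, and dispensing by the pharmacy technologist. Waiting carries no
#' provider and is never costed.
#'
#' @return Named character vector: activity -> cadre.
#' @export
activity_cadre_map <- function() {
  c(
    counselling_hiv_testing = "hiv_testing_counsellor",
    clinical_examination    = "clinical_officer",
    laboratory_testing      = "nurse",
    prep_dispensing         = "pharmacy_technologist"
  )
}

#' Reference 2019 KES/USD exchange rates
#'
#' Two slightly different 2019 reference rates circulate for the Kenyan
#' shilling: 105.50 and 105.35 KES per USD. The package default is 105.50;
#' the alternative is exported so analyses can state which was used.
#'
#' @export
kes_per_usd_2019 <- 105.50

#' @rdname kes_per_usd_2019
#' @export
kes_per_usd_2019_alt <- 105.35
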