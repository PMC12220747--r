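#' Define a scenario transformation
#'
#' A scenario is a named, declarative edit of a base ledger: select a
#' different cadre salary table (e.g. public-sector pay in place of
#' research-site pay), remove items, add items, and/or override start-up
#' items by name. Added and removed sets must be disjoint.
#'
#' @param name Scenario label.
#' @param salary_table Optional scenario tag of the salary table to
#'   activate.
#' @param add_items Ledger item `data.frame` (rows as from [cost_item()]),
#'   or `NULL`.
#' @param remove_items Character vector of item names to drop.
#' @param startup_overrides Item `data.frame` whose rows replace
#'   same-named/same-arm existing items.
#' @return A `prep_scenario` object.
#' @export
scenario <- function(name, salary_table = NULL, add_items = NULL,
                     remove_items = character(), startup_overrides = NULL) {
  if (!is.null(add_items)) validate_items(add_items)
  if (!is.null(startup_overrides)) validate_items(startup_overrides)
  added <- if (is.null(add_items)) character() else add_items$name
  if (length(intersect(added, remove_items))) {
    stop("scenario: added and removed item sets must be disjoint",
         call. = FALSE)
  }
  structure(list(name = name, salary_table = salary_table,
                 add_items = add_items, remove_items = remove_items,
                 startup_overrides = startup_overrides),
            class = "prep_scenario")
}

#' Read a scenario from YAML
#'
#' Scenario documents carry `name` and optional `salary_table`,
#' `remove_items`, `add_items`, `startup_overrides` sections; item entries
#' use the ledger item schema. See the packaged fixtures
#' `moh_scenario.yaml` and `creatinine_addon.yaml`.
#'
#' @param path Scenario YAML path.
#' @return A `prep_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("read_scenario: no such file: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$name)) stop("read_scenario: missing `name`", call. = FALSE)
  items_df <- function(lst) {
    if (is.null(lst) || length(lst) == 0L) return(NULL)
    do.call(rbind, lapply(lst, function(r) {
      do.call(cost_item, r)
    }))
  }
  scenario(
    name = doc$name, salary_table = doc$salary_table,
    add_items = items_df(doc$add_items),
    remove_items = as.character(doc$remove_items %||% character()),
    startup_overrides = items_df(doc$startup_overrides)
  )
}

#' Apply a scenario to a ledger
#'
#' Produces the transformed ledger: salary table swapped, overrides
#' applied, items removed and added; everything else untouched. Removing
#' an item that does not exist is an error. Re-applying a scenario already
#' applied to the ledger is a no-op, so application is idempotent, and
#' scenarios touching disjoint parts of the ledger commute.
#'
#' @param ledger A `prep_ledger`.
#' @param scn A [scenario()].
#' @return The transformed `prep_ledger` (its `scenario_tag` reflects any
#'   salary swap and its name records the scenario).
#' @export
#' @examples
#' led <- load_ledger(system.file("extdata", "trial_2019.yaml",
#'                                package = "prepcost"))
#' moh <- read_scenario(system.file("extdata", "moh_scenario.yaml",
#'                                  package = "prepcost"))
#' apply_scenario(led, moh)
apply_scenario <- function(ledger, scn) {
  stopifnot(inherits(ledger, "prep_ledger"), inherits(scn, "prep_scenario"))
  if (scn$name %in% ledger$applied_scenarios) return(ledger)
  items <- ledger$items
  if (!is.null(scn$startup_overrides)) {
    ov <- scn$startup_overrides
    for (i in seq_len(nrow(ov))) {
      hit <- items$name == ov$name[i] &
        (is.na(ov$arm[i]) | (!is.na(items$arm) & items$arm == ov$arm[i]))
      if (!any(hit)) {
        stop("apply_scenario: override targets nonexistent item '",
             ov$name[i], "'", call. = FALSE)
      }
      items <- items[!hit, , drop = FALSE]
      items <- rbind(items, ov[i, , drop = FALSE])
    }
  }
  for (nm in scn$remove_items) {
    if (!nm %in% items$name) {
      stop("apply_scenario: cannot remove nonexistent item '", nm, "'",
           call. = FALSE)
    }
    items <- items[items$name != nm, , drop = FALSE]
  }
  if (!is.null(scn$add_items)) items <- rbind(items, scn$add_items)
  rownames(items) <- NULL
  tag <- scn$salary_table %||% ledger$scenario_tag
  prep_ledger(
    name = paste0(ledger$name, "+", scn$name), scenario_tag = tag,
    params = ledger$params, salaries = ledger$salaries,
    unit_prices = ledger$unit_prices, items = items,
    applied_scenarios = c(ledger$applied_scenarios, scn$name)
  )
}

#' Compare the two arms' unit costs
#'
#' One row of the cross-scenario summary: per client-month unit cost in
#' each arm, the absolute difference (standard-of-care minus intervention,
#' to the cent) and the percent difference with the standard-of-care unit
#' cost as denominator, rounded to a whole percent.
#'
#' @param soc_report,intervention_report `prep_arm_report`s sharing a
#'   scenario tag.
#' @return One-row `data.frame`: `scenario`, `soc_unit_cost`,
#'   `intervention_unit_cost`, `abs_difference`, `pct_difference`.
#' @export
#' @examples
#' compare_unit_costs(25.50, 17.73, "trial")
compare_arms <- function(soc_report, intervention_report) {
  if (!identical(soc_report$scenario_tag, intervention_report$scenario_tag)) {
    stop("compare_arms: reports are from different scenarios (",
         soc_report$scenario_tag, " vs ", intervention_report$scenario_tag,
         ")", call. = FALSE)
  }
  compare_unit_costs(round_cents(soc_report$unit_cost_total),
                     round_cents(intervention_report$unit_cost_total),
                     soc_report$scenario_tag)
}

#' @rdname compare_arms
#' @param soc_unit_cost,intervention_unit_cost Display-rounded unit costs.
#' @param scenario_name Scenario label for the row.
#' @export
compare_unit_costs <- function(soc_unit_cost, intervention_unit_cost,
                               scenario_name = "scenario") {
  diff <- round_cents(soc_unit_cost - intervention_unit_cost)
  data.frame(
    scenario = scenario_name,
    soc_unit_cost = soc_unit_cost,
    intervention_unit_cost = intervention_unit_cost,
    abs_difference = diff,
    pct_difference = round_half_up(100 * diff / soc_unit_cost),
    stringsAsFactors = FALSE
  )
}

#' Cross-scenario summary matrix
#'
#' Builds per-arm reports for a base ledger and each scenario
#' transformation of it, and returns the arm-comparison table (one row per
#' scenario) together with the per-scenario/arm category share breakdown.
#'
#' @param ledger Base `prep_ledger`.
#' @param accruals List with `soc` and `intervention` [accrual()]s.
#' @param scenarios Named list of [scenario()]s applied to the base ledger
#'   (use `list()` for the base alone). The base ledger itself is always
#'   reported under its own scenario tag.
#' @param tam Per-arm mean activity minutes.
#' @param options Engine options (see [variable_costs()]).
#' @return List with `comparison` (one row per scenario), `shares`
#'   (scenario x arm x category percent shares) and `reports` (the
#'   underlying `prep_arm_report`s).
#' @export
scenario_matrix <- function(ledger, accruals, scenarios = list(),
                            tam = reference_activity_means(),
                            options = list()) {
  ledgers <- c(stats::setNames(list(ledger), ledger$scenario_tag),
               lapply(scenarios, function(s) apply_scenario(ledger, s)))
  names(ledgers)[-1L] <- vapply(scenarios, function(s) s$name, character(1))
  reports <- lapply(names(ledgers), function(nm) {
    lapply(stats::setNames(arms(), arms()), function(a) {
      r <- build_arm_report(ledgers[[nm]], accruals, a, tam, options = options)
      r$scenario_tag <- nm
      r
    })
  })
  names(reports) <- names(ledgers)
  comparison <- do.call(rbind, lapply(names(reports), function(nm) {
    compare_arms(reports[[nm]]$soc, reports[[nm]]$intervention)
  }))
  shares <- do.call(rbind, lapply(names(reports), function(nm) {
    do.call(rbind, lapply(arms(), function(a) {
      r <- reports[[nm]][[a]]
      data.frame(scenario = nm, arm = a,
                 category = names(r$shares),
                 share_pct = as.numeric(100 * r$shares),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(comparison) <- rownames(shares) <- NULL
  list(comparison = comparison, shares = shares, reports = reports)
}
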