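#' Read accruals from CSV
#'
#' Columns: `arm`, `annual_visits`, `prep_client_months`,
#' `visits_per_client_year`, `bottles_per_visit`; one row per arm.
#'
#' @param path CSV path.
#' @return List with `soc` and `intervention` [accrual()]s.
#' @export
read_accruals <- function(path) {
  if (!file.exists(path)) stop("read_accruals: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("arm", "annual_visits", "prep_client_months",
            "visits_per_client_year", "bottles_per_visit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_accruals: missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    accrual(df$arm[i], df$annual_visits[i], df$prep_client_months[i],
            df$visits_per_client_year[i], df$bottles_per_visit[i])
  })
  names(out) <- df$arm
  if (!all(arms() %in% names(out))) {
    stop("read_accruals: need one row per arm (soc, intervention)",
         call. = FALSE)
  }
  out[arms()]
}

#' Run the full costing pipeline
#'
#' Ties the stages together: load the ledger, summarise the observation
#' log into per-arm activity means (or take means directly), build per-arm
#' cost reports for the base ledger and each scenario, and assemble the
#' arm-comparison and share tables into one deterministic bundle.
#' Identical inputs always produce an identical bundle.
#'
#' @param ledger A `prep_ledger` or path to a ledger YAML.
#' @param accruals List with `soc`/`intervention` [accrual()]s, or a CSV
#'   path; defaults to the study accruals.
#' @param observations Observation-log `data.frame` or CSV path; summarised
#'   with [activity_means()]. Ignored when `tam` is given.
#' @param tam Per-arm mean activity minutes; defaults to
#'   [reference_activity_means()] when no observations are supplied.
#' @param scenarios Named list of [scenario()]s (or paths to scenario
#'   YAMLs) applied to the base ledger.
#' @param options Engine options (see [variable_costs()]).
#' @return A `prep_bundle`: list with `comparison`, `shares`, `reports`,
#'   `tam`, and the input digests under `meta`.
#' @export
run_pipeline <- function(ledger, accruals = generate_accruals(),
                         observations = NULL, tam = NULL,
                         scenarios = list(), options = list()) {
  if (is.character(ledger)) ledger <- load_ledger(ledger)
  if (is.character(accruals)) accruals <- read_accruals(accruals)
  if (is.null(tam)) {
    tam <- if (is.null(observations)) {
      reference_activity_means()
    } else {
      if (is.character(observations)) {
        observations <- read_observation_log(observations)
      }
      activity_means(observations)
    }
  }
  scenarios <- lapply(scenarios, function(s) {
    if (is.character(s)) read_scenario(s) else s
  })
  mat <- scenario_matrix(ledger, accruals, scenarios, tam, options)
  structure(list(
    meta = list(
      ledger = ledger$name, scenario_tag = ledger$scenario_tag,
      scenarios = vapply(scenarios, function(s) s$name, character(1),
                         USE.NAMES = FALSE),
      accruals = lapply(accruals, unclass)
    ),
    tam = tam,
    comparison = mat$comparison, shares = mat$shares, reports = mat$reports
  ), class = "prep_bundle")
}

#' @export
print.prep_bundle <- function(x, ...) {
  cat(sprintf("<prep_bundle> ledger '%s', %d scenario(s)\n", x$meta$ledger,
              nrow(x$comparison)))
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

bundle_as_list <- function(bundle) {
  list(
    meta = bundle$meta,
    tam = bundle$tam,
    comparison = bundle$comparison,
    shares = bundle$shares,
    reports = lapply(bundle$reports, function(pair) {
      lapply(pair, function(r) {
        list(arm = r$arm, scenario = r$scenario_tag,
             category_totals = as.list(r$category_totals),
             variable_subtotal = r$variable_subtotal,
             fixed_subtotal = r$fixed_subtotal,
             grand_total = r$grand_total,
             unit_costs = as.list(r$unit_costs),
             unit_cost_total = round_cents(r$unit_cost_total),
             shares_pct = as.list(round(100 * r$shares, 4)),
             prep_client_months = r$prep_client_months,
             annual_visits = r$annual_visits)
      })
    })
  )
}

#' Render a pipeline bundle to files
#'
#' Writes the bundle's tables in the requested format: `"json"` (the full
#' machine-readable bundle, which round-trips), `"csv"` (one file per
#' table, single header row each) or `"markdown"` (cost tables in
#' canonical row order plus the comparison table). Currency is printed to
#' cents and shares as whole percents.
#'
#' @param bundle A `prep_bundle` from [run_pipeline()].
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(bundle, format = c("json", "csv", "markdown"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "prep_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if (format == "json") {
    p <- file.path(dir, "bundle.json")
    jsonlite::write_json(bundle_as_list(bundle), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- p
  } else if (format == "csv") {
    for (nm in names(bundle$reports)) {
      for (a in arms()) {
        p <- file.path(dir, sprintf("costs_%s_%s.csv", nm, a))
        utils::write.csv(report_table(bundle$reports[[nm]][[a]]), p,
                         row.names = FALSE)
        paths <- c(paths, p)
      }
    }
    p <- file.path(dir, "comparison.csv")
    utils::write.csv(bundle$comparison, p, row.names = FALSE)
    p2 <- file.path(dir, "shares.csv")
    utils::write.csv(bundle$shares, p2, row.names = FALSE)
    paths <- c(paths, p, p2)
  } else {
    p <- file.path(dir, "report.md")
    lines <- character()
    for (nm in names(bundle$reports)) {
      for (a in arms()) {
        r <- bundle$reports[[nm]][[a]]
        lines <- c(lines,
                   sprintf("## %s — %s arm (%d visits, %d client-months)",
                           nm, a, r$annual_visits, r$prep_client_months),
                   "", md_table(report_table(r)), "")
      }
    }
    lines <- c(lines, "## Unit cost comparison", "",
               md_table(bundle$comparison), "")
    writeLines(lines, p)
    paths <- p
  }
  invisible(paths)
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.2f", col) else as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
  c(header, sep, rows)
}
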