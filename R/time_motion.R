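#' Read a time-and-motion observation log
#'
#' Reads a CSV of timed visit activities with columns `visit_id`, `arm`,
#' `visit_type`, `activity`, `cadre`, `start_time`, `end_time` (ISO-8601
#' clock times, `HH:MM:SS`). Header case and quoted fields are tolerated.
#' Waiting records carry no cadre.
#'
#' @param path CSV file path.
#' @return A validated observation-log `data.frame`.
#' @export
read_observation_log <- function(path) {
  if (!file.exists(path)) {
    stop("read_observation_log: no such file: ", path, call. = FALSE)
  }
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(log) <- tolower(names(log))
  need <- c("visit_id", "arm", "visit_type", "activity", "cadre",
            "start_time", "end_time")
  miss <- setdiff(need, names(log))
  if (length(miss)) {
    stop("read_observation_log: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_observation_log(log[need])
}

#' @rdname read_observation_log
#' @param log Observation-log `data.frame`.
#' @export
validate_observation_log <- function(log) {
  log$visit_id <- as.character(log$visit_id)
  bad <- setdiff(log$arm, arms())
  if (length(bad)) stop("observation log: unknown arm: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(log$visit_type, visit_types())
  if (length(bad)) stop("observation log: unknown visit_type: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(log$activity, activities())
  if (length(bad)) stop("observation log: unknown activity: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  log$cadre[!is.na(log$cadre) & log$cadre == ""] <- NA_character_
  waiting <- log$activity == "waiting"
  if (any(!is.na(log$cadre[waiting]))) {
    stop("observation log: waiting records must not carry a cadre",
         call. = FALSE)
  }
  bad <- setdiff(log$cadre[!waiting], cadres())
  if (length(bad)) stop("observation log: unknown cadre: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  # non-overlap within a visit for the same provider
  d <- activity_durations(log)
  for (vid in unique(d$visit_id)) {
    sub <- d[d$visit_id == vid & !d$is_waiting, , drop = FALSE]
    for (cad in unique(sub$cadre)) {
      s <- sub[sub$cadre == cad, , drop = FALSE]
      s <- s[order(s$start_min), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start_min[-1L] < s$end_min[-nrow(s)] - 1e-9)) {
        stop("observation log: overlapping activities for ", cad,
             " in visit ", vid, call. = FALSE)
      }
    }
  }
  log
}

parse_clock_minutes <- function(x, what, visit_id) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(seq_along(parts), function(i) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) < 2L || length(p) > 3L || anyNA(p)) {
      stop("observation log: unparseable ", what, " '", x[i], "' in visit ",
           visit_id[i], call. = FALSE)
    }
    if (length(p) == 2L) p <- c(p, 0)
    p[1] * 60 + p[2] + p[3] / 60
  }, numeric(1))
}

#' Per-record activity durations in minutes
#'
#' Computes `end - start` for every record of an observation log.
#' Fractional minutes are preserved; waiting records are flagged so that
#' provider-time totals can exclude them. An end time before its start time
#' is an error naming the offending visit.
#'
#' @param log Observation-log `data.frame` (see [read_observation_log()]).
#' @return `data.frame` with `visit_id`, `arm`, `visit_type`, `activity`,
#'   `cadre`, `start_min`, `end_min`, `minutes`, `is_waiting`.
#' @export
activity_durations <- function(log) {
  start <- parse_clock_minutes(log$start_time, "start_time", log$visit_id)
  end <- parse_clock_minutes(log$end_time, "end_time", log$visit_id)
  if (any(end < start)) {
    bad <- log$visit_id[end < start][[1]]
    stop("activity_durations: end before start in visit ", bad, call. = FALSE)
  }
  data.frame(
    visit_id = as.character(log$visit_id), arm = log$arm,
    visit_type = log$visit_type, activity = log$activity, cadre = log$cadre,
    start_min = start, end_min = end, minutes = end - start,
    is_waiting = log$activity == "waiting", stringsAsFactors = FALSE
  )
}

# Provider minutes per (visit, activity): waiting excluded, multiple
# segments of one activity within a visit summed.
per_visit_activity_minutes <- function(log) {
  d <- activity_durations(log)
  d <- d[!d$is_waiting, , drop = FALSE]
  keys <- unique(d[c("visit_id", "arm", "visit_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$visit_id == keys$visit_id[i], , drop = FALSE]
    agg <- stats::aggregate(minutes ~ activity, data = sub, FUN = sum)
    cbind(keys[rep(i, nrow(agg)), , drop = FALSE], agg, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Per-visit provider time totals
#'
#' Total provider minutes per observed visit, excluding waiting time
#' (which is reported separately, never costed). A visit containing only
#' waiting records totals zero minutes.
#'
#' @inheritParams activity_durations
#' @return `data.frame` with `visit_id`, `arm`, `visit_type`, `minutes`.
#' @export
visit_totals <- function(log) {
  d <- activity_durations(log)
  keys <- unique(d[c("visit_id", "arm", "visit_type")])
  keys$minutes <- vapply(keys$visit_id, function(v) {
    sum(d$minutes[d$visit_id == v & !d$is_waiting])
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}

#' Summarise activity durations for a stratum
#'
#' Medians with interquartile ranges and means with sample standard
#' deviations, per activity and for the per-visit provider total, within a
#' stratum of the log. Quartiles use linear interpolation between order
#' statistics (type-7); SD uses the n-1 denominator and is undefined for a
#' single observation. Raw (unrounded) values are returned; round for
#' display with [round_half_up()] to the nearest whole minute. Because
#' enrollment procedures are identical in both arms, enrollment strata are
#' pooled across arms by default.
#'
#' @inheritParams activity_durations
#' @param arm Optional arm filter (`"soc"`, `"intervention"`).
#' @param visit_type Optional visit-type filter (`"enrollment"`, `"refill"`).
#' @param pool_enrollment Pool both arms when summarising enrollment visits.
#' @return `data.frame` with `arm`, `visit_type`, `activity` (including
#'   `"total"`), `n`, `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
summarize_durations <- function(log, arm = NULL, visit_type = NULL,
                                pool_enrollment = TRUE) {
  pv <- per_visit_activity_minutes(log)
  tot <- visit_totals(log)
  if (!is.null(visit_type)) {
    visit_type <- match.arg(visit_type, visit_types())
    pv <- pv[pv$visit_type == visit_type, , drop = FALSE]
    tot <- tot[tot$visit_type == visit_type, , drop = FALSE]
  }
  pooled <- pool_enrollment && identical(visit_type, "enrollment")
  if (!is.null(arm) && !pooled) {
    arm <- match.arg(arm, arms())
    pv <- pv[pv$arm == arm, , drop = FALSE]
    tot <- tot[tot$arm == arm, , drop = FALSE]
  }
  if (nrow(tot) == 0L) {
    stop("summarize_durations: no observations in stratum", call. = FALSE)
  }
  stat_row <- function(x, activity) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      arm = if (is.null(arm) || pooled) "all" else arm,
      visit_type = visit_type %||% "all", activity = activity,
      n = length(x), median = q[2], q1 = q[1], q3 = q[3],
      mean = mean(x), sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  acts <- intersect(activities(), unique(pv$activity))
  out <- do.call(rbind, c(
    lapply(acts, function(a) stat_row(pv$minutes[pv$activity == a], a)),
    list(stat_row(tot$minutes, "total"))
  ))
  rownames(out) <- NULL
  out
}

#' Per-arm mean activity minutes across all visit types
#'
#' The engine-facing view of a time-and-motion log: one mean duration per
#' (arm, activity), plus the per-visit total, across all visit types.
#'
#' @inheritParams activity_durations
#' @return `data.frame` with `arm`, `activity`, `mean_minutes`.
#' @seealso [reference_activity_means()] for the published study values.
#' @export
activity_means <- function(log) {
  out <- do.call(rbind, lapply(intersect(arms(), unique(log$arm)), function(a) {
    s <- summarize_durations(log, arm = a)
    data.frame(arm = a, activity = s$activity, mean_minutes = s$mean,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Project per-visit time over a client-year
#'
#' Multiplies a per-visit mean duration by the scheduled number of annual
#' visits (4 under quarterly dispensing, 2 under six-month dispensing).
#' Linear in both arguments; when given unrounded per-activity means, the
#' per-activity projections sum to the projected total.
#'
#' @param per_visit_mean Mean minutes per visit (vectorised).
#' @param visits_per_client_year Positive annual visit count.
#' @return Minutes per client-year.
#' @export
#' @examples
#' project_annual(76, 2) # 152
project_annual <- function(per_visit_mean, visits_per_client_year) {
  if (any(per_visit_mean <= 0)) {
    stop("project_annual: `per_visit_mean` must be positive", call. = FALSE)
  }
  if (length(visits_per_client_year) != 1L || visits_per_client_year <= 0) {
    stop("project_annual: `visits_per_client_year` must be positive",
         call. = FALSE)
  }
  per_visit_mean * visits_per_client_year
}

#' Wage-weighted personnel cost of one visit
#'
#' Values each activity's provider time at that cadre's hourly wage
#' (annual salary / annual work hours) and sums across activities:
#' `sum(minutes/60 * annual_salary/annual_work_hours)`. Waiting carries no
#' provider and is ignored.
#'
#' @param minutes Named numeric vector of per-activity minutes (names are
#'   activities).
#' @param salaries Salary table as returned by [ledger_salaries()]
#'   (columns `cadre`, `annual_salary` in USD).
#' @param params [economic_params()] supplying `annual_work_hours`.
#' @param cadre_map Activity-to-cadre mapping, [activity_cadre_map()].
#' @return Personnel cost of the visit in USD (unrounded).
#' @export
#' @examples
#' sal <- data.frame(cadre = "clinical_officer", annual_salary = 10841)
#' personnel_cost_per_visit(c(clinical_examination = 20), sal,
#'                          economic_params())
personnel_cost_per_visit <- function(minutes, salaries,
                                     params = economic_params(),
                                     cadre_map = activity_cadre_map()) {
  minutes <- minutes[!names(minutes) %in% c("waiting", "total")]
  if (length(minutes) == 0L) return(0)
  bad <- setdiff(names(minutes), names(cadre_map))
  if (length(bad)) {
    stop("personnel_cost_per_visit: no cadre mapping for activity: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(minutes < 0)) {
    stop("personnel_cost_per_visit: negative minutes", call. = FALSE)
  }
  sum(vapply(names(minutes), function(a) {
    cad <- cadre_map[[a]]
    sal <- salaries$annual_salary[salaries$cadre == cad]
    if (length(sal) == 0L) {
      stop("personnel_cost_per_visit: missing salary for cadre '", cad, "'",
           call. = FALSE)
    }
    minutes[[a]] / 60 * sal[[1]] / params$annual_work_hours
  }, numeric(1)))
}
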