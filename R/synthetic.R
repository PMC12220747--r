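#' Published per-activity visit durations (means and SDs)
#'
#' The study conditions the synthetic generator emulates: mean provider
#' minutes per activity per visit across all visit types, by arm, with
#' their standard deviations. Standard-of-care visits average 54 provider
#' minutes (counselling & HIV testing 27, clinical examination 17,
#' laboratory 3, dispensing 7); six-month-dispensing visits average 76
#' (32/18/5/21), the extra dispensing time reflecting self-test kit
#' instruction.
#'
#' @return `data.frame` with `arm`, `activity`, `mean_minutes` (and
#'   `sd_minutes` for the SD table).
#' @export
#' @examples
#' reference_activity_means()
reference_activity_means <- function() {
  data.frame(
    arm = rep(arms(), each = 4L),
    activity = rep(names(activity_cadre_map()), 2L),
    mean_minutes = c(27, 17, 3, 7, 32, 18, 5, 21),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_activity_means
#' @export
reference_activity_sds <- function() {
  out <- reference_activity_means()
  names(out)[names(out) == "mean_minutes"] <- "sd_minutes"
  out$sd_minutes <- c(3, 4, 1, 2, 3, 4, 2, 6)
  out
}

#' Configuration for the synthetic observation-log generator
#'
#' Defaults reproduce the study's observation effort: 9 standard-of-care
#' and 13 intervention visits (22 in all, of which 1 + 5 are enrollment
#' visits), activity durations drawn per arm from the published means and
#' SDs under a normal distribution truncated at zero (a lognormal with the
#' same first two moments is available for robustness checks). The seed is
#' a mandatory argument; generation never touches hidden global state
#' beyond a locally restored RNG.
#'
#' @param seed Integer seed (required).
#' @param n_soc,n_intervention Visits to simulate per arm.
#' @param n_enrollment_soc,n_enrollment_intervention How many of those are
#'   enrollment visits.
#' @param means,sds Per-(arm, activity) duration parameters, shaped like
#'   [reference_activity_means()] / [reference_activity_sds()].
#' @param distribution `"normal_truncated_at_zero"` or `"lognormal"`.
#' @param waiting_minutes Mean waiting time inserted per visit (not
#'   provider time; set 0 to omit waiting records).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed, n_soc = 9L, n_intervention = 13L,
                         n_enrollment_soc = 1L, n_enrollment_intervention = 5L,
                         means = reference_activity_means(),
                         sds = reference_activity_sds(),
                         distribution = "normal_truncated_at_zero",
                         waiting_minutes = 10) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("synth_config: an integer `seed` is required", call. = FALSE)
  }
  if (!distribution %in% c("normal_truncated_at_zero", "lognormal")) {
    stop("synth_config: unknown distribution '", distribution, "'",
         call. = FALSE)
  }
  stopifnot(
    "means must be positive" = all(means$mean_minutes > 0),
    "sds must be non-negative" = all(sds$sd_minutes >= 0),
    "n_enrollment cannot exceed n visits" =
      n_enrollment_soc <= n_soc && n_enrollment_intervention <= n_intervention
  )
  structure(list(
    seed = as.integer(seed), n_soc = as.integer(n_soc),
    n_intervention = as.integer(n_intervention),
    n_enrollment_soc = as.integer(n_enrollment_soc),
    n_enrollment_intervention = as.integer(n_enrollment_intervention),
    means = means, sds = sds, distribution = distribution,
    waiting_minutes = waiting_minutes
  ), class = "synth_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

draw_duration <- function(n, mean, sd, distribution) {
  if (sd == 0) return(rep(mean, n))
  if (distribution == "lognormal") {
    sdlog <- sqrt(log(1 + (sd / mean)^2))
    meanlog <- log(mean) - sdlog^2 / 2
    return(stats::rlnorm(n, meanlog, sdlog))
  }
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    bad <- out <= 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate a synthetic time-and-motion observation log
#'
#' Simulates per-visit activity records with sequential, non-overlapping
#' timestamps: each visit runs the four provider activities in clinic
#' order, with a waiting gap before dispensing. Durations are drawn from
#' the configured distribution (SD 0 yields the means exactly); identical
#' seeds yield identical logs.
#'
#' @param config A [synth_config()].
#' @return Observation-log `data.frame` satisfying
#'   [validate_observation_log()].
#' @export
#' @examples
#' log <- generate_observation_log(synth_config(seed = 1))
#' nrow(visit_totals(log)) # 22 observed visits
generate_observation_log <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  acts <- names(activity_cadre_map())
  cadre_of <- activity_cadre_map()
  with_local_seed(config$seed, {
    rows <- list()
    for (a in arms()) {
      n <- if (a == "soc") config$n_soc else config$n_intervention
      n_enr <- if (a == "soc") config$n_enrollment_soc else {
        config$n_enrollment_intervention
      }
      if (n == 0L) next
      m <- config$means[config$means$arm == a, , drop = FALSE]
      s <- config$sds[config$sds$arm == a, , drop = FALSE]
      dur <- sapply(acts, function(act) {
        draw_duration(n, m$mean_minutes[m$activity == act],
                      s$sd_minutes[s$activity == act], config$distribution)
      })
      dur <- matrix(dur, nrow = n)
      wait <- if (config$waiting_minutes > 0) {
        draw_duration(n, config$waiting_minutes, config$waiting_minutes / 4,
                      config$distribution)
      } else {
        numeric(n)
      }
      for (v in seq_len(n)) {
        vid <- sprintf("%s_%03d", a, v)
        vtype <- if (v <= n_enr) "enrollment" else "refill"
        t <- 9 * 60 # visits start at 09:00
        for (j in seq_along(acts)) {
          if (acts[j] == "prep_dispensing" && wait[v] > 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              visit_id = vid, arm = a, visit_type = vtype,
              activity = "waiting", cadre = NA_character_,
              start_time = fmt_clock(t), end_time = fmt_clock(t + wait[v]),
              stringsAsFactors = FALSE)
            t <- t + wait[v]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            visit_id = vid, arm = a, visit_type = vtype, activity = acts[j],
            cadre = unname(cadre_of[acts[j]]),
            start_time = fmt_clock(t), end_time = fmt_clock(t + dur[v, j]),
            stringsAsFactors = FALSE)
          t <- t + dur[v, j]
        }
      }
    }
    validate_observation_log(do.call(rbind, rows))
  })
}

# minutes-from-midnight -> "HH:MM:SS", whole seconds
fmt_clock <- function(min) {
  s <- round(min * 60)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Generate study accruals
#'
#' Defaults are the trial's annual accruals: 304 standard-of-care visits
#' carrying 913 client-months (quarterly visits, 3 bottles each) and 340
#' intervention visits carrying 2,039 client-months (semi-annual visits, 6
#' bottles each). When visit counts are supplied without month counts,
#' months default to `visits * bottles_per_visit`.
#'
#' @param soc_visits,intervention_visits Annual visit counts.
#' @param soc_months,intervention_months Client-month counts; `NULL` means
#'   `visits * bottles`.
#' @param soc_bottles,intervention_bottles Bottles dispensed per visit.
#' @return List with `soc` and `intervention` [accrual()]s.
#' @export
#' @examples
#' generate_accruals()          # the study's accruals
#' generate_accruals(1, 1)      # minimal single-client accrual: 3 and 6
generate_accruals <- function(soc_visits = 304L, intervention_visits = 340L,
                              soc_months = if (soc_visits == 304L) 913L,
                              intervention_months =
                                if (intervention_visits == 340L) 2039L,
                              soc_bottles = 3L, intervention_bottles = 6L) {
  soc_months <- soc_months %||% (soc_visits * soc_bottles)
  intervention_months <- intervention_months %||%
    (intervention_visits * intervention_bottles)
  list(
    soc = accrual("soc", soc_visits, soc_months,
                  visits_per_client_year = 4L,
                  bottles_per_visit = soc_bottles),
    intervention = accrual("intervention", intervention_visits,
                           intervention_months,
                           visits_per_client_year = 2L,
                           bottles_per_visit = intervention_bottles)
  )
}

#' Generate a ledger from a packaged template
#'
#' Loads one of the packaged ledger fixtures (`"trial"`, `"moh"`,
#' `"moh_creatinine"`) and optionally applies multiplicative jitter
#' `U(1 - jitter, 1 + jitter)` to every salary, unit price and item
#' amount — useful for property tests. Zero jitter returns the fixture
#' exactly; identical seeds yield identical ledgers.
#'
#' @param template `"trial"`, `"moh"` or `"moh_creatinine"`.
#' @param jitter Fraction in `[0, 1)`.
#' @param seed Integer seed; required when `jitter > 0`.
#' @return A `prep_ledger`.
#' @export
generate_ledger <- function(template = c("trial", "moh", "moh_creatinine"),
                            jitter = 0, seed = NULL) {
  template <- match.arg(template)
  path <- system.file("extdata", paste0(template, "_2019.yaml"),
                      package = "prepcost")
  led <- load_ledger(path)
  if (jitter < 0 || jitter >= 1) {
    stop("generate_ledger: `jitter` must be in [0, 1)", call. = FALSE)
  }
  if (jitter == 0) return(led)
  if (is.null(seed)) {
    stop("generate_ledger: `seed` is required when jitter > 0", call. = FALSE)
  }
  with_local_seed(seed, {
    jit <- function(x) x * stats::runif(length(x), 1 - jitter, 1 + jitter)
    led$salaries$annual_salary <- jit(led$salaries$annual_salary)
    led$unit_prices$price <- jit(led$unit_prices$price)
    led$items$amount <- jit(led$items$amount)
    led$name <- paste0(led$name, "_jittered")
    validate_ledger(led)
  })
}
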