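#' Time-stratified referent days for an event date
#'
#' Referent days are every other day in the event's calendar month (same year)
#' that falls on the same day of week as the event — the full time-stratified
#' referent set, which the calendar guarantees has 3 or 4 members.
#'
#' @param event_date A Date (or ISO-8601 string).
#' @return Sorted Date vector of 3 or 4 referent days.
#' @export
referent_days <- function(event_date) {
  event_date <- as.Date(event_date)
  stopifnot(length(event_date) == 1, !is.na(event_date))
  fom <- lubridate::floor_date(event_date, "month")
  first_match <- fom + (as.integer(event_date - fom) %% 7L)
  cand <- first_match + 7L * (0:4)
  cand <- cand[lubridate::month(cand) == lubridate::month(event_date)]
  sort(cand[cand != event_date])
}

#' Warm-season indicator
#'
#' The warm season is May 1 through September 30 (months 5--9).
#'
#' @param date Date vector.
#' @param warm_months Integer months defining the season; default `5:9`.
#' @return Logical vector.
#' @export
in_warm_season <- function(date, warm_months = 5:9) {
  lubridate::month(as.Date(date)) %in% warm_months
}

#' Classify births into preterm / early term / other
#'
#' Preterm birth (PTB) is 28--36 completed gestational weeks; early term birth
#' (ETB) is 37--38 weeks.
#'
#' @param ga_weeks Integer vector of completed gestational weeks.
#' @return Character vector `"PTB"`, `"ETB"` or `"other"`.
#' @export
classify_outcome <- function(ga_weeks) {
  dplyr::case_when(
    ga_weeks >= 28 & ga_weeks <= 36 ~ "PTB",
    ga_weeks >= 37 & ga_weeks <= 38 ~ "ETB",
    TRUE ~ "other"
  )
}

# vectorised referent expansion: one row per stratum day (event + referents)
expand_stratum_days <- function(birth_id, event_date) {
  fom <- lubridate::floor_date(event_date, "month")
  first_match <- fom + (as.integer(event_date - fom) %% 7L)
  n_rep <- as.integer(lubridate::days_in_month(event_date) -
                        as.integer(first_match - fom) + 6L) %/% 7L
  days <- rep(first_match, n_rep) + 7L * (sequence(n_rep) - 1L)
  id <- rep(birth_id, n_rep)
  ev <- rep(event_date, n_rep)
  tibble(birth_id = id, date = days, is_case = days == ev)
}

#' Assemble time-stratified case-crossover strata
#'
#' For each warm-season case of the requested outcome, builds the stratum of
#' event day plus same-month same-weekday referent days and attaches the
#' heat-wave exposure metrics and the pregnancy-risk-set adjustment to every
#' day. Cases whose stratum has any missing day-level covariate are excluded;
#' exclusions are counted by reason and attached as the `"exclusions"`
#' attribute (see [exclusion_log()]).
#'
#' @param births Birth-record tibble: `birth_id`, `state`, `zcta_id`,
#'   `birth_date`, `ga_weeks`, plus any subgroup columns to carry through.
#' @param exposures ZCTA-day exposure tibble from [compute_exposures()].
#' @param wadjust Risk-set adjustment tibble from [risk_set_adjustment()] for
#'   the same outcome (`zcta_id`, `date`, `w_i`, `boundary_flag`). Optional;
#'   when `NULL` the `w_adjust` column is omitted.
#' @param outcome `"PTB"` or `"ETB"`.
#' @param warm_months Warm-season months; default `5:9`.
#' @param boundary_policy How to treat stratum days flagged as having a
#'   right-truncated risk set: `"exclude"` drops the stratum (default),
#'   `"flag"` keeps it and carries the flag, `"ignore"` drops the flag.
#' @param carry Extra birth-level columns to carry onto the stratum rows;
#'   defaults to all columns of `births` other than the required ones.
#'
#' @return Long-format tibble with class `"cc_strata"`: one row per stratum
#'   day with `birth_id`, `state`, `zcta_id`, carried columns, `date`,
#'   `is_case`, `run_length`, `aat`, `hw_ge2`, `hw_ge3`, `hw_eq4`,
#'   `w_adjust`. Strata have 4 or 5 days and exactly one case day.
#' @export
case_crossover_strata <- function(births, exposures, wadjust = NULL,
                                  outcome = c("PTB", "ETB"),
                                  warm_months = 5:9,
                                  boundary_policy = c("exclude", "flag", "ignore"),
                                  carry = NULL) {
  outcome <- match.arg(outcome)
  boundary_policy <- match.arg(boundary_policy)
  births <- as_tibble(births)
  births$birth_date <- as.Date(births$birth_date)
  if (is.null(carry)) {
    carry <- setdiff(names(births),
                     c("birth_id", "birth_date", "ga_weeks", "state", "zcta_id"))
  }

  excl <- list()
  n0 <- nrow(births)
  is_case <- classify_outcome(births$ga_weeks) == outcome
  excl$not_case <- sum(!is_case)
  cases <- births[is_case, , drop = FALSE]
  in_season <- in_warm_season(cases$birth_date, warm_months)
  excl$outside_warm_season <- sum(!in_season)
  cases <- cases[in_season, , drop = FALSE]

  if (nrow(cases) == 0) {
    warn(paste0("no eligible ", outcome, " cases"))
    out <- tibble(birth_id = character(), date = as.Date(character()),
                  is_case = logical())
    return(new_cc_strata(out, excl))
  }

  days <- expand_stratum_days(cases$birth_id, cases$birth_date)
  days <- days |>
    left_join(cases[, unique(c("birth_id", "state", "zcta_id", carry))],
              by = "birth_id") |>
    left_join(exposures |> select(any_of(c(
      "zcta_id", "date", "run_length", "aat",
      "hw_ge2", "hw_ge3", "hw_eq4"))), by = c("zcta_id", "date"))

  if (!is.null(wadjust)) {
    wa <- wadjust |> select(any_of(c("zcta_id", "date", "w_i", "boundary_flag")))
    days <- days |>
      left_join(wa, by = c("zcta_id", "date")) |>
      rename(w_adjust = "w_i")
    if (!"boundary_flag" %in% names(days)) days$boundary_flag <- FALSE
    days$boundary_flag[is.na(days$boundary_flag)] <- FALSE
  }

  bad_expo <- days |> filter(is.na(.data$aat)) |> distinct(.data$birth_id)
  excl$missing_exposure <- nrow(bad_expo)
  days <- days |> filter(!.data$birth_id %in% bad_expo$birth_id)

  if (!is.null(wadjust)) {
    bad_w <- days |> filter(is.na(.data$w_adjust)) |> distinct(.data$birth_id)
    excl$missing_adjustment <- nrow(bad_w)
    days <- days |> filter(!.data$birth_id %in% bad_w$birth_id)
    if (boundary_policy == "exclude") {
      bad_b <- days |> filter(.data$boundary_flag) |> distinct(.data$birth_id)
      excl$truncated_risk_set <- nrow(bad_b)
      days <- days |> filter(!.data$birth_id %in% bad_b$birth_id)
    }
    if (boundary_policy != "flag") days$boundary_flag <- NULL
  }

  days <- days |> arrange(.data$birth_id, .data$date)
  stopifnot(sum(days$is_case) == length(unique(days$birth_id)))
  new_cc_strata(days, excl)
}

new_cc_strata <- function(days, excl) {
  log <- tibble(reason = names(excl), n = unlist(excl, use.names = FALSE))
  structure(days, exclusions = log,
            class = c("cc_strata", class(tibble())))
}

#' Exclusion log of a case-crossover stratum table
#'
#' @param strata Object returned by [case_crossover_strata()].
#' @return Tibble with columns `reason`, `n`.
#' @export
exclusion_log <- function(strata) {
  attr(strata, "exclusions")
}
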