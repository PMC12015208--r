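#' Gestational week of a pregnancy on a calendar day
#'
#' The pregnancy start is reconstructed as `birth_date - 7 * ga_weeks` days, so
#' the pregnancy spends exactly seven days in each completed week `0 ..
#' ga_weeks - 1` and is counted as an event (not at risk) on the birth day
#' itself.
#'
#' @param birth_date Date vector of birth days.
#' @param ga_weeks Completed gestational weeks at birth.
#' @param day Calendar day (scalar or vector recycled against the births).
#' @return Integer week on `day` for ongoing pregnancies, `NA` where the
#'   pregnancy is not ongoing (before start, or on/after the birth day).
#' @export
gestational_week_on_day <- function(birth_date, ga_weeks, day) {
  birth_date <- as.Date(birth_date)
  day <- as.Date(day)
  start <- birth_date - 7L * as.integer(ga_weeks)
  week <- as.integer(as.integer(day - start) %/% 7L)
  week[day < start | day >= birth_date] <- NA_integer_
  week
}

#' Gestational-week birth hazard from all births
#'
#' For each state, estimates `W_g`, the probability of birth at completed week
#' `g` among pregnancies reaching week `g` (a discrete hazard): the number of
#' births at week `g` divided by the number at week `g` or later. All births —
#' every outcome class — contribute.
#'
#' @param births Birth-record tibble with `state` and `ga_weeks`.
#' @return Tibble `state`, `g`, `w_g`, covering every week from the minimum to
#'   the maximum observed within state.
#' @export
birth_week_hazard <- function(births) {
  if (nrow(births) == 0) abort("empty birth table")
  births |>
    as_tibble() |>
    summarise(n = dplyr::n(), .by = c("state", "ga_weeks")) |>
    rename(g = "ga_weeks") |>
    group_by(.data$state) |>
    # weeks below the earliest observed birth have hazard 0 (everyone at
    # risk, nobody delivers); weeks above the latest stay undefined
    tidyr::complete(g = tidyr::full_seq(c(20, .data$g), 1),
                    fill = list(n = 0L)) |>
    arrange(.data$g, .by_group = TRUE) |>
    mutate(
      at_risk = rev(cumsum(rev(.data$n))),
      w_g = .data$n / .data$at_risk
    ) |>
    ungroup() |>
    select("state", "g", "w_g")
}

risk_range <- function(outcome) {
  switch(outcome, PTB = 28:36, ETB = 37:38,
         abort("outcome must be 'PTB' or 'ETB'"))
}

#' Daily pregnancy-risk-set adjustment W_i
#'
#' For each ZCTA-day, computes the average probability of birth among ongoing
#' pregnancies at risk of the outcome:
#' `W_i = sum_g Z_ig * W_g / Z_i`, where `Z_ig` counts ongoing pregnancies at
#' gestational week `g` (`g` in 28--36 for PTB, 37--38 for ETB), `Z_i` counts
#' all ongoing pregnancies in the ZCTA on day `i`, and `W_g` is the state
#' week-`g` birth hazard from [birth_week_hazard()]. This covariate absorbs
#' within-month trends in the number and gestational-age mix of pregnancies at
#' risk (conception seasonality, secular trends) that would otherwise bias the
#' case-crossover contrast.
#'
#' @param births Birth-record tibble (`birth_id`, `state`, `zcta_id`,
#'   `birth_date`, `ga_weeks`) — all births, not only cases.
#' @param outcome `"PTB"` or `"ETB"`.
#' @param week_hazard Optional precomputed [birth_week_hazard()] table.
#' @param dates Optional Date vector (range of days wanted); defaults to the
#'   span from the earliest pregnancy start to the day before the last birth.
#' @param data_end Administrative end of the birth register, if the register
#'   is right-truncated: days later than `data_end - 45*7` days are flagged
#'   (`boundary_flag`) because pregnancies delivering after `data_end` are
#'   unobserved and the risk set is understated. `NULL` (default) declares the
#'   register complete, so nothing is flagged.
#'
#' @return Tibble `zcta_id`, `date`, `outcome`, `z_total`, `w_i`,
#'   `boundary_flag`. Days with no ongoing pregnancy (`z_total == 0`) have
#'   `w_i = NA` and are excluded downstream.
#' @export
risk_set_adjustment <- function(births, outcome = c("PTB", "ETB"),
                                week_hazard = NULL, dates = NULL,
                                data_end = NULL) {
  outcome <- match.arg(outcome)
  births <- as_tibble(births)
  births$birth_date <- as.Date(births$birth_date)
  if (is.null(week_hazard)) week_hazard <- birth_week_hazard(births)
  rng <- risk_range(outcome)

  ga <- as.integer(births$ga_weeks)
  start <- births$birth_date - 7L * ga
  if (is.null(dates)) {
    dates <- seq(min(start), max(births$birth_date) - 1L, by = "day")
  } else {
    dates <- seq(min(as.Date(dates)), max(as.Date(dates)), by = "day")
  }
  origin <- dates[1]
  n_days <- length(dates)

  zctas <- sort(unique(births$zcta_id))
  zi <- match(births$zcta_id, zctas)
  n_z <- length(zctas)

  # per-birth W_g of its state at each risk-range week
  wg <- week_hazard
  key <- paste(wg$state, wg$g)
  wg_lookup <- setNames(wg$w_g, key)
  need <- unique(paste(rep(unique(births$state), each = length(rng)), rng))
  if (anyNA(wg_lookup[need])) {
    abort("week hazard undefined for a week in the outcome risk range")
  }

  day0 <- as.integer(start - origin)          # first ongoing day index (0-based)
  day_end <- as.integer(births$birth_date - origin)  # first day NOT ongoing

  # difference-array accumulation on a (day x zcta) grid
  accumulate <- function(d_start, d_stop, weight, zidx) {
    # contributes `weight` to days [d_start, d_stop) clipped to [0, n_days)
    d_start <- pmax(d_start, 0L)
    d_stop <- pmin(d_stop, n_days)
    keep <- d_start < d_stop
    d_start <- d_start[keep]; d_stop <- d_stop[keep]
    weight <- weight[keep]; zidx <- zidx[keep]
    delta <- matrix(0, n_days + 1L, n_z)
    up <- rowsum(weight, d_start + (zidx - 1L) * (n_days + 1L))
    delta[as.integer(rownames(up)) + 1L] <- up
    dn <- rowsum(weight, d_stop + (zidx - 1L) * (n_days + 1L))
    delta[as.integer(rownames(dn)) + 1L] <-
      delta[as.integer(rownames(dn)) + 1L] - dn
    apply(delta[seq_len(n_days), , drop = FALSE], 2, cumsum)
  }

  z_total <- accumulate(day0, day_end, rep(1, length(day0)), zi)

  # numerator sum_g Z_ig * W_g: each birth contributes W_g over its week-g days
  m <- length(rng)
  g_rep <- rep(rng, times = length(ga))
  ga_rep <- rep(ga, each = m)
  keep <- g_rep < ga_rep           # week g fully lived iff g <= ga - 1
  b_idx <- rep(seq_along(ga), each = m)[keep]
  g_kept <- g_rep[keep]
  num <- accumulate(
    day0[b_idx] + 7L * g_kept,
    day0[b_idx] + 7L * g_kept + 7L,
    wg_lookup[paste(births$state[b_idx], g_kept)],
    zi[b_idx]
  )

  w_i <- ifelse(z_total > 0, num / pmax(z_total, 1), NA_real_)

  flag_from <- if (is.null(data_end)) {
    as.integer(n_days)  # never
  } else {
    as.integer(as.Date(data_end) - 45L * 7L - origin) + 1L
  }

  tibble(
    zcta_id = rep(zctas, each = n_days),
    date = rep(dates, times = n_z),
    outcome = outcome,
    z_total = as.vector(z_total),
    w_i = as.vector(w_i),
    boundary_flag = rep(seq_len(n_days) - 1L >= flag_from, times = n_z)
  )
}
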