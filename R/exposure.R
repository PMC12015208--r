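#' Aggregate gridded daily temperatures to ZCTA daily mean series
#'
#' Averages daily minimum and maximum temperatures over all grid points mapped
#' to each ZIP Code Tabulation Area (ZCTA) and forms the daily mean as the
#' midpoint of the two averages, the standard convention for min/max pairs.
#'
#' @param grid_temps Data frame with columns `point_id`, `date` (Date or
#'   ISO-8601 string), `tmin_c`, `tmax_c` (degrees Celsius).
#' @param grid_map Data frame with columns `point_id`, `zcta_id` mapping each
#'   grid point to the ZCTA containing it.
#'
#' @details Every mapped grid point must have a temperature record for every
#'   date present in `grid_temps`; missing point-days are a hard error (no
#'   imputation), as is a ZCTA with no mapped points or a mapping that names an
#'   unknown point.
#'
#' @return A tibble with columns `zcta_id`, `date`, `avg_tmin_c`, `avg_tmax_c`,
#'   `tmean_c`, sorted by ZCTA and date.
#' @export
zcta_daily_series <- function(grid_temps, grid_map) {
  grid_temps <- as_tibble(grid_temps)
  grid_map <- as_tibble(grid_map)
  stopifnot(all(c("point_id", "date", "tmin_c", "tmax_c") %in% names(grid_temps)),
            all(c("point_id", "zcta_id") %in% names(grid_map)))
  grid_temps$date <- as.Date(grid_temps$date)

  unknown <- setdiff(grid_map$point_id, grid_temps$point_id)
  if (length(unknown) > 0) {
    abort(paste0("grid_map references unknown point id(s): ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  empty <- grid_map |> count(.data$zcta_id) |> filter(.data$n == 0)
  if (nrow(empty) > 0) {
    abort(paste0("ZCTA with zero mapped grid points: ",
                 paste(empty$zcta_id, collapse = ", ")))
  }
  if (any(grid_temps$tmin_c > grid_temps$tmax_c)) {
    abort("tmin_c > tmax_c in grid_temps")
  }

  n_dates <- length(unique(grid_temps$date))
  per_point <- grid_temps |> count(.data$point_id)
  if (any(per_point$n != n_dates)) {
    bad <- per_point$point_id[per_point$n != n_dates]
    abort(paste0("missing date(s) for grid point(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }

  grid_map |>
    inner_join(grid_temps, by = "point_id", relationship = "many-to-many") |>
    summarise(
      avg_tmin_c = mean(.data$tmin_c),
      avg_tmax_c = mean(.data$tmax_c),
      .by = c("zcta_id", "date")
    ) |>
    mutate(tmean_c = (.data$avg_tmin_c + .data$avg_tmax_c) / 2) |>
    arrange(.data$zcta_id, .data$date)
}

#' Relative hot-day threshold for a temperature series
#'
#' The ZCTA-specific hot-day threshold is an upper percentile (default 97.5th)
#' of the daily mean temperature over the full multi-year series, all seasons
#' included.
#'
#' @param tmean Numeric vector of daily mean temperatures (degrees Celsius).
#' @param percentile Percentile in (0, 100); default 97.5.
#' @param type Quantile plumbing position passed to [stats::quantile()];
#'   default 6 (Weibull, linear interpolation of `(n+1)p` order statistics).
#'
#' @return Threshold in degrees Celsius.
#' @export
hot_day_threshold <- function(tmean, percentile = 97.5, type = 6) {
  if (length(tmean) == 0) abort("empty temperature series")
  if (anyNA(tmean) || any(!is.finite(tmean))) abort("tmean must be finite")
  if (percentile <= 0 || percentile >= 100) abort("percentile must be in (0, 100)")
  unname(quantile(tmean, probs = percentile / 100, type = type))
}

#' Longest run of consecutive hot days in a 4-day window
#'
#' A day is hot when its mean temperature strictly exceeds the threshold; ties
#' at the threshold do not count.
#'
#' @param window_temps Exactly 4 daily mean temperatures, in calendar order.
#' @param threshold Hot-day threshold (degrees Celsius).
#' @return Integer in 0..4: length of the longest run of consecutive
#'   exceedances within the window.
#' @export
window_run_length <- function(window_temps, threshold) {
  if (length(window_temps) != 4) abort("window must contain exactly 4 values")
  hot <- window_temps > threshold
  r <- rle(hot)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}

#' Average degrees above threshold (AAT) over a 4-day window
#'
#' Mean of the 4 daily temperatures minus the threshold, floored at zero.
#' Days below the threshold count negatively before the floor is applied, so
#' the metric reflects both intensity and duration of a hot spell.
#'
#' @inheritParams window_run_length
#' @return AAT in degrees Celsius, `>= 0`.
#' @export
window_aat <- function(window_temps, threshold) {
  if (length(window_temps) != 4) abort("window must contain exactly 4 values")
  max(0, mean(window_temps) - threshold)
}

# lookup of longest run for each of the 16 exceedance patterns of a 4-day
# window, indexed by 1 + sum(hot * c(8,4,2,1))
run_length_table <- local({
  tab <- integer(16)
  for (code in 0:15) {
    hot <- as.logical(bitwAnd(code, c(8L, 4L, 2L, 1L)) > 0L)
    r <- rle(hot)
    runs <- r$lengths[r$values]
    tab[code + 1L] <- if (length(runs) == 0) 0L else max(runs)
  }
  tab
})

#' Heat-wave exposure metrics for one date
#'
#' Computes the 4-day-window metrics (window = the date itself plus the three
#' preceding days, i.e. lags 0--3) for a single ZCTA date.
#'
#' @param series A tibble for one ZCTA with columns `date`, `tmean_c` and a
#'   `threshold_c` column (or supply `threshold`).
#' @param date Date of interest (window end).
#' @param threshold Optional threshold overriding `series$threshold_c`.
#' @return One-row tibble with `zcta_id` (if present), `date`, `run_length`,
#'   `aat`, `hw_ge2`, `hw_ge3`, `hw_eq4`; all metric columns are `NA` when the
#'   window extends before the series start (missing-exposure signal).
#' @export
exposure_for_date <- function(series, date, threshold = NULL) {
  date <- as.Date(date)
  if (is.null(threshold)) threshold <- series$threshold_c[1]
  idx <- match(date - 3:0, series$date)
  zid <- if ("zcta_id" %in% names(series)) series$zcta_id[1] else NA_character_
  if (anyNA(idx)) {
    return(tibble(zcta_id = zid, date = date, run_length = NA_integer_,
                  aat = NA_real_, hw_ge2 = NA, hw_ge3 = NA, hw_eq4 = NA))
  }
  w <- series$tmean_c[idx]
  rl <- window_run_length(w, threshold)
  tibble(
    zcta_id = zid, date = date,
    run_length = rl, aat = window_aat(w, threshold),
    hw_ge2 = rl >= 2L, hw_ge3 = rl >= 3L, hw_eq4 = rl == 4L
  )
}

#' Heat-wave exposure metrics for every ZCTA-day
#'
#' Vectorised computation of the relative-threshold heat-wave metrics over a
#' ZCTA daily mean temperature table: hot-day threshold per ZCTA (over the full
#' series), then for each date the 4-day window (lags 0--3) run length of
#' consecutive hot days, the average degrees above threshold (AAT, floored at
#' zero), and the dichotomous definitions `hw_ge2` (run length >= 2), `hw_ge3`
#' (>= 3) and `hw_eq4` (all 4 days hot).
#'
#' @param zcta_tmean Tibble from [zcta_daily_series()] (columns `zcta_id`,
#'   `date`, `tmean_c`); dates must be contiguous within ZCTA.
#' @param percentile,type Passed to [hot_day_threshold()].
#' @return Tibble `zcta_id`, `date`, `tmean_c`, `threshold_c`, `run_length`,
#'   `aat`, `hw_ge2`, `hw_ge3`, `hw_eq4`. The first three dates of each series
#'   have `NA` metrics (incomplete window).
#' @export
compute_exposures <- function(zcta_tmean, percentile = 97.5, type = 6) {
  zcta_tmean |>
    as_tibble() |>
    arrange(.data$zcta_id, .data$date) |>
    group_by(.data$zcta_id) |>
    group_modify(function(df, key) {
      d <- as.integer(diff(df$date))
      if (length(d) && any(d != 1L)) {
        abort(paste0("dates not contiguous for ZCTA ", key$zcta_id[1]))
      }
      thr <- hot_day_threshold(df$tmean_c, percentile = percentile, type = type)
      n <- nrow(df)
      hot <- df$tmean_c > thr
      rl <- rep(NA_integer_, n)
      aat <- rep(NA_real_, n)
      if (n >= 4) {
        i <- 4:n
        code <- hot[i - 3] * 8L + hot[i - 2] * 4L + hot[i - 1] * 2L + hot[i]
        rl[i] <- run_length_table[code + 1L]
        cs <- cumsum(df$tmean_c)
        win_mean <- (cs[i] - c(0, cs)[i - 3]) / 4
        aat[i] <- pmax(0, win_mean - thr)
      }
      df |> mutate(
        threshold_c = thr, run_length = rl, aat = aat,
        hw_ge2 = rl >= 2L, hw_ge3 = rl >= 3L, hw_eq4 = rl == 4L
      )
    }) |>
    ungroup() |>
    select(any_of(c("zcta_id", "date", "tmean_c", "threshold_c",
                    "run_length", "aat", "hw_ge2", "hw_ge3", "hw_eq4")))
}
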