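#' Default weekly birth hazards
#'
#' Baseline probability of birth at each completed gestational week `g` among
#' pregnancies reaching `g`, for weeks 20--45. The defaults give roughly 1%
#' of births before week 28, 8--9% preterm (28--36), 24--25% early term
#' (37--38), and the remainder at term, with certain birth by week 45.
#'
#' @return Named numeric vector, names `"20"`..`"45"`.
#' @export
default_week_hazard <- function() {
  c(
    `20` = 8e-4, `21` = 8e-4, `22` = 1e-3, `23` = 1e-3, `24` = 1.2e-3,
    `25` = 1.5e-3, `26` = 2e-3, `27` = 2.5e-3,
    `28` = 3e-3, `29` = 4e-3, `30` = 5e-3, `31` = 6e-3, `32` = 8e-3,
    `33` = 0.010, `34` = 0.013, `35` = 0.017, `36` = 0.022,
    `37` = 0.12, `38` = 0.17,
    `39` = 0.42, `40` = 0.55, `41` = 0.70, `42` = 0.85, `43` = 0.95,
    `44` = 0.99, `45` = 1.0
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: the spatial layout, the
#' ZCTA temperature process (seasonal cycle plus AR(1) day-to-day
#' persistence), the gestational baseline hazards, the multiplicative heat
#' effect on the daily birth hazard, and population mixing proportions.
#'
#' @param n_states Number of states.
#' @param zctas_per_state ZCTAs per state.
#' @param pregnancies_per_zcta Pregnancies per ZCTA.
#' @param years Number of conception years (conceptions are drawn uniformly,
#'   up to seasonality, over this window; temperatures extend 46 weeks past
#'   it so every pregnancy is fully exposed and observed).
#' @param start_year First conception year.
#' @param seed Integer seed; all randomness in [simulate_study()] flows from
#'   one generator seeded with it.
#' @param temp_mean_c,temp_amplitude_c Annual mean and seasonal semi-amplitude
#'   of the latent daily mean temperature (degrees Celsius).
#' @param temp_peak_doy Day of year of the seasonal peak (196 = mid July).
#' @param temp_rho AR(1) coefficient of the deseasonalised daily series.
#' @param temp_innovation_sd_c AR(1) innovation standard deviation (degrees C).
#' @param temp_offset_sd_c Standard deviation of the per-ZCTA (e.g. urban
#'   heat island) temperature offset.
#' @param diurnal_half_range_c Half the diurnal range: emitted
#'   `tmin = latent - delta`, `tmax = latent + delta`.
#' @param points_per_zcta Grid points mapped to each ZCTA.
#' @param week_hazard Named weekly hazard vector, see [default_week_hazard()].
#' @param beta Log-odds heat effect per degree Celsius of 4-day AAT applied to
#'   the daily birth hazard: either a scalar, or a named vector over the
#'   levels of `beta_modifier`.
#' @param beta_modifier Optional pregnancy-level column name (e.g.
#'   `"age_group"` or `"sdi_group"`) whose levels index `beta`.
#' @param effect_weeks Gestational weeks during which the heat effect acts;
#'   default 28--38 (the preterm and early term risk window).
#' @param age_props,edu_props Multinomial proportions for maternal age and
#'   education groups.
#' @param states_missing_edu States whose records carry no education data
#'   (`edu_group = "missing"`).
#' @param conception_amplitude Relative amplitude of conception-date
#'   seasonality (0 = uniform).
#' @param conception_peak_doy Day of year of the conception peak.
#' @param area_temp_cor Correlation (Gaussian copula) between the ZCTA
#'   temperature offset and its social deprivation / impervious-cover scores.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_states = 4,
                       zctas_per_state = 25,
                       pregnancies_per_zcta = 2000,
                       years = 3,
                       start_year = 2010,
                       seed = 1L,
                       temp_mean_c = 15,
                       temp_amplitude_c = 10,
                       temp_peak_doy = 196,
                       temp_rho = 0.75,
                       temp_innovation_sd_c = 2,
                       temp_offset_sd_c = 1.5,
                       diurnal_half_range_c = 5,
                       points_per_zcta = 3,
                       week_hazard = default_week_hazard(),
                       beta = 0,
                       beta_modifier = NULL,
                       effect_weeks = 28:38,
                       age_props = c("<25" = 0.31, "25-34" = 0.52, "35+" = 0.17),
                       edu_props = c("<HS" = 0.25, "HS/GED" = 0.30, ">HS" = 0.45),
                       states_missing_edu = character(),
                       conception_amplitude = 0.1,
                       conception_peak_doy = 250,
                       area_temp_cor = 0.3) {
  stopifnot(temp_rho >= 0, temp_rho < 1,
            all(week_hazard >= 0), all(week_hazard <= 1),
            abs(sum(age_props) - 1) < 1e-8, abs(sum(edu_props) - 1) < 1e-8)
  if (!is.null(beta_modifier) && is.null(names(beta))) {
    abort("beta must be a named vector when beta_modifier is set")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

sim_date_range <- function(config) {
  start <- as.Date(sprintf("%d-01-01", config$start_year))
  end <- as.Date(sprintf("%d-12-31", config$start_year + config$years - 1))
  list(conception_start = start, conception_end = end,
       temp_start = start - 7L, temp_end = end + 46L * 7L)
}

#' Generate gridded daily temperatures and the grid-to-ZCTA mapping
#'
#' Each grid point follows `latent(d) = mean + amplitude *
#' cos(2*pi*(doy(d) - peak)/365.25) + zcta_offset + AR1(rho, sd)`, and emits
#' `tmin = latent - delta`, `tmax = latent + delta`. Uses the current RNG
#' state; [simulate_study()] seeds it once from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `grid_temps` (`point_id`, `date`, `tmin_c`,
#'   `tmax_c`), `grid_map` (`point_id`, `zcta_id`), and `zcta_meta`
#'   (`zcta_id`, `state`, `offset_c`).
#' @export
gen_temperature <- function(config) {
  rng <- sim_date_range(config)
  dates <- seq(rng$temp_start, rng$temp_end, by = "day")
  n_days <- length(dates)
  doy <- lubridate::yday(dates)
  seasonal <- config$temp_mean_c + config$temp_amplitude_c *
    cos(2 * pi * (doy - config$temp_peak_doy) / 365.25)

  n_zcta <- config$n_states * config$zctas_per_state
  zcta_ids <- sprintf("Z%03d", seq_len(n_zcta))
  states <- sprintf("S%d", rep(seq_len(config$n_states),
                               each = config$zctas_per_state))
  offsets <- rnorm(n_zcta, 0, config$temp_offset_sd_c)

  ppz <- config$points_per_zcta
  n_pts <- n_zcta * ppz
  point_ids <- sprintf("P%05d", seq_len(n_pts))
  pt_zcta <- rep(seq_len(n_zcta), each = ppz)

  rho <- config$temp_rho
  sd0 <- config$temp_innovation_sd_c / sqrt(1 - rho^2)
  innov <- matrix(rnorm(n_days * n_pts, 0, config$temp_innovation_sd_c),
                  n_days, n_pts)
  innov[1, ] <- rnorm(n_pts, 0, sd0)  # stationary start
  ar1 <- apply(innov, 2, function(e) {
    as.numeric(stats::filter(e, rho, method = "recursive"))
  })
  latent <- seasonal + sweep(ar1, 2, offsets[pt_zcta], `+`)

  delta <- config$diurnal_half_range_c
  grid_temps <- tibble(
    point_id = rep(point_ids, each = n_days),
    date = rep(dates, times = n_pts),
    tmin_c = as.vector(latent) - delta,
    tmax_c = as.vector(latent) + delta
  )
  list(
    grid_temps = grid_temps,
    grid_map = tibble(point_id = point_ids, zcta_id = zcta_ids[pt_zcta]),
    zcta_meta = tibble(zcta_id = zcta_ids, state = states, offset_c = offsets)
  )
}

#' Generate the pregnancy roster and area attributes
#'
#' Conception dates follow a sinusoidal seasonal density; maternal age and
#' education groups are multinomial; each ZCTA receives a Social Deprivation
#' Index centile (1--100) and a medium/high-intensity impervious-cover
#' fraction, both optionally correlated with the ZCTA temperature offset
#' through a Gaussian copula.
#'
#' @param config A [sim_config()].
#' @param zcta_meta `zcta_meta` tibble from [gen_temperature()].
#' @return List with tibbles `pregnancies` (`preg_id`, `state`, `zcta_id`,
#'   `conception_date`, `age_group`, `edu_group`) and `area` (`zcta_id`,
#'   `state`, `sdi_score`, `imperv_frac`).
#' @export
gen_population <- function(config, zcta_meta) {
  rng <- sim_date_range(config)
  days <- seq(rng$conception_start, rng$conception_end, by = "day")
  doy <- lubridate::yday(days)
  wts <- 1 + config$conception_amplitude *
    cos(2 * pi * (doy - config$conception_peak_doy) / 365.25)

  n_zcta <- nrow(zcta_meta)
  n <- n_zcta * config$pregnancies_per_zcta
  zidx <- rep(seq_len(n_zcta), each = config$pregnancies_per_zcta)

  pregnancies <- tibble(
    preg_id = sprintf("B%07d", seq_len(n)),
    state = zcta_meta$state[zidx],
    zcta_id = zcta_meta$zcta_id[zidx],
    conception_date = sample(days, n, replace = TRUE, prob = wts),
    age_group = sample(names(config$age_props), n, replace = TRUE,
                       prob = config$age_props),
    edu_group = sample(names(config$edu_props), n, replace = TRUE,
                       prob = config$edu_props)
  )
  pregnancies$edu_group[pregnancies$state %in% config$states_missing_edu] <-
    "missing"

  r <- config$area_temp_cor
  z_off <- as.numeric(scale(zcta_meta$offset_c))
  if (any(!is.finite(z_off))) z_off <- rep(0, n_zcta)
  g1 <- r * z_off + sqrt(1 - r^2) * rnorm(n_zcta)
  g2 <- r * z_off + sqrt(1 - r^2) * rnorm(n_zcta)
  area <- tibble(
    zcta_id = zcta_meta$zcta_id,
    state = zcta_meta$state,
    sdi_score = pmax(1L, ceiling(100 * pnorm(g1))),
    imperv_frac = round(pnorm(g2)^1.3, 4)
  )
  list(pregnancies = pregnancies, area = area)
}

#' Generate birth records under a known heat effect
#'
#' Simulates each pregnancy day by day from week 20: the probability of birth
#' on a day at completed week `g` is
#' `1 - (1 - W_g)^(1/7)` (so the weekly hazard equals `W_g` without heat)
#' multiplied by `exp(beta * AAT)` during the effect weeks, where `AAT` is the
#' 4-day average-degrees-above-threshold of the pregnancy's ZCTA on that day.
#' The first success is the birth day; any pregnancy still ongoing at week 45
#' is delivered then (the final weekly hazard is 1).
#'
#' @param pregnancies Pregnancy tibble from [gen_population()].
#' @param exposures ZCTA-day exposure tibble from [compute_exposures()]
#'   covering every day any pregnancy could give birth.
#' @param config A [sim_config()].
#' @return Birth-record tibble: `birth_id`, `state`, `zcta_id`, `birth_date`,
#'   `ga_weeks`, `age_group`, `edu_group` (plus any extra pregnancy columns).
#' @export
gen_births <- function(pregnancies, exposures, config) {
  n <- nrow(pregnancies)
  zctas <- sort(unique(exposures$zcta_id))
  origin <- min(exposures$date)
  n_days <- as.integer(max(exposures$date) - origin) + 1L
  A <- matrix(NA_real_, n_days, length(zctas))
  A[cbind(as.integer(exposures$date - origin) + 1L,
          match(exposures$zcta_id, zctas))] <- exposures$aat

  weeks <- 20:45
  t_days <- (min(weeks) * 7L):(max(weeks) * 7L + 6L)
  wk_of_t <- t_days %/% 7L
  wh <- config$week_hazard[as.character(wk_of_t)]
  if (anyNA(wh)) abort("week_hazard must cover weeks 20..45")
  h_day <- 1 - (1 - wh)^(1 / 7)
  in_effect <- wk_of_t %in% config$effect_weeks

  if (is.null(config$beta_modifier)) {
    beta_i <- rep(unname(config$beta[1]), n)
  } else {
    lev <- pregnancies[[config$beta_modifier]]
    beta_i <- unname(config$beta[lev])
    if (anyNA(beta_i)) abort("beta has no value for some beta_modifier level")
  }

  conc_idx <- as.integer(as.Date(pregnancies$conception_date) - origin) + 1L
  zidx <- match(pregnancies$zcta_id, zctas)
  if (anyNA(zidx)) abort("pregnancy ZCTA missing from exposures")

  log_u <- log(runif(n))
  log_surv <- numeric(n)
  born_t <- rep(NA_integer_, n)
  for (j in seq_along(t_days)) {
    active <- which(is.na(born_t))
    if (length(active) == 0) break
    di <- conc_idx[active] + t_days[j]
    if (any(di > n_days)) abort("exposures do not cover the full risk period")
    aat <- A[cbind(di, zidx[active])]
    if (anyNA(aat)) abort("missing exposure during the risk period")
    lam <- h_day[j]
    if (in_effect[j]) {
      lam <- pmin(lam * exp(beta_i[active] * aat), 0.999)
    }
    if (wk_of_t[j] == 45L) lam <- 1  # forced delivery in the final week
    log_surv[active] <- log_surv[active] + log1p(-pmin(lam, 1))
    newly <- active[log_surv[active] < log_u[active] | lam >= 1]
    born_t[newly] <- t_days[j]
  }

  out <- pregnancies |>
    mutate(
      birth_id = .data$preg_id,
      birth_date = as.Date(.data$conception_date) + born_t,
      ga_weeks = born_t %/% 7L
    ) |>
    select(-"preg_id", -"conception_date") |>
    relocate("birth_id")
  attr(out, "n_forced") <- sum(born_t %/% 7L == 45L)
  out
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator with one seeded RNG: temperatures, exposure
#' metrics, population, area attributes, and birth records.
#'
#' @param config A [sim_config()].
#' @param keep_grid Keep the (large) grid-level temperature tables in the
#'   result; default `FALSE`.
#' @return List of class `"heatbirth_sim"`: `births`, `exposures`, `area`,
#'   `pregnancies`, `zcta_meta`, `truth` (the configuration, including the
#'   seed), and optionally `grid_temps`/`grid_map`.
#' @export
simulate_study <- function(config = sim_config(), keep_grid = FALSE) {
  set.seed(config$seed)
  tmp <- gen_temperature(config)
  series <- zcta_daily_series(tmp$grid_temps, tmp$grid_map)
  exposures <- compute_exposures(series)
  pop <- gen_population(config, tmp$zcta_meta)
  # area-derived subgroup labels (SDI, land cover) are attached before birth
  # simulation so `beta_modifier` can address them
  pop$pregnancies <- add_strata_vars(pop$pregnancies, pop$area)
  births <- gen_births(pop$pregnancies, exposures, config)
  out <- list(
    births = births, exposures = exposures, area = pop$area,
    pregnancies = pop$pregnancies, zcta_meta = tmp$zcta_meta,
    truth = unclass(config)
  )
  if (keep_grid) {
    out$grid_temps <- tmp$grid_temps
    out$grid_map <- tmp$grid_map
  }
  structure(out, class = "heatbirth_sim")
}
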