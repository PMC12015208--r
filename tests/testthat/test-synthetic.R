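test_that("temperature generator is seeded, seasonal and autocorrelated", {
  cfg <- sim_config(n_states = 1, zctas_per_state = 2, points_per_zcta = 2,
                    years = 1, seed = 5)
  set.seed(cfg$seed)
  a <- gen_temperature(cfg)
  set.seed(cfg$seed)
  b <- gen_temperature(cfg)
  expect_identical(a$grid_temps, b$grid_temps)

  # degenerate config: no noise, no seasonality, no offsets -> constant mean
  cfg0 <- sim_config(n_states = 1, zctas_per_state = 1, points_per_zcta = 1,
                     years = 1, seed = 5, temp_amplitude_c = 0,
                     temp_innovation_sd_c = 1e-12, temp_offset_sd_c = 0)
  set.seed(1)
  flat <- gen_temperature(cfg0)
  expect_equal((flat$grid_temps$tmin_c + flat$grid_temps$tmax_c) / 2,
               rep(cfg0$temp_mean_c, nrow(flat$grid_temps)),
               tolerance = 1e-6)

  # lag-1 autocorrelation of the deseasonalised series is close to rho
  cfg10 <- sim_config(n_states = 1, zctas_per_state = 1, points_per_zcta = 1,
                      years = 10, seed = 6, temp_offset_sd_c = 0)
  set.seed(cfg10$seed)
  long <- gen_temperature(cfg10)
  tm <- (long$grid_temps$tmin_c + long$grid_temps$tmax_c) / 2
  doy <- lubridate::yday(long$grid_temps$date)
  seasonal <- cfg10$temp_mean_c + cfg10$temp_amplitude_c *
    cos(2 * pi * (doy - cfg10$temp_peak_doy) / 365.25)
  resid <- tm - seasonal
  r1 <- stats::acf(resid, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1 - cfg10$temp_rho), 0.05)

  # the hottest days cluster at the configured mid-July peak
  hottest <- long$grid_temps$date[order(tm, decreasing = TRUE)][1:40]
  expect_lt(abs(stats::median(lubridate::yday(hottest)) - 196), 35)
})

test_that("population generator respects seasonality and subgroup mixes", {
  cfg <- sim_config(n_states = 2, zctas_per_state = 10,
                    pregnancies_per_zcta = 400, years = 2, seed = 7,
                    conception_amplitude = 0)
  set.seed(cfg$seed)
  zm <- gen_temperature(cfg)$zcta_meta
  pop <- gen_population(cfg, zm)
  # uniform conceptions: month counts roughly equal
  mo <- table(lubridate::month(pop$pregnancies$conception_date))
  expect_lt((max(mo) - min(mo)) / mean(mo), 0.25)
  # subgroup mixing proportions recovered
  agep <- prop.table(table(pop$pregnancies$age_group))
  expect_lt(max(abs(as.numeric(agep[names(cfg$age_props)]) - cfg$age_props)),
            0.02)
  # area attributes live on the documented scales
  expect_true(all(pop$area$sdi_score >= 1 & pop$area$sdi_score <= 100))
  expect_true(all(pop$area$imperv_frac >= 0 & pop$area$imperv_frac <= 1))
  # education can be flagged missing for a whole state
  cfg2 <- sim_config(n_states = 2, zctas_per_state = 2,
                     pregnancies_per_zcta = 50, years = 1, seed = 8,
                     states_missing_edu = "S2")
  set.seed(cfg2$seed)
  zm2 <- gen_temperature(cfg2)$zcta_meta
  pop2 <- gen_population(cfg2, zm2)
  ed <- pop2$pregnancies |>
    dplyr::summarise(miss = all(edu_group == "missing"), .by = "state")
  expect_true(ed$miss[ed$state == "S2"])
  expect_false(ed$miss[ed$state == "S1"])
})

test_that("null-model births reproduce the configured weekly hazards", {
  sim <- small_sim(seed = 99, pregnancies_per_zcta = 600)
  wh_hat <- birth_week_hazard(sim$births) |>
    dplyr::summarise(w_g = mean(w_g), .by = "g") # average the two states
  wh_true <- default_week_hazard()
  for (g in c(30, 34, 37, 38, 39, 40)) {
    est <- wh_hat$w_g[wh_hat$g == g]
    truth <- unname(wh_true[as.character(g)])
    n_at_risk <- sum(sim$births$ga_weeks >= g) / 2
    tol <- 4 * sqrt(truth * (1 - truth) / n_at_risk)
    expect_lt(abs(est - truth), tol + 0.005)
  }
  # gestational ages live in the simulated range
  expect_true(all(sim$births$ga_weeks >= 20 & sim$births$ga_weeks <= 45))
})

test_that("the whole study simulation is reproducible from its seed", {
  s1 <- small_sim(seed = 123)
  s2 <- small_sim(seed = 123)
  expect_identical(s1$births, s2$births)
  expect_identical(s1$exposures, s2$exposures)
  s3 <- small_sim(seed = 124)
  expect_false(identical(s1$births$birth_date, s3$births$birth_date))
})

test_that("a strong heat effect shifts births into heat-wave windows", {
  # same seed with and without effect: under beta > 0, more births on
  # positive-AAT days
  base <- small_sim(seed = 55, pregnancies_per_zcta = 400)
  eff <- small_sim(seed = 55, pregnancies_per_zcta = 400, beta = log(3))
  rate_on_hot <- function(sim) {
    b <- sim$births |>
      dplyr::inner_join(sim$exposures, by = c("zcta_id", "birth_date" = "date"))
    mean(b$aat > 0, na.rm = TRUE)
  }
  expect_gt(rate_on_hot(eff), rate_on_hot(base))
})

test_that("subgroup-specific effects address the configured modifier", {
  cfg <- sim_config(n_states = 1, zctas_per_state = 4,
                    pregnancies_per_zcta = 100, years = 1, seed = 60,
                    beta = c("<25" = log(4), "25-34" = 0, "35+" = 0),
                    beta_modifier = "age_group")
  sim <- simulate_study(cfg)
  expect_true(all(c("age_group", "edu_group") %in% names(sim$births)))
  # misconfigured: missing level
  cfg_bad <- sim_config(n_states = 1, zctas_per_state = 1,
                        pregnancies_per_zcta = 20, years = 1, seed = 61,
                        beta = c("<25" = 0.1), beta_modifier = "age_group")
  expect_error(simulate_study(cfg_bad), "beta has no value")
})
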