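test_that("gestational week on a day follows the start/ongoing convention", {
  bd <- as.Date("2010-10-01")
  # day before a 36-week birth: 251 days elapsed -> week 35
  expect_identical(gestational_week_on_day(bd, 36, bd - 1), 35L)
  # pregnancy start is week 0
  expect_identical(gestational_week_on_day(bd, 36, bd - 7 * 36), 0L)
  # the birth day itself is an event, not at risk
  expect_identical(gestational_week_on_day(bd, 36, bd), NA_integer_)
  expect_identical(gestational_week_on_day(bd, 36, bd - 7 * 36 - 1), NA_integer_)
})

test_that("weekly birth hazard is births at g over births at >= g, per state", {
  b <- tibble::tibble(state = "S1", ga_weeks = c(39, 39, 40, 40))
  wh <- birth_week_hazard(b)
  expect_equal(wh$w_g[wh$g == 39], 0.5)
  expect_equal(wh$w_g[wh$g == 40], 1.0)
  # degenerate: all births at one week
  b2 <- tibble::tibble(state = "S1", ga_weeks = rep(39, 5))
  wh2 <- birth_week_hazard(b2)
  expect_equal(wh2$w_g[wh2$g == 39], 1)
  # states are estimated separately
  b3 <- dplyr::bind_rows(b, tibble::tibble(state = "S2", ga_weeks = c(39, 40)))
  wh3 <- birth_week_hazard(b3)
  expect_equal(wh3$w_g[wh3$state == "S2" & wh3$g == 39], 0.5)
  expect_error(birth_week_hazard(b[0, ]), "empty")
})

test_that("W_i is the hazard-weighted share of pregnancies in the risk range", {
  # engineered day: Z_i = 10 ongoing, 2 at week 28 (W_28 = 0.01),
  # 3 at week 30 (W_30 = 0.02) -> W_i = (2*0.01 + 3*0.02)/10 = 0.008
  day <- as.Date("2010-06-15")
  mk <- function(n, ga_at_day, ga_final) {
    # born after `day`, at week `ga_at_day` on `day`
    tibble::tibble(
      state = "S1", zcta_id = "Z1",
      birth_date = day + 7 * (ga_final - ga_at_day),
      ga_weeks = ga_final
    )
  }
  births <- dplyr::bind_rows(
    mk(2, 28, 40)[rep(1, 2), ], mk(3, 30, 40)[rep(1, 3), ],
    mk(5, 39, 40)[rep(1, 5), ]
  )
  births$birth_id <- sprintf("b%02d", seq_len(nrow(births)))
  wh <- tibble::tibble(state = "S1", g = 20:45, w_g = 0)
  wh$w_g[wh$g == 28] <- 0.01
  wh$w_g[wh$g == 30] <- 0.02
  wa <- risk_set_adjustment(births, "PTB", week_hazard = wh)
  row <- wa[wa$date == day, ]
  expect_equal(row$z_total, 10)
  expect_equal(row$w_i, (2 * 0.01 + 3 * 0.02) / 10)
})

test_that("W_i equals the constant hazard when all pregnancies are in range", {
  day <- as.Date("2010-06-15")
  births <- tibble::tibble(
    birth_id = sprintf("b%d", 1:4), state = "S1", zcta_id = "Z1",
    birth_date = day + 7 * (36 - 30:33), ga_weeks = 36L
  )
  wh <- tibble::tibble(state = "S1", g = 20:45, w_g = 0.04)
  wa <- risk_set_adjustment(births, "PTB", week_hazard = wh)
  row <- wa[wa$date == day, ]
  expect_equal(row$w_i, 0.04)
  # ongoing pregnancies past the risk range still count in Z_i but give W_i = 0
  wa2 <- risk_set_adjustment(
    births |> dplyr::mutate(ga_weeks = 44L), "PTB",
    week_hazard = wh
  )
  d2 <- max(births$birth_date) - 1 # only a week-43 pregnancy remains ongoing
  row2 <- wa2[wa2$date == d2, ]
  expect_gt(row2$z_total, 0)
  expect_equal(row2$w_i, 0)
})

test_that("vectorised risk sets equal per-pregnancy enumeration", {
  set.seed(77)
  births <- tibble::tibble(
    birth_id = sprintf("b%02d", 1:40),
    state = sample(c("S1", "S2"), 40, TRUE),
    zcta_id = sample(c("Z1", "Z2"), 40, TRUE),
    birth_date = as.Date("2010-01-01") + sample(300:500, 40, TRUE),
    ga_weeks = sample(25:44, 40, TRUE)
  )
  for (outcome in c("PTB", "ETB")) {
    rng <- if (outcome == "PTB") 28:36 else 37:38
    wh <- birth_week_hazard(births)
    wa <- risk_set_adjustment(births, outcome)
    check <- wa[sample(nrow(wa), 80), ]
    for (i in seq_len(nrow(check))) {
      wk <- gestational_week_on_day(births$birth_date, births$ga_weeks,
                                    check$date[i])
      here <- births$zcta_id == check$zcta_id[i] & !is.na(wk)
      zi <- sum(here)
      num <- 0
      for (j in which(here & wk %in% rng)) {
        num <- num + wh$w_g[wh$state == births$state[j] & wh$g == wk[j]]
      }
      expect_equal(check$z_total[i], zi)
      if (zi == 0) {
        expect_true(is.na(check$w_i[i]))
      } else {
        expect_equal(check$w_i[i], num / zi)
      }
    }
  }
})

test_that("shifting all birth dates by a week shifts the risk sets exactly", {
  set.seed(3)
  births <- tibble::tibble(
    birth_id = sprintf("b%02d", 1:20), state = "S1",
    zcta_id = sample(c("Z1", "Z2"), 20, TRUE),
    birth_date = as.Date("2010-01-01") + sample(300:400, 20, TRUE),
    ga_weeks = sample(30:42, 20, TRUE)
  )
  wa1 <- risk_set_adjustment(births, "PTB")
  wa2 <- risk_set_adjustment(
    births |> dplyr::mutate(birth_date = birth_date + 7), "PTB"
  )
  wa2_shift <- wa2 |> dplyr::mutate(date = date - 7)
  joined <- dplyr::inner_join(wa1, wa2_shift, by = c("zcta_id", "date"))
  expect_gt(nrow(joined), 100)
  expect_equal(joined$z_total.x, joined$z_total.y)
  expect_equal(joined$w_i.x, joined$w_i.y)
})

test_that("an administrative register end flags truncated days", {
  births <- tibble::tibble(
    birth_id = c("a", "b"), state = "S1", zcta_id = "Z1",
    birth_date = as.Date(c("2010-06-01", "2011-06-01")), ga_weeks = 40L
  )
  data_end <- as.Date("2011-06-01")
  wa <- risk_set_adjustment(births, "PTB", data_end = data_end)
  flagged <- wa$date[wa$boundary_flag]
  expect_true(all(flagged > data_end - 45 * 7))
  expect_true(all(wa$date[!wa$boundary_flag] <= data_end - 45 * 7))
  # complete register: nothing flagged
  wa0 <- risk_set_adjustment(births, "PTB")
  expect_false(any(wa0$boundary_flag))
})
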