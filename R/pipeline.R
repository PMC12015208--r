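hw_covariate <- function(hw_def) {
  switch(hw_def,
         aat = "aat", ge2 = "hw_ge2", ge3 = "hw_ge3", eq4 = "hw_eq4",
         abort("hw_def must be one of 'aat', 'ge2', 'ge3', 'eq4'"))
}

#' Attach stratification variables to birth records
#'
#' Derives the analysis stratification columns: maternal age and education
#' groups come from the birth record; `sdi_group` dichotomises the ZCTA
#' Social Deprivation Index at the given cut (low deprivation below it);
#' `landcover_group` cuts the fraction of ZCTA area with medium/high-intensity
#' impervious cover at 25% and 66%.
#'
#' @param births Birth-record tibble with `zcta_id`.
#' @param area Optional area tibble (`zcta_id`, `sdi_score`, `imperv_frac`).
#' @param sdi_cut SDI dichotomisation cut point; default 70.
#' @param landcover_cuts Two increasing fractions; default `c(0.25, 0.66)`.
#' @return `births` with any derivable columns `sdi_group`
#'   (`"low"`/`"high"`) and `landcover_group` (`"<25%"`, `"25-66%"`,
#'   `">66%"`) added.
#' @export
add_strata_vars <- function(births, area = NULL, sdi_cut = 70,
                            landcover_cuts = c(0.25, 0.66)) {
  births <- as_tibble(births)
  if (is.null(area)) return(births)
  area <- as_tibble(area)
  joined <- births |>
    left_join(area |> select(any_of(c("zcta_id", "sdi_score", "imperv_frac"))),
              by = "zcta_id")
  if ("sdi_score" %in% names(joined)) {
    joined <- joined |>
      mutate(sdi_group = if_else(.data$sdi_score < sdi_cut, "low", "high")) |>
      select(-"sdi_score")
  }
  if ("imperv_frac" %in% names(joined)) {
    joined <- joined |>
      mutate(landcover_group = dplyr::case_when(
        .data$imperv_frac < landcover_cuts[1] ~ "<25%",
        .data$imperv_frac <= landcover_cuts[2] ~ "25-66%",
        TRUE ~ ">66%"
      )) |>
      select(-"imperv_frac")
  }
  joined
}

strat_column <- function(strat_var) {
  switch(strat_var,
         none = NULL, age = "age_group", education = "edu_group",
         sdi = "sdi_group", landcover = "landcover_group",
         abort(paste0("unknown stratification variable: ", strat_var)))
}

#' Run the full stratified case-crossover analysis
#'
#' For every requested outcome, stratification variable and heat-wave
#' definition: builds warm-season case-crossover strata per state and stratum
#' level, fits conditional logistic regression (heat-wave metric plus the
#' pregnancy-risk-set adjustment `w_adjust`), pools state estimates by
#' fixed-effect inverse-variance weighting within stratum level, and tests
#' heterogeneity across levels (Wald chi-square; at two levels this equals
#' the squared Z-score test).
#'
#' States in which a stratification variable is entirely missing (e.g. no
#' education data in the register) are dropped from that variable's analysis
#' and logged. State-stratum cells with no informative strata or a
#' non-converged fit are recorded and pooling proceeds over the remaining
#' states.
#'
#' @param births Birth-record tibble (`birth_id`, `state`, `zcta_id`,
#'   `birth_date`, `ga_weeks`, subgroup columns).
#' @param exposures ZCTA-day exposure tibble from [compute_exposures()].
#' @param area Optional area-attribute tibble for `sdi`/`landcover` strata.
#' @param outcomes Outcomes to analyse, subset of `c("PTB", "ETB")`.
#' @param hw_defs Heat-wave definitions, subset of
#'   `c("aat", "ge2", "ge3", "eq4")`.
#' @param strat_vars Stratification variables, subset of
#'   `c("none", "age", "education", "sdi", "landcover")`.
#' @param warm_months Warm-season months; default May--September.
#' @param boundary_policy Passed to [case_crossover_strata()].
#' @param data_end Passed to [risk_set_adjustment()]; `NULL` for a complete
#'   register.
#' @param sdi_cut,landcover_cuts Passed to [add_strata_vars()].
#' @return List of class `"heatbirth_results"`: `fits` (per state x level),
#'   `pooled` (per level), `heterogeneity` (per variable), `exclusions`,
#'   `dropped_cells`, and the call parameters in `meta`.
#' @export
run_analysis <- function(births, exposures, area = NULL,
                         outcomes = c("PTB", "ETB"),
                         hw_defs = c("aat", "ge2", "ge3", "eq4"),
                         strat_vars = "none",
                         warm_months = 5:9,
                         boundary_policy = c("exclude", "flag", "ignore"),
                         data_end = NULL,
                         sdi_cut = 70, landcover_cuts = c(0.25, 0.66)) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  boundary_policy <- match.arg(boundary_policy)
  hw_defs <- vapply(hw_defs, function(h) {
    hw_covariate(h); h
  }, character(1))
  births <- add_strata_vars(births, area, sdi_cut, landcover_cuts)
  if (nrow(births) == 0) {
    warn("no birth records supplied; returning empty results")
    empty_fits <- tibble(
      outcome = character(), stratum_var = character(),
      stratum_level = character(), state = character(), hw_def = character(),
      beta = double(), se = double(), or = double(), lcl = double(),
      ucl = double(), n_cases = integer(), n_informative = integer(),
      converged = logical()
    )
    return(structure(
      list(fits = empty_fits,
           pooled = empty_fits[0, c("outcome", "stratum_var",
                                    "stratum_level", "hw_def")] |>
             mutate(beta = double(), se = double(), or = double(),
                    lcl = double(), ucl = double(), k = integer(),
                    n_cases = integer()),
           heterogeneity = tibble(outcome = character(),
                                  stratum_var = character(),
                                  hw_def = character(), chi2 = double(),
                                  df = integer(), p = double()),
           exclusions = tibble(outcome = character(), reason = character(),
                               n = integer()),
           dropped_cells = tibble(),
           meta = list(outcomes = outcomes, hw_defs = unname(hw_defs),
                       strat_vars = strat_vars, warm_months = warm_months,
                       boundary_policy = boundary_policy, sdi_cut = sdi_cut,
                       landcover_cuts = landcover_cuts)),
      class = "heatbirth_results"
    ))
  }
  week_hazard <- birth_week_hazard(births)

  fits <- list()
  exclusions <- list()
  dropped <- list()

  for (outcome in outcomes) {
    wadj <- risk_set_adjustment(births, outcome, week_hazard = week_hazard,
                                data_end = data_end)
    strata_all <- case_crossover_strata(
      births, exposures, wadj, outcome = outcome, warm_months = warm_months,
      boundary_policy = boundary_policy
    )
    exclusions[[outcome]] <- exclusion_log(strata_all) |>
      mutate(outcome = outcome, .before = 1)

    for (strat_var in strat_vars) {
      col <- strat_column(strat_var)
      if (!is.null(col) && !col %in% names(strata_all)) {
        abort(paste0("stratification column '", col, "' not available; ",
                     "supply the needed birth/area columns"))
      }
      sdat <- strata_all
      if (is.null(col)) {
        sdat$.level <- "all"
      } else {
        sdat$.level <- as.character(sdat[[col]])
        # states with the variable entirely missing are excluded from this
        # stratified analysis (they cannot contribute any level)
        miss_state <- sdat |>
          summarise(all_miss = all(is.na(.data$.level) |
                                     .data$.level == "missing"),
                    .by = "state") |>
          filter(.data$all_miss)
        if (nrow(miss_state) > 0) {
          dropped[[length(dropped) + 1L]] <- tibble(
            outcome = outcome, stratum_var = strat_var,
            state = miss_state$state, reason = "stratifier missing in state"
          )
          sdat <- sdat |> filter(!.data$state %in% miss_state$state)
        }
        sdat <- sdat |>
          filter(!is.na(.data$.level), .data$.level != "missing")
      }

      cells <- sdat |> distinct(.data$state, .data$.level)
      for (ci in seq_len(nrow(cells))) {
        cell <- sdat |>
          filter(.data$state == cells$state[ci],
                 .data$.level == cells$.level[ci])
        n_cases <- sum(cell$is_case)
        for (hw in hw_defs) {
          xvar <- hw_covariate(hw)
          fit <- tryCatch(
            fit_clogit(cell, covariates = c(xvar, "w_adjust")),
            error = function(e) NULL
          )
          ok <- !is.null(fit) && fit$converged
          if (!ok) {
            dropped[[length(dropped) + 1L]] <- tibble(
              outcome = outcome, stratum_var = strat_var,
              state = cells$state[ci],
              reason = paste0(
                "no estimate for level ", cells$.level[ci], ", ", hw,
                if (!is.null(fit)) paste0(" (", fit$diagnostic %||%
                                            "not converged", ")")
                else " (no informative strata)"
              )
            )
          }
          fits[[length(fits) + 1L]] <- tibble(
            outcome = outcome, stratum_var = strat_var,
            stratum_level = cells$.level[ci], state = cells$state[ci],
            hw_def = hw,
            beta = if (ok) unname(fit$beta[1]) else NA_real_,
            se = if (ok) unname(fit$se[1]) else NA_real_,
            or = if (ok) fit$or_ci$or else NA_real_,
            lcl = if (ok) fit$or_ci$lcl else NA_real_,
            ucl = if (ok) fit$or_ci$ucl else NA_real_,
            n_cases = n_cases,
            n_informative = if (!is.null(fit)) fit$n_informative else 0L,
            converged = ok
          )
        }
      }
    }
  }

  fits <- bind_rows(fits)
  pooled <- fits |>
    filter(.data$converged) |>
    group_by(.data$outcome, .data$stratum_var, .data$stratum_level,
             .data$hw_def) |>
    group_modify(function(df, key) {
      if (nrow(df) == 0) {
        return(tibble(beta = double(), se = double(), or = double(),
                      lcl = double(), ucl = double(), k = integer(),
                      n_cases = integer()))
      }
      ivw_pool(df) |> mutate(n_cases = sum(df$n_cases))
    }) |>
    ungroup()

  heterogeneity <- pooled |>
    group_by(.data$outcome, .data$stratum_var, .data$hw_def) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
      }
      heterogeneity_wald(df)
    }) |>
    ungroup() |>
    filter(!is.na(.data$chi2))

  structure(
    list(
      fits = fits, pooled = pooled, heterogeneity = heterogeneity,
      exclusions = bind_rows(exclusions), dropped_cells = bind_rows(dropped),
      meta = list(outcomes = outcomes, hw_defs = unname(hw_defs),
                  strat_vars = strat_vars, warm_months = warm_months,
                  boundary_policy = boundary_policy, sdi_cut = sdi_cut,
                  landcover_cuts = landcover_cuts)
    ),
    class = "heatbirth_results"
  )
}

#' @export
print.heatbirth_results <- function(x, ...) {
  cat("heatbirth analysis:",
      paste(x$meta$outcomes, collapse = "/"), "x",
      paste(x$meta$hw_defs, collapse = "/"), "x strata",
      paste(x$meta$strat_vars, collapse = "/"), "\n")
  print(summarize_results(x), n = 20)
  invisible(x)
}

#' Tidy summary of pooled results
#'
#' One row per outcome, heat-wave definition and stratum level, with the
#' pooled OR, 95% CI and the across-level heterogeneity p-value (repeated
#' within its variable), in deterministic order — the table behind a forest
#' plot.
#'
#' @param results A `"heatbirth_results"` object from [run_analysis()].
#' @return Tibble `outcome`, `stratum_var`, `stratum_level`, `hw_def`, `or`,
#'   `lcl`, `ucl`, `n_cases`, `k_states`, `p_heterogeneity`.
#' @export
summarize_results <- function(results) {
  pooled <- results$pooled
  if (nrow(pooled) == 0) {
    warn("no pooled results")
    return(tibble(outcome = character(), stratum_var = character(),
                  stratum_level = character(), hw_def = character(),
                  or = double(), lcl = double(), ucl = double(),
                  n_cases = integer(), k_states = integer(),
                  p_heterogeneity = double()))
  }
  pooled |>
    left_join(results$heterogeneity |>
                select("outcome", "stratum_var", "hw_def", p_heterogeneity = "p"),
              by = c("outcome", "stratum_var", "hw_def")) |>
    transmute(
      .data$outcome, .data$stratum_var, .data$stratum_level, .data$hw_def,
      .data$or, .data$lcl, .data$ucl, .data$n_cases, k_states = .data$k,
      p_heterogeneity = .data$p_heterogeneity
    ) |>
    arrange(.data$outcome, .data$stratum_var, .data$hw_def,
            .data$stratum_level)
}

#' Estimate the heat effect on one simulated study
#'
#' Convenience wrapper used throughout the package's validation studies:
#' computes the risk-set adjustment, assembles warm-season strata, fits the
#' conditional logistic model per state and pools by inverse variance.
#'
#' @param sim A `"heatbirth_sim"` object from [simulate_study()] (or a list
#'   with `births` and `exposures`).
#' @param outcome `"PTB"` or `"ETB"`.
#' @param hw_def Heat-wave definition; default `"aat"`.
#' @param warm_months Warm-season months.
#' @return One-row tibble: `beta`, `se`, `or`, `lcl`, `ucl`, `k`, `n_cases`,
#'   `p` (two-sided Wald p-value of the pooled estimate).
#' @export
estimate_heat_effect <- function(sim, outcome = "ETB", hw_def = "aat",
                                 warm_months = 5:9) {
  res <- run_analysis(sim$births, sim$exposures, outcomes = outcome,
                      hw_defs = hw_def, strat_vars = "none",
                      warm_months = warm_months)
  est <- res$pooled
  if (nrow(est) == 0) {
    return(tibble(beta = NA_real_, se = NA_real_, or = NA_real_,
                  lcl = NA_real_, ucl = NA_real_, k = 0L, n_cases = 0L,
                  p = NA_real_))
  }
  est |>
    transmute(.data$beta, .data$se, .data$or, .data$lcl, .data$ucl, .data$k,
              .data$n_cases, p = 2 * pnorm(-abs(.data$beta / .data$se)))
}
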