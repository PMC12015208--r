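# Shared fixtures, all built in code.

# A tiny ZCTA series: constant cool days with a hot spell inserted.
make_series <- function(n = 60, base = 20, start = as.Date("2010-06-01"),
                        zcta = "Z1") {
  tibble::tibble(
    zcta_id = zcta,
    date = start + seq_len(n) - 1,
    tmean_c = rep(base, n),
    threshold_c = base + 5
  )
}

# Random one-case strata with a continuous covariate (and optional second).
make_random_strata <- function(n_strata, beta = 0.5, seed = 1,
                               two_covariates = TRUE) {
  set.seed(seed)
  out <- lapply(seq_len(n_strata), function(s) {
    k <- sample(4:5, 1)
    x <- rnorm(k)
    w <- rnorm(k, 0, 0.01)
    eta <- beta * x
    p <- exp(eta - max(eta))
    case <- sample(k, 1, prob = p / sum(p))
    df <- data.frame(birth_id = sprintf("s%04d", s),
                     is_case = seq_len(k) == case, aat = x)
    if (two_covariates) df$w_adjust <- w
    df
  })
  do.call(rbind, out)
}

# 1:1 matched binary-exposure strata: n10 with case exposed / referent not,
# n01 the reverse, n_conc concordant.
make_paired_strata <- function(n10, n01, n_conc = 5) {
  rows <- list()
  add <- function(id, x_case, x_ref) {
    data.frame(birth_id = id, is_case = c(TRUE, FALSE), aat = c(x_case, x_ref))
  }
  i <- 0
  for (s in seq_len(n10)) rows[[i <- i + 1]] <- add(sprintf("d10_%02d", s), 1, 0)
  for (s in seq_len(n01)) rows[[i <- i + 1]] <- add(sprintf("d01_%02d", s), 0, 1)
  for (s in seq_len(n_conc)) rows[[i <- i + 1]] <- add(sprintf("cc_%02d", s), 1, 1)
  do.call(rbind, rows)
}

# Small-but-complete simulated study for pipeline tests.
small_sim <- function(seed = 314, ...) {
  args <- utils::modifyList(
    list(n_states = 2, zctas_per_state = 4, pregnancies_per_zcta = 250,
         years = 2, seed = seed),
    list(...)
  )
  simulate_study(do.call(sim_config, args))
}
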