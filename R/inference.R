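prepare_clogit_data <- function(strata, covariates) {
  strata <- as_tibble(strata)
  missing_cov <- setdiff(covariates, names(strata))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate(s) not in strata: ",
                 paste(missing_cov, collapse = ", ")))
  }
  X <- vapply(strata[covariates], as.numeric, numeric(nrow(strata)))
  X <- matrix(X, nrow = nrow(strata),
              dimnames = list(NULL, covariates))
  if (any(!is.finite(X))) abort("covariates must be finite")
  ids <- unique(strata$birth_id)
  sid <- match(strata$birth_id, ids)
  case <- as.logical(strata$is_case)
  cases_per <- rowsum(as.numeric(case), sid)
  if (any(cases_per != 1)) {
    abort("every stratum must contain exactly one case day")
  }
  list(X = X, sid = sid, case = case, n_strata = length(ids))
}

# within-stratum variation indicator, strata x covariates
stratum_varies <- function(X, sid) {
  k <- max(sid)
  varies <- matrix(FALSE, k, ncol(X))
  for (j in seq_len(ncol(X))) {
    mx <- tapply(X[, j], sid, max)
    mn <- tapply(X[, j], sid, min)
    varies[, j] <- (mx - mn) > 0
  }
  varies
}

clogit_eval <- function(X, sid, case, beta) {
  eta <- as.vector(X %*% beta)
  m <- as.vector(tapply(eta, sid, max))
  w <- exp(eta - m[sid])
  denom <- as.vector(rowsum(w, sid))
  p <- w / denom[sid]
  loglik <- sum(eta[case]) - sum(log(denom) + m)
  Xp <- X * p
  grad <- colSums(X[case, , drop = FALSE]) - colSums(Xp)
  B <- rowsum(Xp, sid)
  info <- crossprod(X, Xp) - crossprod(B)
  list(loglik = loglik, gradient = grad, information = info)
}

#' Conditional logistic log-likelihood for one-case strata
#'
#' Evaluates the exact conditional likelihood for matched sets with exactly
#' one case day each:
#' `l(beta) = sum_s [ x_case . beta - log sum_{j in s} exp(x_j . beta) ]`,
#' together with its analytic gradient and observed information.
#'
#' @param strata Long-format stratum tibble (as from
#'   [case_crossover_strata()]) with `birth_id`, `is_case` and the covariate
#'   columns.
#' @param beta Coefficient vector, one entry per covariate.
#' @param covariates Covariate column names, in the order of `beta`.
#' @return List with `loglik`, `gradient`, `information`.
#' @export
clogit_loglik <- function(strata, beta, covariates) {
  d <- prepare_clogit_data(strata, covariates)
  stopifnot(length(beta) == length(covariates))
  clogit_eval(d$X, d$sid, d$case, beta)
}

#' Fit conditional logistic regression on case-crossover strata
#'
#' Maximises the one-case-per-stratum conditional likelihood by
#' Newton-Raphson from `beta = 0`, with step-halving whenever a step would
#' decrease the (concave) log-likelihood. Strata in which every covariate is
#' constant contribute only a constant and are dropped from the likelihood;
#' they are still counted in `n_strata`. `n_informative` counts strata in
#' which the exposure covariate (the first of `covariates`) varies.
#'
#' @inheritParams clogit_loglik
#' @param covariates Ordered covariate names; the first is the exposure of
#'   interest reported in `or_ci`.
#' @param tol Convergence tolerance on the gradient max-norm; default `1e-8`.
#' @param max_iter Maximum Newton iterations; default 50.
#' @param level Confidence level for `or_ci`; default 0.95.
#' @return Object of class `"heatbirth_clogit"`: coefficients `beta`, `se`,
#'   `vcov`, `loglik`, `n_strata`, `n_informative`, `converged`, `iterations`,
#'   `or_ci` (OR and Wald CI for the exposure), and a `diagnostic` message
#'   when the fit is flagged (perfect separation / non-identifiability yields
#'   `converged = FALSE` rather than an error).
#' @export
fit_clogit <- function(strata, covariates = c("aat", "w_adjust"),
                       tol = 1e-8, max_iter = 50, level = 0.95) {
  d <- prepare_clogit_data(strata, covariates)
  varies <- stratum_varies(d$X, d$sid)
  n_informative <- sum(varies[, 1])
  if (n_informative == 0) {
    abort("exposure covariate is constant within every stratum (no informative strata)")
  }
  keep_strata <- which(rowSums(varies) > 0)
  keep <- d$sid %in% keep_strata
  X <- d$X[keep, , drop = FALSE]
  sid <- match(d$sid[keep], keep_strata)
  case <- d$case[keep]

  # internal standardisation: covariates can live on very different scales
  # (AAT in degrees vs the risk-set adjustment near zero); scale by the
  # within-stratum residual SD so Newton steps and the divergence guard are
  # scale-free, then transform estimates back
  ctr <- X - apply(X, 2, function(v) as.vector(tapply(v, sid, mean))[sid])
  scl <- apply(ctr, 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  X <- sweep(X, 2, scl, `/`)

  beta <- rep(0, length(covariates))
  ev <- clogit_eval(X, sid, case, beta)
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0
  while (iter < max_iter) {
    if (max(abs(ev$gradient)) < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1
    step <- tryCatch(solve(ev$information, ev$gradient),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      diagnostic <- "singular information matrix (non-identifiable fit)"
      break
    }
    h <- 1
    repeat {
      cand <- beta + h * step
      ev_new <- clogit_eval(X, sid, case, cand)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-10) {
        cand <- beta
        ev_new <- ev
        break
      }
    }
    beta <- cand
    ev <- ev_new
    if (max(abs(beta)) > 10) { # per-SD scale: far beyond any plausible effect
      diagnostic <- "coefficients diverging (possible perfect separation)"
      break
    }
  }
  if (converged && max(abs(beta)) > 10) {
    converged <- FALSE
    diagnostic <- "coefficients diverging (possible perfect separation)"
  }
  if (!converged && iter >= max_iter && is.null(diagnostic)) {
    diagnostic <- "maximum iterations reached"
  }

  vc <- tryCatch(solve(ev$information), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(NA_real_, length(beta))
    vc <- matrix(NA_real_, length(beta), length(beta))
    if (converged) {
      converged <- FALSE
      diagnostic <- "singular information at the optimum"
    }
  } else {
    se <- sqrt(pmax(diag(vc), 0))
  }
  # back to the original covariate scale
  beta <- beta / scl
  se <- se / scl
  vc <- vc / tcrossprod(scl)
  names(beta) <- names(se) <- covariates
  dimnames(vc) <- list(covariates, covariates)

  structure(
    list(
      beta = beta, se = se, vcov = vc, loglik = ev$loglik,
      n_strata = d$n_strata, n_informative = n_informative,
      converged = converged, iterations = iter,
      covariates = covariates, exposure = covariates[1],
      or_ci = wald_ci(beta[1], se[1], level = level),
      diagnostic = diagnostic
    ),
    class = "heatbirth_clogit"
  )
}

#' Odds ratio with Wald confidence interval
#'
#' @param beta Log-odds-ratio estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @param level Confidence level; default 0.95.
#' @return Tibble with `or`, `lcl`, `ucl`.
#' @export
wald_ci <- function(beta, se, level = 0.95) {
  stopifnot(all(se >= 0 | is.na(se)))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(or = exp(beta), lcl = exp(beta - z * se), ucl = exp(beta + z * se))
}

#' @export
print.heatbirth_clogit <- function(x, ...) {
  cat("Conditional logistic fit (", x$n_strata, " strata, ",
      x$n_informative, " informative for ", x$exposure, ")\n", sep = "")
  print(tidy(x))
  if (!x$converged) {
    cat("NOT CONVERGED:", x$diagnostic %||% "", "\n")
  }
  invisible(x)
}

#' Tidy a conditional logistic fit
#'
#' @param x A `heatbirth_clogit` object.
#' @param exponentiate Report odds ratios instead of log-odds; default FALSE.
#' @param conf.level Confidence level; default 0.95.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.heatbirth_clogit <- function(x, exponentiate = FALSE,
                                  conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = x$covariates,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = 2 * pnorm(-abs(unname(x$beta / x$se))),
    conf.low = unname(x$beta - z * x$se),
    conf.high = unname(x$beta + z * x$se)
  )
  if (exponentiate) {
    out <- out |> mutate(across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' Glance at a conditional logistic fit
#'
#' @param x A `heatbirth_clogit` object.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `n_strata`, `n_informative`,
#'   `converged`, `iterations`.
#' @export
glance.heatbirth_clogit <- function(x, ...) {
  tibble(logLik = x$loglik, n_strata = x$n_strata,
         n_informative = x$n_informative, converged = x$converged,
         iterations = x$iterations)
}
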