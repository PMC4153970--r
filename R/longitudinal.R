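## Latent-trajectory disease-progression model: D_i(t) = D0_i + a_i * t
## with correlated subject random effects on baseline and slope, an
## optional fractional drug effect on the slope, and interval-censored
## dropout. Time is stored in months at the interface and converted to
## years internally (progression rates are per year).

#' Disease-progression population parameters
#'
#' @param theta1 Typical baseline latent disability.
#' @param theta2 Typical progression slope (latent units per year).
#' @param omega1 SD of the baseline random effect (>= 0).
#' @param omega2 SD of the slope random effect (>= 0).
#' @param rho Correlation of the two random effects (|rho| <= 1).
#' @param beta_drug Fractional slope reduction in the treated arm,
#'   in (-1, 1): the subject slope is `(1 - beta_drug * x_grp) * (theta2 + eta2)`.
#' @return Object of class `progression_params`.
#' @export
progression_params <- function(theta1, theta2, omega1, omega2, rho = 0,
                               beta_drug = 0) {
  check_that(omega1 >= 0 && omega2 >= 0, "omegas must be >= 0")
  check_that(abs(rho) <= 1, "|rho| must be <= 1")
  check_that(beta_drug > -1 && beta_drug < 1, "beta_drug must lie in (-1, 1)")
  structure(list(theta1 = theta1, theta2 = theta2, omega1 = omega1,
                 omega2 = omega2, rho = rho, beta_drug = beta_drug),
            class = "progression_params")
}

#' Default progression parameters
#'
#' Typical values for a mild-to-moderate AD placebo population followed
#' for 18-20 months: baseline disability 0.95 latent SD units, progression
#' 0.35 per year, between-subject SDs 0.68 (baseline) and 0.39 (slope)
#' with correlation 0.54.
#'
#' @param beta_drug Fractional slope reduction for the treated arm
#'   (default 0.2, i.e. a 20% slower progression).
#' @return A [progression_params()] object.
#' @export
default_progression_params <- function(beta_drug = 0.2) {
  progression_params(theta1 = 0.95, theta2 = 0.35, omega1 = 0.68,
                     omega2 = 0.39, rho = 0.54, beta_drug = beta_drug)
}

#' Dropout hazard specification
#'
#' Log-linear hazards for study dropout: `constant` (log h = theta3),
#' `disability` (log h = theta3 + theta4 * D_i(t)), `progression_rate`
#' (log h = theta3 + theta4 * a_i) and `baseline_disability`
#' (log h = theta3 + theta4 * D0_i). Time unit: years.
#'
#' @param kind Hazard form (see above).
#' @param theta3 Log baseline hazard (per year).
#' @param theta4 Covariate coefficient; absent for `constant`.
#' @return Object of class `hazard_spec`.
#' @export
hazard_spec <- function(kind = c("constant", "disability",
                                 "progression_rate", "baseline_disability"),
                        theta3, theta4 = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    check_that(is.null(theta4), "`theta4` must be absent for constant hazard")
    theta4 <- NA_real_
  } else check_that(!is.null(theta4) && is.finite(theta4),
                    "`theta4` is required for covariate hazards")
  structure(list(kind = kind, theta3 = theta3, theta4 = theta4),
            class = "hazard_spec")
}

hazard_kind_code <- function(kind) {
  c(constant = 0L, disability = 1L, progression_rate = 2L,
    baseline_disability = 3L)[kind]
}

## subject effects as a plain list/tibble row: eta1, eta2, x_grp
as_effects <- function(effects) {
  if (is.data.frame(effects)) effects <- as.list(effects)
  effects$eta1 <- effects$eta1 %||% 0
  effects$eta2 <- effects$eta2 %||% 0
  effects$x_grp <- effects$x_grp %||% 0
  effects
}

subject_coefs <- function(effects, params) {
  effects <- as_effects(effects)
  list(d0 = params$theta1 + effects$eta1,
       slope = (1 - params$beta_drug * effects$x_grp) *
         (params$theta2 + effects$eta2))
}

#' Latent disability trajectory
#'
#' `D_i(t) = D0_i + a_i * t` with `D0_i = theta1 + eta1` and
#' `a_i = (1 - beta_drug * x_grp) * (theta2 + eta2)`.
#'
#' @param t_months Visit times in months (vector).
#' @param effects List or one-row data frame with `eta1`, `eta2`, `x_grp`.
#' @param params A [progression_params()].
#' @return Latent disability at each time.
#' @export
trajectory <- function(t_months, effects, params) {
  check_that(all(t_months >= 0), "`t_months` must be >= 0")
  sc <- subject_coefs(effects, params)
  sc$d0 + sc$slope * (t_months / 12)
}

## cumulative hazard in years
cumulative_hazard <- function(t_years, sc, hazard) {
  th3 <- hazard$theta3; th4 <- hazard$theta4
  switch(hazard$kind,
         constant = exp(th3) * t_years,
         progression_rate = exp(th3 + th4 * sc$slope) * t_years,
         baseline_disability = exp(th3 + th4 * sc$d0) * t_years,
         disability = {
           cc <- th4 * sc$slope
           h0 <- exp(th3 + th4 * sc$d0)
           ifelse(abs(cc * t_years) < 1e-8,
                  h0 * t_years * (1 + 0.5 * cc * t_years),
                  h0 * expm1(cc * t_years) / cc)
         })
}

#' Probability of remaining in the study
#'
#' `S(t) = exp(-integral_0^t h(u) du)`. All four hazard kinds admit a
#' closed-form cumulative hazard (the disability-dependent kind is
#' exponential-linear in time); a numeric quadrature route is provided as
#' an independent check.
#'
#' @param t_months Time(s) in months.
#' @inheritParams trajectory
#' @param hazard A [hazard_spec()].
#' @param method `"closed"` (default) or `"quadrature"` (adaptive
#'   quadrature of the hazard, tolerance 1e-8).
#' @return Survival probabilities in (0, 1].
#' @export
survival_prob <- function(t_months, effects, params, hazard,
                          method = c("closed", "quadrature")) {
  method <- match.arg(method)
  check_that(all(t_months >= 0), "`t_months` must be >= 0")
  sc <- subject_coefs(effects, params)
  t_years <- t_months / 12
  if (method == "closed") return(exp(-cumulative_hazard(t_years, sc, hazard)))
  vapply(t_years, function(tt) {
    if (tt == 0) return(1)
    hfun <- function(u) {
      Du <- sc$d0 + sc$slope * u
      switch(hazard$kind,
             constant = rep(exp(hazard$theta3), length(u)),
             disability = exp(hazard$theta3 + hazard$theta4 * Du),
             progression_rate =
               rep(exp(hazard$theta3 + hazard$theta4 * sc$slope), length(u)),
             baseline_disability =
               rep(exp(hazard$theta3 + hazard$theta4 * sc$d0), length(u)))
    }
    H <- stats::integrate(hfun, 0, tt, rel.tol = 1e-8, abs.tol = 1e-12)$value
    exp(-H)
  }, 0)
}

#' Interval-censored dropout log-likelihood
#'
#' A subject seen last at `last_seen` and missing from `first_missed`
#' onward contributes `log(S(last_seen) - S(first_missed))`; a completer
#' (no `first_missed`) contributes `log S(last_seen)`.
#'
#' @param last_seen Last attended visit time (months).
#' @param first_missed First missed visit time (months) or `NA`/`NULL`
#'   for completers.
#' @inheritParams survival_prob
#' @return Log probability.
#' @export
dropout_interval_loglik <- function(last_seen, first_missed, effects, params,
                                    hazard) {
  s1 <- survival_prob(last_seen, effects, params, hazard)
  if (is.null(first_missed) || is.na(first_missed)) return(log(s1))
  check_that(first_missed > last_seen,
             "`first_missed` must exceed `last_seen`")
  s2 <- survival_prob(first_missed, effects, params, hazard)
  d <- s1 - s2
  if (d <= .Machine$double.xmin) {
    warn("survival difference underflowed; flooring at log(eps)")
    return(log(.Machine$double.xmin))
  }
  log(d)
}

## ---- joint likelihood -----------------------------------------------------

## item-table cache: tables depend only on the (fixed) item parameters
the <- new.env(parent = emptyenv())
item_table_cache <- function(ia) {
  key <- rlang::hash(ia[c("fam", "a", "b", "c", "d", "delta", "n", "m",
                          "ncat", "th")])
  hit <- the[[key]]
  if (!is.null(hit)) return(hit)
  tabs <- cpp_build_item_tables(ia$fam, ia$a, ia$b, ia$c, ia$d, ia$delta,
                                ia$n, ia$m, ia$th, ia$ncat,
                                as.integer(ia$sup), -12, 14, 0.02)
  if (length(ls(the)) > 20) rm(list = ls(the), envir = the)
  the[[key]] <- tabs
  tabs
}

## assemble dropout status arrays aligned with subjects
dropout_arrays <- function(subjects, dropout) {
  n <- length(subjects)
  if (is.null(dropout))
    return(list(status = integer(n), t1 = numeric(n), t2 = numeric(n)))
  i <- match(subjects, dropout$subject_id)
  check_that(!anyNA(i), "dropout data must cover every subject")
  fm <- dropout$first_missed_months[i]
  status <- ifelse(is.na(fm), 2L, 1L)
  list(status = as.integer(status),
       t1 = dropout$last_seen_months[i] / 12,
       t2 = ifelse(is.na(fm), 0, fm / 12))
}

long_arrays <- function(responses, bank) {
  check_that(all(c("time_months", "arm") %in% names(responses)),
             "longitudinal responses need `time_months` and `arm` columns")
  oa <- obs_arrays(responses, bank)
  arm <- responses$arm[match(oa$subjects, responses$subject_id)]
  oa$xgrp <- as.numeric(arm %in% c(1, "1", "treatment", "active"))
  oa
}

#' Joint subject log-likelihood of the longitudinal model
#'
#' For each subject, integrates the product of item likelihoods along the
#' latent trajectory (and the dropout likelihood, when given) over the
#' bivariate random-effect distribution, by a 2-D Laplace approximation or
#' adaptive Gauss-Hermite quadrature. Item parameters come from `bank`
#' and are treated as fixed.
#'
#' @param responses Long-format responses with `subject_id`, `time_months`,
#'   `arm`, `item_id`, `value`.
#' @param bank An [item_bank()].
#' @param params A [progression_params()].
#' @param hazard A [hazard_spec()] or `NULL` (no dropout model).
#' @param dropout Dropout tibble (`subject_id`, `last_seen_months`,
#'   `first_missed_months` with `NA` for completers) or `NULL`.
#' @param method `"laplace"` (default) or `"agh"`.
#' @param nodes Gauss-Hermite nodes per dimension for `"agh"`.
#' @return Tibble with `subject_id` and `loglik`.
#' @export
joint_loglik <- function(responses, bank, params, hazard = NULL,
                         dropout = NULL, method = c("laplace", "agh"),
                         nodes = 7) {
  method <- match.arg(method)
  validate_responses(responses, bank)
  oa <- long_arrays(responses, bank)
  da <- dropout_arrays(oa$subjects, dropout)
  if (is.null(hazard)) da$status[] <- 0L
  gh <- gauss_hermite(nodes)
  eta <- matrix(0, length(oa$subjects), 2)
  res <- cpp_long_marginal(
    oa$off, oa$y, oa$fam, oa$a, oa$b, oa$c, oa$d, oa$delta, oa$n, oa$m,
    oa$lch, oa$th, oa$ncat, oa$t_years, oa$xgrp,
    params$theta1, params$theta2, params$omega1, params$omega2, params$rho,
    params$beta_drug,
    if (is.null(hazard)) -1L else hazard_kind_code(hazard$kind),
    if (is.null(hazard)) 0 else hazard$theta3,
    if (is.null(hazard) || is.na(hazard$theta4)) 0 else hazard$theta4,
    da$status, da$t1, da$t2,
    if (method == "laplace") 0L else 1L, gh$nodes, gh$weights, eta)
  if (any(!is.finite(res$subject)))
    abort(paste0("non-finite joint likelihood for subject(s): ",
                 paste(head(oa$subjects[!is.finite(res$subject)], 5),
                       collapse = ", ")))
  tibble(subject_id = oa$subjects, loglik = as.numeric(res$subject))
}

## two-stage starting values: per-visit empirical Bayes disability scores
## regressed on time within subject
start_values_longitudinal <- function(oa, dropout, hazard_kind, drug_effect) {
  rsp <- oa$responses
  key <- paste(rsp$subject_id, rsp$time_months, sep = "\r")
  ord <- order(key)
  rsp2 <- rsp[ord, ]
  idx2 <- oa$item_idx[ord]
  ukey <- unique(key[ord])
  ki <- match(key[ord], ukey)
  off2 <- c(0L, cumsum(tabulate(ki, nbins = length(ukey))))
  eb <- cpp_ebe(as.integer(off2), as.integer(rsp2$value), oa$fam[ord],
                oa$a[ord], oa$b[ord], oa$c[ord], oa$d[ord], oa$delta[ord],
                oa$n[ord], oa$m[ord], oa$lch[ord],
                oa$th[ord, , drop = FALSE], oa$ncat[ord])
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  sv <- tibble(subject_id = vapply(parts, `[`, "", 1),
               t = as.numeric(vapply(parts, `[`, "", 2)) / 12,
               d = eb[, 1])
  per <- sv |>
    group_by(.data$subject_id) |>
    summarise(nv = dplyr::n(), tbar = mean(.data$t), dbar = mean(.data$d),
              sxx = sum((.data$t - mean(.data$t))^2),
              sxy = sum((.data$t - mean(.data$t)) * (.data$d - mean(.data$d))),
              .groups = "drop") |>
    mutate(slope = ifelse(.data$sxx > 0, .data$sxy / .data$sxx, NA_real_),
           icpt = .data$dbar - ifelse(is.na(.data$slope), 0, .data$slope) *
             .data$tbar)
  x <- oa$xgrp[match(per$subject_id, oa$subjects)]
  th1 <- mean(per$icpt)
  sl_pbo <- per$slope[x == 0]
  sl_trt <- per$slope[x == 1]
  th2 <- if (length(sl_pbo) > 1) mean(sl_pbo, na.rm = TRUE)
         else mean(per$slope, na.rm = TRUE)
  if (!is.finite(th2) || abs(th2) < 1e-3) th2 <- 0.1
  beta0 <- 0
  if (drug_effect && length(sl_trt) > 1 && is.finite(mean(sl_trt, na.rm = TRUE)))
    beta0 <- min(max(1 - mean(sl_trt, na.rm = TRUE) / th2, -0.5), 0.5)
  om1 <- max(sd(per$icpt) * 0.9, 0.05)
  om2 <- max(sd(per$slope, na.rm = TRUE) * 0.6, 0.05)
  rho0 <- suppressWarnings(cor(per$icpt, per$slope, use = "complete.obs"))
  if (!is.finite(rho0)) rho0 <- 0
  rho0 <- min(max(rho0 * 0.8, -0.9), 0.9)
  par <- c(theta1 = th1, theta2 = th2, logw1 = log(om1), logw2 = log(om2),
           zrho = atanh(rho0))
  if (drug_effect) par <- c(par, beta = beta0)
  if (!is.null(hazard_kind)) {
    n_drop <- if (is.null(dropout)) 0 else
      sum(!is.na(dropout$first_missed_months))
    py <- if (is.null(dropout)) length(oa$subjects) else
      sum(dropout$last_seen_months) / 12 + 1e-6
    par <- c(par, theta3 = log(max(n_drop, 0.5) / max(py, 1e-3)))
    if (hazard_kind != "constant") par <- c(par, theta4 = 0)
  }
  par
}

#' Fit the longitudinal latent-progression model
#'
#' Maximum marginal likelihood over the bivariate subject random effects
#' (baseline, slope) with item parameters fixed to the bank's values,
#' optionally with a fractional drug effect on the slope and an
#' interval-censored dropout model.
#'
#' @inheritParams joint_loglik
#' @param data Long-format responses (`subject_id`, `time_months`, `arm`,
#'   `item_id`, `value`).
#' @param hazard `NULL` (no dropout model) or a hazard kind string
#'   (`"constant"`, `"disability"`, `"progression_rate"`,
#'   `"baseline_disability"`).
#' @param drug_effect Estimate the fractional slope-reduction parameter
#'   (`beta_drug`)? Requires both arms in `data`.
#' @param start Optional named starting vector on the transformed scale;
#'   two-stage empirical-Bayes starting values are used by default.
#' @param se Compute standard errors / Wald intervals from the observed
#'   information.
#' @param use_tables Accelerate optimization by tabulating the per-item
#'   outcome log-likelihoods on a latent grid (step 0.02) and
#'   interpolating (cubic Hermite); exact evaluation is restored for the
#'   reported log-likelihood. Disable for oracle-grade likelihood values
#'   throughout.
#' @param control Passed to [stats::nlminb()].
#' @return A `cogirt_fit` of type `"longitudinal"` with natural-scale
#'   `estimates` (theta1, theta2, omega1, omega2, rho, and where present
#'   beta_drug, theta3, theta4), standard errors, the Wald 95% CI for
#'   `beta_drug`, the subject random-effect modes (`$ebe`) and settings.
#' @export
fit_longitudinal <- function(data, bank, hazard = NULL, drug_effect = FALSE,
                             dropout = NULL, method = c("laplace", "agh"),
                             nodes = 7, start = NULL, se = TRUE,
                             use_tables = TRUE, control = list()) {
  method <- match.arg(method)
  validate_responses(data, bank)
  if (is.character(hazard)) hazard_kind <- match.arg(
    hazard, c("constant", "disability", "progression_rate",
              "baseline_disability"))
  else hazard_kind <- NULL
  check_that(is.null(hazard_kind) || !is.null(dropout),
             "a hazard model needs `dropout` data")
  oa <- long_arrays(data, bank)
  check_that(any(diff(oa$off) >= 2), "need subjects with >= 2 observations")
  if (drug_effect)
    check_that(length(unique(oa$xgrp)) == 2,
               "drug_effect requires both arms in the data")
  da <- dropout_arrays(oa$subjects, dropout)
  if (is.null(hazard_kind)) da$status[] <- 0L
  gh <- gauss_hermite(nodes)
  n_subj <- length(oa$subjects)
  eta <- matrix(0, n_subj, 2)
  if (is.null(start))
    start <- start_values_longitudinal(oa, dropout, hazard_kind, drug_effect)
  hk_code <- if (is.null(hazard_kind)) -1L else hazard_kind_code(hazard_kind)
  mcode <- if (method == "laplace") 0L else 1L
  ## tabulated item curves: item parameters are fixed, so the per-item
  ## outcome log-likelihoods are precomputed on a latent grid once and
  ## interpolated during optimization; the reported log-likelihood is
  ## re-evaluated exactly at the optimum
  ia <- item_arrays(bank$items)
  tabs <- if (use_tables) item_table_cache(ia) else NULL
  obs_item0 <- as.integer(oa$item_idx - 1L)
  nll_impl <- function(par, with_tabs) {
    b <- if (drug_effect) par[["beta"]] else 0
    th3 <- if (!is.null(hazard_kind)) par[["theta3"]] else 0
    th4 <- if (!is.null(hazard_kind) && hazard_kind != "constant")
      par[["theta4"]] else 0
    res <- cpp_long_marginal(
      oa$off, oa$y, oa$fam, oa$a, oa$b, oa$c, oa$d, oa$delta, oa$n, oa$m,
      oa$lch, oa$th, oa$ncat, oa$t_years, oa$xgrp,
      par[["theta1"]], par[["theta2"]], exp(par[["logw1"]]),
      exp(par[["logw2"]]), tanh(par[["zrho"]]), b,
      hk_code, th3, th4, da$status, da$t1, da$t2, mcode,
      gh$nodes, gh$weights, eta,
      if (with_tabs) tabs else NULL,
      if (with_tabs) obs_item0 else NULL,
      if (with_tabs) as.integer(ia$sup) else NULL)
    -res$loglik
  }
  nll <- function(par) nll_impl(par, use_tables)
  ctl <- modifyList(list(iter.max = 500, eval.max = 2000, rel.tol = 1e-8),
                    control)
  opt <- nlminb(start, nll, control = ctl)
  par <- opt$par
  if (use_tables) opt$objective <- nll_impl(par, FALSE)
  natural <- c(theta1 = par[["theta1"]], theta2 = par[["theta2"]],
               omega1 = exp(par[["logw1"]]), omega2 = exp(par[["logw2"]]),
               rho = tanh(par[["zrho"]]))
  if (drug_effect) natural <- c(natural, beta_drug = par[["beta"]])
  if (!is.null(hazard_kind)) {
    natural <- c(natural, theta3 = par[["theta3"]])
    if (hazard_kind != "constant")
      natural <- c(natural, theta4 = par[["theta4"]])
  }
  if (abs(natural[["rho"]]) > 0.995)
    warn("random-effect correlation at boundary", class = "cogirt_boundary_warning")
  ses <- NULL; vc <- NULL
  if (se) {
    H <- try(optimHess(par, nll), silent = TRUE)
    ok <- !inherits(H, "try-error") &&
      all(is.finite(H)) &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 1e-10)
    if (ok) {
      Vt <- solve(H)
      jac <- rep(1, length(par))
      names(jac) <- names(par)
      jac[names(par) == "logw1"] <- natural[["omega1"]]
      jac[names(par) == "logw2"] <- natural[["omega2"]]
      jac[names(par) == "zrho"] <- 1 - natural[["rho"]]^2
      vc <- diag(jac) %*% Vt %*% diag(jac)
      dimnames(vc) <- list(names(natural), names(natural))
      ses <- setNames(sqrt(pmax(diag(vc), 0)), names(natural))
    } else {
      warn("observed-information Hessian not positive definite; standard errors skipped")
    }
  }
  ## final pass to refresh the random-effect modes at the optimum
  nll(par)
  sc_slope <- (1 - (if (drug_effect) par[["beta"]] else 0) * oa$xgrp) *
    (natural[["theta2"]] + eta[, 2])
  ebe <- tibble(subject_id = oa$subjects, x_grp = oa$xgrp,
                eta1 = eta[, 1], eta2 = eta[, 2],
                d0 = natural[["theta1"]] + eta[, 1], slope = sc_slope)
  fit <- new_cogirt_fit(
    type = "longitudinal",
    estimates = natural, se = ses,
    loglik = -opt$objective,
    converged = opt$convergence == 0,
    n_subjects = n_subj, n_obs = nrow(data),
    settings = list(method = method, nodes = nodes, hazard = hazard_kind,
                    drug_effect = drug_effect),
    vcov = vc, ebe = ebe, optim = opt
  )
  fit
}

#' Wald confidence interval for a fitted parameter
#'
#' @param fit A `cogirt_fit` with standard errors.
#' @param term Parameter name (e.g. `"beta_drug"`).
#' @param level Confidence level.
#' @return Named numeric `c(estimate, lower, upper)`.
#' @export
wald_ci <- function(fit, term = "beta_drug", level = 0.95) {
  check_that(term %in% names(fit$estimates),
             paste0("no parameter called ", term))
  check_that(!is.null(fit$se), "fit has no standard errors")
  z <- qnorm(1 - (1 - level) / 2)
  est <- fit$estimates[[term]]
  s <- fit$se[[term]]
  c(estimate = est, lower = est - z * s, upper = est + z * s)
}

#' Select the dropout hazard by likelihood-ratio testing
#'
#' Fits the constant hazard and each one-covariate hazard, compares each
#' covariate hazard to the constant one with a 1-df likelihood-ratio test
#' at the given significance level, and returns the best accepted hazard
#' together with the Delta(-2LL) table.
#'
#' @inheritParams fit_longitudinal
#' @param alpha LRT significance level (default 0.05, critical 3.84).
#' @param kinds Covariate hazard kinds to consider.
#' @return List with `hazard` (a [hazard_spec()] at the selected
#'   estimates), `kind`, `table` (tibble of fits and tests) and `fits`.
#' @export
select_hazard <- function(data, bank, dropout, drug_effect = FALSE,
                          alpha = 0.05,
                          kinds = c("disability", "progression_rate",
                                    "baseline_disability"), ...) {
  fits <- list()
  fits$constant <- fit_longitudinal(data, bank, hazard = "constant",
                                    dropout = dropout,
                                    drug_effect = drug_effect, se = FALSE, ...)
  ## warm-start every covariate hazard at the constant-hazard optimum
  ## (theta4 = 0), which guarantees the nested-likelihood ordering
  start0 <- c(fits$constant$optim$par, theta4 = 0)
  for (k in kinds)
    fits[[k]] <- fit_longitudinal(data, bank, hazard = k, dropout = dropout,
                                  drug_effect = drug_effect, se = FALSE,
                                  start = start0, ...)
  ll0 <- fits$constant$loglik
  tab <- purrr::map_dfr(names(fits), function(k) {
    ll <- fits[[k]]$loglik
    tibble(kind = k, loglik = ll,
           delta_m2ll = if (k == "constant") NA_real_ else 2 * (ll - ll0),
           df = if (k == "constant") NA_integer_ else 1L,
           p_value = if (k == "constant") NA_real_ else
             pchisq(max(2 * (ll - ll0), 0), 1, lower.tail = FALSE))
  })
  cand <- tab |> filter(.data$kind != "constant",
                        .data$p_value < alpha) |>
    arrange(desc(.data$loglik))
  kind <- if (nrow(cand) > 0) cand$kind[1] else "constant"
  est <- fits[[kind]]$estimates
  hz <- if (kind == "constant") hazard_spec("constant", est[["theta3"]])
        else hazard_spec(kind, est[["theta3"]], est[["theta4"]])
  list(hazard = hz, kind = kind, table = tab, fits = fits)
}
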