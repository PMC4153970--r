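## Total-score analysis methods used in the power comparison:
## (1) LS-means repeated-measures analysis of change from baseline and
## (2) a pharmacometric linear mixed-effects model for the total score
## with correlated baseline/slope random effects and a fractional drug
## effect on the slope.

decision_row <- function(method, estimate, ci_low, ci_high, null_value = 0) {
  tibble(method = method, estimate = estimate,
         ci_low = ci_low, ci_high = ci_high,
         significant = (null_value < ci_low) | (null_value > ci_high))
}

#' Least-squares means repeated-measures analysis
#'
#' Change from baseline as the dependent variable, treatment as the major
#' factor, visit as the repeated (categorical) factor with a
#' treatment-by-visit interaction, baseline score as a covariate, and
#' subjects as the grouping factor. The drug effect is the estimated
#' treatment difference at the last scheduled visit, declared significant
#' when its 95% confidence interval excludes 0 (Wald test).
#'
#' @param totals Tibble of subject-visit total scores: `subject_id`,
#'   `arm` ("placebo"/"treatment"), `time_months`, `total`.
#' @param covariance Within-subject covariance structure: compound
#'   symmetry (`"cs"`, default) or unstructured (`"un"`).
#' @param level Confidence level.
#' @return One-row decision tibble (`method`, `estimate`, `ci_low`,
#'   `ci_high`, `significant`), with the `gls` fit as attribute `"fit"`.
#' @export
ls_means_analysis <- function(totals, covariance = c("cs", "un"),
                              level = 0.95) {
  covariance <- match.arg(covariance)
  check_that(all(c("subject_id", "arm", "time_months", "total") %in%
                   names(totals)), "totals lack required columns")
  t0 <- min(totals$time_months)
  base <- totals |> filter(.data$time_months == t0) |>
    select("subject_id", baseline = "total")
  post <- totals |> filter(.data$time_months > t0) |>
    inner_join(base, by = "subject_id") |>
    mutate(change = .data$total - .data$baseline,
           visit = factor(.data$time_months),
           arm = factor(.data$arm, levels = c("placebo", "treatment")))
  check_that(nlevels(droplevels(post$arm)) == 2,
             "both arms must be present after baseline")
  check_that(length(unique(post$visit)) >= 2,
             "need at least two post-baseline visits")
  corr <- if (covariance == "cs")
    nlme::corCompSymm(form = ~ 1 | subject_id)
  else nlme::corSymm(form = ~ as.integer(visit) | subject_id)
  wts <- if (covariance == "un") nlme::varIdent(form = ~ 1 | visit) else NULL
  fit <- nlme::gls(change ~ baseline + visit * arm, data = post,
                   correlation = corr, weights = wts, method = "REML")
  beta <- coef(fit)
  V <- vcov(fit)
  last <- levels(post$visit)[nlevels(post$visit)]
  cvec <- setNames(numeric(length(beta)), names(beta))
  cvec["armtreatment"] <- 1
  inter <- paste0("visit", last, ":armtreatment")
  if (inter %in% names(cvec)) cvec[inter] <- 1
  est <- sum(cvec * beta)
  sed <- sqrt(drop(t(cvec) %*% V %*% cvec))
  z <- qnorm(1 - (1 - level) / 2)
  out <- decision_row("ls_means", est, est - z * sed, est + z * sed)
  attr(out, "fit") <- fit
  out
}

## negative log-likelihood of the total-score linear mixed model;
## subjects grouped by (arm, visit pattern) so each group shares one
## marginal covariance matrix
ts_nll_factory <- function(totals) {
  totals <- arrange(totals, .data$subject_id, .data$time_months)
  totals$t <- totals$time_months / 12
  totals$x <- as.numeric(totals$arm %in% c("treatment", "active", 1, "1"))
  pat <- totals |>
    group_by(.data$subject_id) |>
    summarise(x = .data$x[1],
              key = paste(.data$time_months, collapse = ","),
              .groups = "drop")
  gid <- paste(pat$x, pat$key, sep = "|")
  ysplit <- split(totals$total, totals$subject_id)
  tsplit <- split(totals$t, totals$subject_id)
  ## one response matrix (visits x subjects) per (arm, visit-pattern) group
  groups <- lapply(split(pat$subject_id, gid), function(ids) {
    list(Y = do.call(cbind, ysplit[ids]), tv = tsplit[[ids[1]]],
         x = pat$x[match(ids[1], pat$subject_id)])
  })
  function(par) {
    B <- par[["B"]]; S <- par[["S"]]
    wB <- exp(par[["logwB"]]); wS <- exp(par[["logwS"]])
    rho <- tanh(par[["zrho"]]); sig <- exp(par[["logsig"]])
    beta <- if ("beta" %in% names(par)) par[["beta"]] else 0
    Om <- matrix(c(wB^2, rho * wB * wS, rho * wB * wS, wS^2), 2, 2)
    nll <- 0
    for (g in groups) {
      s <- 1 - beta * g$x
      Z <- cbind(1, s * g$tv)
      Sig <- Z %*% Om %*% t(Z) + diag(sig^2, length(g$tv))
      ch <- try(chol(Sig), silent = TRUE)
      if (inherits(ch, "try-error")) return(1e10)
      mu <- B + s * S * g$tv
      W <- backsolve(ch, g$Y - mu, transpose = TRUE)
      nll <- nll + 0.5 * (ncol(g$Y) * (2 * sum(log(diag(ch))) +
                                         length(g$tv) * log(2 * pi)) +
                            sum(W * W))
    }
    nll
  }
}

#' Pharmacometric total-score mixed model
#'
#' Linear disease-progression model for the total score:
#' `Y_ij = (B + etaB_i) + (1 - beta * x_i) (S + etaS_i) t_ij + eps_ij`
#' with correlated subject random effects on baseline and slope, additive
#' residual error and a fractional drug effect on the slope. Fitted by
#' maximum likelihood (the marginal likelihood is Gaussian and closed
#' form); the drug effect is declared significant when the Wald 95%
#' confidence interval of `beta` excludes 0.
#'
#' @inheritParams ls_means_analysis
#' @param drug_effect Estimate the fractional drug effect (default TRUE;
#'   set FALSE to fit the placebo progression model only).
#' @return One-row decision tibble with attribute `"fit"` (named
#'   estimates, standard errors, log-likelihood, convergence flag).
#' @export
fit_total_score_model <- function(totals, drug_effect = TRUE, level = 0.95) {
  check_that(all(c("subject_id", "arm", "time_months", "total") %in%
                   names(totals)), "totals lack required columns")
  nllf <- ts_nll_factory(totals)
  t0 <- min(totals$time_months)
  b0 <- mean(totals$total[totals$time_months == t0])
  tend <- max(totals$time_months)
  s0 <- (mean(totals$total[totals$time_months == tend]) - b0) / (tend / 12)
  sd0 <- sd(totals$total[totals$time_months == t0])
  par0 <- c(B = b0, S = if (is.finite(s0)) s0 else 1,
            logwB = log(max(sd0 * 0.8, 0.5)), logwS = log(1),
            zrho = 0, logsig = log(max(sd0 * 0.4, 0.5)))
  if (drug_effect) par0 <- c(par0, beta = 0)
  opt <- nlminb(par0, nllf,
                control = list(iter.max = 500, eval.max = 2000))
  par <- opt$par
  nat <- c(B = par[["B"]], S = par[["S"]], omegaB = exp(par[["logwB"]]),
           omegaS = exp(par[["logwS"]]), rho = tanh(par[["zrho"]]),
           sigma = exp(par[["logsig"]]))
  if (drug_effect) nat <- c(nat, beta_drug = par[["beta"]])
  H <- try(optimHess(par, nllf), silent = TRUE)
  se_beta <- NA_real_
  ses <- NULL
  if (!inherits(H, "try-error") &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 1e-10)) {
    V <- solve(H)
    ses <- sqrt(diag(V))
    names(ses) <- names(par)
    if (drug_effect) se_beta <- ses[["beta"]]
  }
  z <- qnorm(1 - (1 - level) / 2)
  est <- if (drug_effect) par[["beta"]] else NA_real_
  out <- decision_row("total_score", est,
                      est - z * se_beta, est + z * se_beta)
  if (!drug_effect) out$significant <- NA
  attr(out, "fit") <- list(estimates = nat, se = ses,
                           loglik = -opt$objective,
                           converged = opt$convergence == 0)
  out
}

#' Longitudinal IRT analysis decision
#'
#' Fits the longitudinal IRT model with the fractional drug effect free
#' (item parameters fixed to the bank) and tests the drug effect by the
#' Wald criterion: significant when the 95% confidence interval of
#' `beta_drug` excludes 0.
#'
#' @param responses Item-level trial responses.
#' @param bank An [item_bank()] with calibrated item parameters.
#' @param level Confidence level.
#' @param ... Passed to [fit_longitudinal()].
#' @return One-row decision tibble with the fit as attribute `"fit"`.
#' @export
irt_analysis <- function(responses, bank, level = 0.95, ...) {
  fit <- fit_longitudinal(responses, bank, drug_effect = TRUE, se = TRUE,
                          ...)
  if (is.null(fit$se)) {
    out <- decision_row("irt", fit$estimates[["beta_drug"]], NA_real_,
                        NA_real_)
    out$significant <- FALSE # conservative when the Wald step failed
  } else {
    ci <- wald_ci(fit, "beta_drug", level)
    out <- decision_row("irt", ci[["estimate"]], ci[["lower"]],
                        ci[["upper"]])
  }
  attr(out, "fit") <- fit
  out
}
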