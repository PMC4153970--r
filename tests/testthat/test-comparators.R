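## simulate totals directly from a Gaussian progression model (cheap,
## independent of the IRT machinery)
sim_totals <- function(n, B = 22, S = 4, wB = 5, wS = 1.5, rho = 0.4,
                       sig = 2.5, beta = 0, visits = c(0, 3, 6, 9, 12, 15,
                                                       18)) {
  x <- rep(c(0, 1), length.out = n)
  z <- matrix(rnorm(2 * n), n)
  eB <- wB * z[, 1]
  eS <- wS * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  purrr::map_dfr(seq_len(n), function(i) {
    tv <- visits / 12
    mu <- (B + eB[i]) + (1 - beta * x[i]) * (S + eS[i]) * tv
    tibble::tibble(subject_id = sprintf("P%04d", i),
                   arm = ifelse(x[i] == 1, "treatment", "placebo"),
                   time_months = visits,
                   total = mu + rnorm(length(visits), 0, sig))
  })
}

test_that("LS-means analysis recovers constructed effects and nulls", {
  set.seed(41)
  ## identical arms, (near) zero noise: difference ~ 0, non-significant
  tot0 <- sim_totals(40, wB = 1e-3, wS = 1e-4, sig = 1e-3, beta = 0)
  d0 <- ls_means_analysis(tot0)
  expect_lt(abs(d0$estimate), 1e-2)
  expect_false(d0$significant)
  ## shifting treated post-baseline totals by -5: estimate ~ -5, significant
  tot <- sim_totals(60, wB = 1, wS = 0.2, sig = 0.3, beta = 0)
  tot$total <- tot$total - 5 * (tot$arm == "treatment") * (tot$time_months > 0)
  d <- ls_means_analysis(tot)
  expect_true(d$significant)
  expect_lt(abs(d$estimate + 5), 0.5)
  ## singular design: one arm missing
  expect_error(ls_means_analysis(dplyr::filter(tot, arm == "placebo")),
               "both arms")
})

test_that("LS-means compound-symmetry fit agrees with the random-intercept reference", {
  skip_if_not_installed("lme4")
  set.seed(42)
  tot <- sim_totals(60, wB = 5, wS = 0, rho = 0, sig = 3, beta = 0.3)
  d <- ls_means_analysis(tot)
  ## equivalent model: change ~ baseline + visit*arm + (1 | subject)
  t0 <- min(tot$time_months)
  base <- tot |> dplyr::filter(time_months == t0) |>
    dplyr::select(subject_id, baseline = total)
  post <- tot |> dplyr::filter(time_months > t0) |>
    dplyr::inner_join(base, by = "subject_id") |>
    dplyr::mutate(change = total - baseline, visit = factor(time_months),
                  arm = factor(arm, levels = c("placebo", "treatment")))
  ref <- lme4::lmer(change ~ baseline + visit * arm + (1 | subject_id),
                    data = post, REML = TRUE)
  fe <- lme4::fixef(ref)
  last <- levels(post$visit)[nlevels(post$visit)]
  ref_est <- fe[["armtreatment"]] +
    fe[[paste0("visit", last, ":armtreatment")]]
  expect_equal(d$estimate, ref_est, tolerance = 1e-6)
})

test_that("total-score mixed model recovers its own generating parameters", {
  set.seed(7)
  tot <- sim_totals(400, B = 22.7, S = 4.3, wB = 6, wS = 2, rho = 0.5,
                    sig = 3, beta = 0.2)
  d <- fit_total_score_model(tot)
  f <- attr(d, "fit")
  expect_true(f$converged)
  est <- f$estimates
  expect_lt(abs(est[["B"]] - 22.7) / 22.7, 0.1)
  expect_lt(abs(est[["S"]] - 4.3) / 4.3, 0.1)
  expect_lt(abs(est[["omegaB"]] - 6) / 6, 0.1)
  expect_lt(abs(est[["sigma"]] - 3) / 3, 0.1)
  expect_lt(abs(est[["beta_drug"]] - 0.2), 0.1)
  ## deterministic limit: no random effects, negligible noise
  set.seed(8)
  tot0 <- sim_totals(80, wB = 1e-3, wS = 1e-4, sig = 1e-3, beta = 0.25)
  d0 <- fit_total_score_model(tot0)
  expect_lt(abs(d0$estimate - 0.25), 1e-3)
  f0 <- attr(d0, "fit")
  expect_lt(abs(f0$estimates[["B"]] - 22), 0.01)
  expect_lt(abs(f0$estimates[["S"]] - 4), 0.01)
})

test_that("drug-effect confidence interval covers the null at the nominal rate", {
  set.seed(99)
  hits <- 0
  R <- 150
  for (r in seq_len(R)) {
    tot <- sim_totals(80, beta = 0)
    d <- fit_total_score_model(tot)
    hits <- hits + (d$ci_low <= 0 && d$ci_high >= 0)
  }
  cover <- hits / R
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.995)
})

test_that("CS LS-means and an unstructured MMRM reject at matching null rates", {
  set.seed(17)
  R <- 150
  rej <- matrix(FALSE, R, 2)
  for (r in seq_len(R)) {
    tot <- sim_totals(60, beta = 0, visits = c(0, 6, 12, 18))
    rej[r, 1] <- ls_means_analysis(tot, covariance = "cs")$significant
    rej[r, 2] <- ls_means_analysis(tot, covariance = "un")$significant
  }
  p1 <- mean(rej[, 1]); p2 <- mean(rej[, 2])
  ## paired Monte-Carlo tolerance from the discordant fraction
  disc <- mean(rej[, 1] != rej[, 2])
  expect_lt(abs(p1 - p2), 2 * sqrt(disc / R) + 0.02)
  expect_lt(p1, 0.12) # near-nominal null rejection
})

test_that("IRT analysis reports a Wald decision from the fitted drug effect", {
  bank <- reduced_item_bank()
  des <- trial_design(120, default_progression_params(0.5), bank, seed = 61)
  tr <- simulate_trial(des)
  dec <- irt_analysis(tr$responses, bank)
  expect_equal(dec$method, "irt")
  expect_true(dec$significant) # a 50% slope reduction is unmissable
  expect_true(dec$ci_low <= dec$estimate && dec$estimate <= dec$ci_high)
  f <- attr(dec, "fit")
  expect_s3_class(f, "cogirt_fit")
  expect_equal(f$settings$drug_effect, TRUE)
})
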