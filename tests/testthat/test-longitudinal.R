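test_that("trajectory arithmetic follows the linear progression model", {
  p <- progression_params(0.95, 0.35, 0.68, 0.39, 0.54, beta_drug = 0.2)
  eff0 <- list(eta1 = 0, eta2 = 0, x_grp = 0)
  expect_equal(trajectory(0, eff0, p), 0.95)
  expect_equal(trajectory(24, eff0, p), 0.95 + 0.35 * 2)
  ## treated: slope scaled by 1 - 0.2 = 0.8
  efft <- list(eta1 = 0, eta2 = 0, x_grp = 1)
  expect_equal(trajectory(12, efft, p) - trajectory(0, efft, p),
               0.8 * 0.35, tolerance = 1e-12)
  expect_equal(0.8 * 0.35, 0.28)
  ## subject effects shift both coefficients
  eff <- list(eta1 = 0.5, eta2 = -0.1, x_grp = 0)
  expect_equal(trajectory(12, eff, p), (0.95 + 0.5) + (0.35 - 0.1))
})

test_that("survival closed forms match the constant-hazard benchmark and quadrature", {
  p <- progression_params(0.9, 0.4, 0.5, 0.3, 0.3)
  eff <- list(eta1 = 0.2, eta2 = 0.1, x_grp = 0)
  hz_const <- hazard_spec("constant", theta3 = log(0.5))
  expect_equal(survival_prob(12, eff, p, hz_const), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(round(exp(-0.5), 6), 0.606531)
  expect_equal(survival_prob(0, eff, p, hz_const), 1)
  ## every kind: closed form vs adaptive quadrature and a dense Riemann sum
  for (kind in c("constant", "disability", "progression_rate",
                 "baseline_disability")) {
    hz <- if (kind == "constant") hazard_spec(kind, -0.5)
          else hazard_spec(kind, -0.5, 0.7)
    tt <- c(3, 9, 18)
    closed <- survival_prob(tt, eff, p, hz)
    quadr <- survival_prob(tt, eff, p, hz, method = "quadrature")
    expect_lt(max(abs(closed - quadr)), 1e-6)
    ## independent Riemann oracle for the disability-dependent kind
    if (kind == "disability") {
      sc <- cogirt:::subject_coefs(eff, p)
      u <- seq(0, 18 / 12, length.out = 2e5)
      h <- exp(-0.5 + 0.7 * (sc$d0 + sc$slope * u))
      S_riemann <- exp(-mean(h) * 18 / 12)
      expect_lt(abs(closed[3] - S_riemann), 1e-6)
    }
  }
})

test_that("interval-censored dropout likelihood uses survival differences", {
  p <- progression_params(0.9, 0.4, 0.5, 0.3, 0)
  eff <- list(eta1 = 0, eta2 = 0, x_grp = 0)
  hz <- hazard_spec("constant", theta3 = log(0.5))
  ## interval (1, 1.25) years = (12, 15) months
  ll <- dropout_interval_loglik(12, 15, eff, p, hz)
  expect_equal(ll, log(exp(-0.5) - exp(-0.5 * 1.25)), tolerance = 1e-12)
  expect_equal(exp(-0.5) - exp(-0.5 * 1.25), 0.0712692, tolerance = 1e-6)
  ## completer under a negligible hazard retains with certainty
  hz0 <- hazard_spec("constant", theta3 = -60)
  expect_equal(dropout_interval_loglik(20, NA, eff, p, hz0), 0,
               tolerance = 1e-12)
  ## interval probabilities over a partition of (0, infinity) sum to one
  cuts <- c(0, 3, 6, 12, 24, 60, 1e5)
  probs <- vapply(seq_len(length(cuts) - 1), function(i)
    exp(dropout_interval_loglik(cuts[i], cuts[i + 1], eff, p, hz)), 0)
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  expect_error(dropout_interval_loglik(15, 12, eff, p, hz), "exceed")
})

test_that("joint likelihood degenerates to the typical trajectory when variances vanish", {
  bank <- item_bank(dplyr::bind_rows(toy_binary("bin1", a = 1.2, b = 0.5),
                                     toy_recall("rec1")))
  rec <- manual_two_visit_records()
  p0 <- progression_params(0.8, 0.4, 1e-3, 1e-3, 0)
  jl <- joint_loglik(rec, bank, p0)
  direct <- item_loglik(1, 0.8, bank_item(bank, "bin1")) +
    item_loglik(3, 0.8, bank_item(bank, "rec1")) +
    item_loglik(1, 1.2, bank_item(bank, "bin1")) +
    item_loglik(6, 1.2, bank_item(bank, "rec1"))
  expect_equal(jl$loglik, direct, tolerance = 1e-3)
})

test_that("2-D adaptive quadrature matches a dense 401^2 grid oracle", {
  bank <- item_bank(dplyr::bind_rows(toy_binary("bin1", a = 1.2, b = 0.5),
                                     toy_recall("rec1")))
  rec <- manual_two_visit_records()
  p <- progression_params(0.6, 0.3, 0.7, 0.4, 0.4)
  jl <- joint_loglik(rec, bank, p, method = "agh", nodes = 40)
  ## dense 2-D grid over eta-space
  g <- seq(-8, 8, length.out = 401)
  h <- g[2] - g[1]
  Sg <- matrix(c(0.7^2, 0.4 * 0.7 * 0.4, 0.4 * 0.7 * 0.4, 0.4^2), 2)
  Si <- solve(Sg)
  items <- list(bank_item(bank, "bin1"), bank_item(bank, "rec1"))
  vals <- c(1, 3, 1, 6); tv <- c(0, 0, 1, 1); itix <- c(1, 2, 1, 2)
  ll_item <- function(D, i) item_loglik(vals[i], D, items[[itix[i]]])
  lpost <- outer(g, g, function(e1, e2) {
    out <- -0.5 * (Si[1, 1] * e1^2 + 2 * Si[1, 2] * e1 * e2 +
                     Si[2, 2] * e2^2) - log(2 * pi) -
      0.5 * determinant(Sg)$modulus[1]
    for (i in 1:4) out <- out + ll_item(0.6 + e1 + (0.3 + e2) * tv[i], i)
    out
  })
  oracle <- log(sum(exp(lpost)) * h * h)
  expect_lt(abs(jl$loglik - oracle), 1e-6)
})

test_that("constant-hazard dropout factorizes out of the joint likelihood", {
  bank <- item_bank(dplyr::bind_rows(toy_binary("bin1", a = 1.2, b = 0.5),
                                     toy_recall("rec1")))
  rec <- manual_two_visit_records()
  p <- progression_params(0.6, 0.3, 0.7, 0.4, 0.4)
  hz <- hazard_spec("constant", theta3 = log(0.4))
  drp <- tibble::tibble(subject_id = "A", last_seen_months = 12,
                        first_missed_months = 15)
  with_h <- joint_loglik(rec, bank, p, hazard = hz, dropout = drp)
  without <- joint_loglik(rec, bank, p)
  expected_term <- log(exp(-0.4) - exp(-0.4 * 1.25))
  expect_equal(with_h$loglik - without$loglik, expected_term,
               tolerance = 1e-9)
})

test_that("arms are exchangeable when the drug effect is zero", {
  bank <- mixed_toy_bank()
  des <- trial_design(40, progression_params(0.9, 0.35, 0.6, 0.35, 0.5,
                                             beta_drug = 0),
                      bank, seed = 6)
  tr <- simulate_trial(des)
  base <- joint_loglik(tr$responses, bank, des$params)
  flipped <- dplyr::mutate(tr$responses,
                           arm = ifelse(arm == "placebo", "treatment",
                                        "placebo"))
  expect_equal(sum(joint_loglik(flipped, bank, des$params)$loglik),
               sum(base$loglik), tolerance = 1e-9)
})

test_that("longitudinal fitting recovers parameters and obeys time-shift identities", {
  bank <- reduced_item_bank()
  p <- progression_params(0.9, 0.4, 0.6, 0.35, 0.4)
  des <- trial_design(150, p, bank, seed = 44)
  tr <- simulate_trial(des)
  fit <- fit_longitudinal(tr$responses, bank, se = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["theta1"]] - 0.9), 0.15)
  expect_lt(abs(fit$estimates[["theta2"]] - 0.4), 0.1)
  ## shifting all visit times by +6 months shifts theta1 by -theta2/2
  shifted <- dplyr::mutate(tr$responses, time_months = time_months + 6)
  fit2 <- fit_longitudinal(shifted, bank, se = FALSE)
  expect_equal(fit2$estimates[["theta1"]],
               fit$estimates[["theta1"]] - fit$estimates[["theta2"]] / 2,
               tolerance = 0.02)
  expect_equal(fit2$estimates[["theta2"]], fit$estimates[["theta2"]],
               tolerance = 0.02)
  ## tabulated and exact objectives land on the same optimum
  fit3 <- fit_longitudinal(tr$responses, bank, se = FALSE,
                           use_tables = FALSE)
  expect_equal(fit3$estimates, fit$estimates, tolerance = 1e-3)
})

test_that("likelihood-ratio selection distinguishes hazard structures", {
  bank <- reduced_item_bank()
  ## data generated under a constant hazard: constant should survive
  p <- progression_params(0.9, 0.35, 0.6, 0.3, 0)
  hzc <- hazard_spec("constant", theta3 = -1)
  des <- trial_design(150, p, bank, hazard = hzc, seed = 21,
                      schedule_months = c(0, 3, 6, 9, 12, 15, 18))
  tr <- simulate_trial(des)
  sel <- select_hazard(tr$responses, bank, tr$dropout)
  expect_equal(sel$kind, "constant")
  expect_true(all(sel$table$delta_m2ll >= -1e-6, na.rm = TRUE))
  ## strong progression-rate dependence: the slope-dependent kind wins
  p2 <- progression_params(0.9, 0.35, 0.3, 0.5, 0)
  hzs <- hazard_spec("progression_rate", theta3 = -1.4, theta4 = 2.2)
  des2 <- trial_design(250, p2, bank, hazard = hzs, seed = 22,
                       schedule_months = c(0, 3, 6, 9, 12, 15, 18))
  tr2 <- simulate_trial(des2)
  sel2 <- select_hazard(tr2$responses, bank, tr2$dropout)
  expect_equal(sel2$kind, "progression_rate")
  expect_gt(sel2$table$delta_m2ll[sel2$table$kind == "progression_rate"],
            qchisq(0.95, 1))
})

test_that("tidy and glance summarize longitudinal fits", {
  bank <- mixed_toy_bank()
  des <- trial_design(60, progression_params(0.9, 0.4, 0.5, 0.3, 0.3),
                      bank, seed = 2)
  tr <- simulate_trial(des)
  fit <- fit_longitudinal(tr$responses, bank)
  td <- tidy(fit)
  expect_setequal(td$term, c("theta1", "theta2", "omega1", "omega2", "rho"))
  expect_true(all(c("estimate", "std.error", "conf.low") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 60)
  expect_true(is.finite(gl$logLik))
  ## EBE table covers every subject
  expect_equal(nrow(fit$ebe), 60)
})
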