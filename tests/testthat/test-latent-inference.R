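test_that("single symmetric binary item has marginal probability one half", {
  rec <- tibble::tibble(subject_id = "s1", item_id = "bin1", value = 1L)
  bank <- item_bank(toy_binary(a = 1, b = 0, c = 0))
  ml <- marginal_loglik(rec, bank, nodes = 30)
  expect_equal(ml$loglik, log(0.5), tolerance = 1e-8)
})

test_that("adaptive quadrature matches a 20,001-point trapezoid oracle", {
  bank <- mixed_toy_bank()
  set.seed(14)
  rec <- tibble::tibble(
    subject_id = "s1",
    item_id = c("bin1", "rec1", "ord1"),
    value = c(1L, 4L, 2L))
  oracle <- grid_marginal_oracle(rec, bank)
  agh <- marginal_loglik(rec, bank, nodes = 50)
  expect_lt(abs(agh$loglik - oracle$loglik), 1e-8)
})

test_that("Laplace agrees with high-order quadrature on an item-rich subject", {
  ## 40-item bank: two copies of the reduced bank with fresh ids
  it1 <- reduced_item_bank()$items
  it2 <- dplyr::mutate(it1, item_id = paste0(item_id, "_rep"))
  bank <- item_bank(dplyr::bind_rows(it1, it2))
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 3), seed = 3)
  one <- resp[resp$subject_id == resp$subject_id[1], ]
  expect_equal(nrow(one), 40)
  la <- marginal_loglik(one, bank, method = "laplace")
  ag <- marginal_loglik(one, bank, nodes = 50)
  expect_lt(abs(la$loglik - ag$loglik) / abs(ag$loglik), 0.005)
})

test_that("marginal likelihood is invariant to item order and subject labels", {
  bank <- mixed_toy_bank()
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 30), seed = 8)
  base <- sum(marginal_loglik(resp, bank)$loglik)
  shuf <- resp[sample(nrow(resp)), ]
  expect_equal(sum(marginal_loglik(shuf, bank)$loglik), base,
               tolerance = 1e-10)
  relab <- dplyr::mutate(resp, subject_id = paste0("zz_", subject_id))
  expect_equal(sum(marginal_loglik(relab, bank)$loglik), base,
               tolerance = 1e-10)
})

test_that("empirical Bayes estimates behave like posterior modes", {
  bank <- item_bank(dplyr::bind_rows(
    toy_binary("b1", a = 1, b = 0.7, c = 0),
    toy_binary("b2", a = 1, b = 0.7, c = 0),
    toy_binary("b3", a = 1, b = 0.7, c = 0),
    toy_binary("b4", a = 1, b = 0.7, c = 0)))
  ## half failed, symmetric items: mode solves the score equation; compare
  ## with a root-finding oracle on the posterior derivative
  rec <- tibble::tibble(subject_id = "s", item_id = paste0("b", 1:4),
                        value = c(1L, 1L, 0L, 0L))
  eb <- estimate_ebe(rec, bank)
  dpost <- function(D) 2 * plogis(-(D - 0.7)) - 2 * plogis(D - 0.7) - D
  mode <- uniroot(dpost, c(-3, 3), tol = 1e-12)$root
  expect_equal(eb$d_hat, mode, tolerance = 1e-6)
  expect_true(eb$d_sd > 0)
  ## subjects without records fall back to the prior, with a warning
  expect_warning(eb2 <- estimate_ebe(rec, bank, subjects = c("s", "ghost")),
                 "without records")
  expect_equal(eb2$d_hat[eb2$subject_id == "ghost"], 0)
  expect_equal(eb2$d_sd[eb2$subject_id == "ghost"], 1)
  ## more items never increase the posterior uncertainty (nested sets)
  bank20 <- reduced_item_bank()
  resp <- simulate_baseline_studies(bank20, tibble::tibble(study_id = "S",
                                                           n = 40), seed = 4)
  sub5 <- resp |> dplyr::group_by(subject_id) |> dplyr::slice_head(n = 5) |>
    dplyr::ungroup()
  full_sd <- estimate_ebe(resp, bank20)$d_sd
  part_sd <- estimate_ebe(sub5, bank20)$d_sd
  expect_true(all(full_sd <= part_sd + 1e-10))
})

test_that("joint item-parameter estimation recovers a small bank", {
  bank <- item_bank(dplyr::bind_rows(
    toy_binary("b1", a = 1.4, b = -0.5, c = 0.05),
    toy_binary("b2", a = 1.0, b = 0.8, c = 0.1),
    toy_recall("r1", a = 1.2, b = -0.8, c = 0.08, n = 10),
    toy_recall("r2", a = 1.5, b = 0.2, c = 0.05, n = 10),
    toy_ordered("o1", a = 1, th = c(-0.5, 0.5, 1.5, 2.5))))
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 800), seed = 31)
  fit <- fit_baseline(resp, bank)
  expect_true(fit$converged)
  est <- fit$bank$items
  tru <- bank$items
  ## word-list items carry most information: tight recovery
  wl <- est$family == "binomial_words"
  expect_lt(max(abs(est$a[wl] - tru$a[wl])), 0.25)
  expect_lt(max(abs(est$b[wl] - tru$b[wl])), 0.25)
  expect_lt(max(abs(est$c[wl] - tru$c[wl])), 0.08)
  expect_lt(max(abs(est$thresholds[[5]] - tru$thresholds[[5]])), 0.4)
})

test_that("fitted likelihood beats systematically perturbed parameters", {
  bank <- item_bank(dplyr::bind_rows(
    toy_binary("b1", a = 1.2, b = -0.3, c = 0.05),
    toy_binary("b2", a = 0.9, b = 0.6, c = 0.05),
    toy_recall("r1", a = 1.2, b = -0.5, c = 0.05)))
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 600), seed = 7)
  ll_at <- function(bk) sum(marginal_loglik(resp, bk, nodes = 21)$loglik)
  worse <- bank
  worse$items$b <- worse$items$b + 0.5
  expect_gt(ll_at(bank), ll_at(worse))
})

test_that("items with degenerate responses are held with a named warning", {
  bank <- item_bank(dplyr::bind_rows(
    toy_binary("easy", a = 1, b = 12, c = 0), # nobody fails
    toy_binary("b2", a = 1, b = 0, c = 0),
    toy_recall("r1")))
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 150), seed = 9)
  expect_true(all(resp$value[resp$item_id == "easy"] == 0))
  expect_warning(fit <- fit_baseline(resp, bank, min_subjects = 10),
                 class = "cogirt_identifiability_warning")
  expect_true(fit$converged)
})

test_that("two-parameter binary fits cross-check against a Rasch glmer fit", {
  skip_if_not_installed("lme4")
  ## equal discriminations and c = 0: the model coincides with a Rasch
  ## model whose glmer parameterization is logit p = beta_item + u_i,
  ## u ~ N(0, sigma^2); then a_j = sigma and b_j = -beta_j / sigma.
  sig <- 1.3
  bs <- c(-1, -0.3, 0.2, 0.8, 1.4, -0.6, 0.5, 1.0)
  items <- dplyr::bind_rows(purrr::imap(bs, function(b, i)
    toy_binary(paste0("it", i), a = sig, b = b, c = 0)))
  bank <- item_bank(items)
  resp <- simulate_baseline_studies(bank, tibble::tibble(study_id = "S",
                                                         n = 1200),
                                    seed = 19)
  suppressWarnings(fit <- fit_baseline(resp, bank, start = "bank",
                                       fix_fields = "c"))
  g <- lme4::glmer(value ~ 0 + item_id + (1 | subject_id),
                   data = resp, family = binomial)
  sig_hat <- sqrt(unlist(lme4::VarCorr(g))[[1]])
  beta <- lme4::fixef(g)
  ord <- match(paste0("item_id", bank$items$item_id), names(beta))
  b_glmer <- -beta[ord] / sig_hat
  est <- fit$bank$items
  expect_lt(abs(mean(est$a) - sig_hat), 0.12)
  expect_lt(max(abs(est$b - b_glmer)), 0.2)
})
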