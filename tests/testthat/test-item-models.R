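test_that("binary 3PL failure curve matches direct evaluation", {
  it <- toy_binary(a = 1, b = 0, c = 0)
  expect_equal(prob_fail_3pl(0, it), 0.5)
  it2 <- toy_binary(a = 2, b = 1, c = 0.2)
  expect_equal(prob_fail_3pl(1, it2), 0.6) # midpoint (1+c)/2
  it3 <- toy_binary(a = 2, b = 1, c = 0.1)
  expect_equal(prob_fail_3pl(0, it3), 0.1 + 0.9 * plogis(-2),
               tolerance = 1e-12)
  expect_equal(round(prob_fail_3pl(0, it3), 6), 0.207283)
  ## strictly increasing, range (c, 1)
  p <- prob_fail_3pl(seq(-8, 8, 0.5), it3)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0.1 & p < 1))
  expect_error(prob_fail_3pl(0, toy_recall()), "binary3pl")
})

test_that("word-recognition curve has both asymptotes and reduces to 3PL at d = 1", {
  it <- toy_recognition(a = 1.1, b = 0.3, c = 0.1, d = 0.9)
  expect_equal(prob_fail_word_recognition(-50, it), 0.1, tolerance = 1e-12)
  expect_equal(prob_fail_word_recognition(50, it), 0.9, tolerance = 1e-12)
  expect_equal(prob_fail_word_recognition(0.3, it), 0.5)
  ## d = 1: identical to the 3PL curve everywhere
  it1 <- toy_recognition(a = 1.4, b = -0.2, c = 0.15, d = 1)
  itb <- toy_binary(a = 1.4, b = -0.2, c = 0.15)
  D <- seq(-6, 6, 0.1)
  expect_lt(max(abs(prob_fail_word_recognition(D, it1) -
                      prob_fail_3pl(D, itb))), 1e-12)
  expect_error(item_spec("x", "w", "word_recognition", a = 1, b = 0,
                         c = 0.9, d = 0.5, n_words = 12), "c")
})

test_that("word-count pmf matches exact binomial arithmetic and renormalizes", {
  it <- toy_recall(a = 1, b = 0, c = 0, n = 12)
  ## p = 1/2 at D = b: C(12,6)/2^12 = 924/4096
  expect_equal(pmf_word_count(6, 0, it), 924 / 4096, tolerance = 1e-12)
  expect_equal(round(pmf_word_count(6, 0, it), 6), 0.225586)
  ## degenerate: p ~ 0 puts all mass at zero errors
  it0 <- toy_recall(a = 1, b = 50, c = 0, n = 10)
  expect_equal(pmf_word_count(0, 0, it0), 1, tolerance = 1e-10)
  expect_equal(sum(pmf_word_count(0:12, 0.7, it)), 1, tolerance = 1e-12)
  ## truncated variant renormalizes over 0..max_count
  itt <- toy_recognition(n = 24, max_count = 12)
  p <- cogirt:::word_fail_prob(0.5, cogirt:::as_item(itt))
  manual <- dbinom(0:12, 24, p) / pbinom(12, 24, p)
  expect_equal(pmf_word_count(0:12, 0.5, itt), manual, tolerance = 1e-12)
  expect_equal(sum(pmf_word_count(0:12, 0.5, itt)), 1, tolerance = 1e-12)
  expect_error(pmf_word_count(13, 0.5, itt), "support")
})

test_that("generalized-Poisson pmf matches the unnormalized term and truncates", {
  ## direct term: p (p + delta k)^{k-1} e^{-p - delta k} / k!
  p <- 2; delta <- 0.1; k <- 3
  term <- p * (p + delta * k)^(k - 1) * exp(-p - delta * k) / factorial(k)
  expect_equal(round(term, 6), 0.17679)
  expect_equal(exp(cogirt:::gp_log_terms(k, p, delta)), term,
               tolerance = 1e-12)
  ## pmf proportional to the terms after truncation to 0..40
  it <- toy_count(delta = 0.1)
  D <- 0.5
  pm <- pmf_cancellation(0:40, D, it)
  expect_equal(sum(pm), 1, tolerance = 1e-12)
  pD <- it$d * (1 - plogis(it$a * (D - it$b)))
  t0 <- exp(-pD)
  t3 <- pD * (pD + 0.3)^2 * exp(-pD - 0.3) / 6
  expect_equal(pm[4] / pm[1], t3 / t0, tolerance = 1e-10)
  ## delta = 0 reduces to a truncated ordinary Poisson
  it0 <- toy_count(delta = 0)
  pm0 <- pmf_cancellation(0:40, D, it0)
  pois <- dpois(0:40, pD) / ppois(40, pD)
  expect_equal(pm0, pois, tolerance = 1e-10)
  ## mean decreasing in D (disability lowers the score)
  mns <- expected_item_score(c(-2, 0, 2, 4), it)
  expect_true(all(diff(mns) < 0))
  expect_error(item_spec("x", "nc", "gen_poisson_count", a = 1, b = 0,
                         d = 20, delta = -0.6), "delta")
})

test_that("proportional-odds probabilities come from cumulative differences", {
  it <- toy_ordered(a = 1, th = c(-1, 0, 1, 2))
  pr <- pmf_ordered(0:4, 0, it)
  expect_equal(round(pr, 6),
               c(0.268941, 0.231059, 0.231059, 0.149738, 0.119203))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))
  ## extreme disability concentrates on the top category
  expect_equal(pmf_ordered(4, 60, it), 1, tolerance = 1e-10)
  expect_error(item_spec("x", "r", "ordered_categorical", a = 1,
                         thresholds = c(1, 0.5, 2, 3)), "non-decreasing")
})

test_that("all pmfs normalize to one across random parameter draws", {
  set.seed(91)
  for (r in 1:100) {
    fam <- sample(c("binary", "recall", "recognition", "count", "ordered"), 1)
    D <- runif(1, -4, 4)
    it <- switch(fam,
      binary = toy_binary(a = runif(1, 0.3, 2.5), b = runif(1, -3, 3),
                          c = runif(1, 0, 0.4)),
      recall = toy_recall(a = runif(1, 0.3, 2.5), b = runif(1, -3, 3),
                          c = runif(1, 0, 0.4),
                          n = sample(5:15, 1)),
      recognition = {
        cc <- runif(1, 0, 0.4)
        toy_recognition(a = runif(1, 0.3, 2.5), b = runif(1, -3, 3),
                        c = cc, d = runif(1, cc + 0.1, 1))
      },
      count = toy_count(a = runif(1, 0.3, 2), b = runif(1, -2, 3),
                        d = runif(1, 5, 38), delta = runif(1, 0, 0.6)),
      ordered = toy_ordered(a = runif(1, 0.3, 2.5),
                            th = sort(runif(4, -3, 4))))
    sup <- item_support(it)
    expect_equal(sum(item_pmf(sup, D, it)), 1, tolerance = 1e-10)
  }
})

test_that("expected item score is monotone in disability for every family", {
  D <- seq(-6, 6, 0.1)
  for (it in list(toy_binary(a = 1.2, b = 0.5, c = 0.1), toy_recall(),
                  toy_recognition(), toy_ordered())) {
    es <- expected_item_score(D, it)
    expect_true(all(diff(es) >= -1e-12))
  }
  ## cancellation: points decrease, so 40 - points increases
  es <- 40 - expected_item_score(D, toy_count())
  expect_true(all(diff(es) >= -1e-12))
})

test_that("item log-likelihood agrees with the pmf and normalizes", {
  set.seed(5)
  bank <- mixed_toy_bank()
  for (r in 1:200) {
    j <- sample(nrow(bank$items), 1)
    it <- bank$items[j, ]
    D <- runif(1, -3, 3)
    sup <- item_support(it)
    v <- sample(sup, 1)
    expect_equal(exp(item_loglik(v, D, it)), item_pmf(v, D, it),
                 tolerance = 1e-12)
  }
  it <- toy_ordered()
  ll <- item_loglik(0:4, 0.3, it)
  expect_equal(cogirt:::logsumexp(ll), 0, tolerance = 1e-12)
  expect_equal(item_loglik(1, 0, toy_binary()), log(0.5))
})

test_that("samplers reproduce their pmfs (chi-square at n = 1e5) and are seed-stable", {
  set.seed(33)
  n <- 1e5
  ## near-certain failure
  sure <- toy_binary(a = 1, b = -40, c = 0)
  expect_true(all(sample_item(rep(0, 100), sure) == 1))
  ## binomial mean within 3 MC sd
  itb <- toy_recall(a = 1, b = 0, c = 0, n = 10)
  D <- rep(cogirt:::as_item(itb)$b + qlogis(0.3), n) # p = 0.3
  x <- sample_item(D, itb)
  expect_lt(abs(mean(x) - 3), 3 * sqrt(10 * 0.3 * 0.7 / n))
  ## chi-square goodness of fit for count and ordered samplers
  itg <- toy_count()
  xg <- sample_item(rep(1, n), itg)
  pg <- pmf_cancellation(0:40, 1, itg)
  keep <- pg * n >= 5
  ob <- tabulate(xg + 1, 41)
  expect_gt(chisq.test(c(ob[keep], sum(ob[!keep])),
                       p = c(pg[keep], sum(pg[!keep])))$p.value, 0.01)
  ito <- toy_ordered()
  xo <- sample_item(rep(0.5, n), ito)
  expect_gt(chisq.test(tabulate(xo + 1, 5),
                       p = pmf_ordered(0:4, 0.5, ito))$p.value, 0.01)
  ## reproducibility contract
  set.seed(77); a1 <- sample_item(rnorm(50), itg)
  set.seed(77); a2 <- sample_item(rnorm(50), itg)
  expect_identical(a1, a2)
})
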