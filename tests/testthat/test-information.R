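test_that("binary information matches closed-form algebra", {
  it <- toy_binary(a = 1, b = 0, c = 0)
  expect_equal(item_information(it, 0), 0.25)
  ## 3PL at D = b: a^2 (1 - c) / (4 (1 + c))
  it2 <- toy_binary(a = 1, b = 0.5, c = 0.2)
  expect_equal(item_information(it2, 0.5), 0.8 / 4.8, tolerance = 1e-12)
  expect_equal(round(item_information(it2, 0.5), 6), 0.166667)
  a <- 1.7; cc <- 0.1
  it3 <- toy_binary(a = a, b = -1, c = cc)
  expect_equal(item_information(it3, -1), a^2 * (1 - cc) / (4 * (1 + cc)),
               tolerance = 1e-12)
})

test_that("every family matches the finite-difference expectation oracle", {
  D <- c(-2, -0.5, 0.8, 2.5)
  for (it in list(toy_binary(a = 1.3, b = 0.4, c = 0.08),
                  toy_recall(), toy_recognition(),
                  toy_recognition("wrgt", n = 24, max_count = 12),
                  toy_count(), toy_ordered())) {
    info <- item_information(it, D)
    oracle <- fd_information_oracle(it, D)
    expect_lt(max(abs(info - oracle) / pmax(abs(oracle), 1e-8)), 1e-5)
    expect_true(all(info >= 0))
  }
})

test_that("binomial information is n times the per-word binary information", {
  itb <- toy_binary(a = 1.2, b = -0.4, c = 0.07)
  itw <- toy_recall(a = 1.2, b = -0.4, c = 0.07, n = 10)
  D <- seq(-3, 3, 0.5)
  expect_equal(item_information(itw, D), 10 * item_information(itb, D),
               tolerance = 1e-12)
})

test_that("population-average information has the right limits and oracle", {
  it <- toy_recall()
  ## point-mass limit
  pop0 <- population_spec("pt", mean = 0.7, sd = 1e-6)
  expect_equal(average_information(it, pop0), item_information(it, 0.7),
               tolerance = 1e-4)
  ## Monte-Carlo oracle
  pop <- population_spec("MCI", mean = -0.5, sd = 0.6)
  set.seed(12)
  draws <- rnorm(2e5, pop$mean, pop$sd)
  mc <- item_information(it, draws)
  expect_lt(abs(average_information(it, pop) - mean(mc)),
            3 * sd(mc) / sqrt(length(mc)))
  ## additivity: component average equals the sum of item averages
  items <- dplyr::bind_rows(toy_recall("r1"), toy_recall("r2", b = 0.3))
  expect_equal(average_information(items, pop),
               average_information(items[1, ], pop) +
                 average_information(items[2, ], pop), tolerance = 1e-12)
})

test_that("component ranking sorts, sums to 100 percent and is population dependent", {
  pop <- population_spec("MCI", -0.5, 0.7)
  single <- item_bank(toy_recall())
  r1 <- rank_components(single, pop)
  expect_equal(r1$pct_total, 100)
  ## two-component toy where one dominates at all D: scaling every a by 2
  ## preserves the ordering
  bank <- item_bank(dplyr::bind_rows(
    item_spec("strong", "memory", "binomial_words", a = 1.6, b = 0,
              c = 0, n_words = 10),
    item_spec("weak", "language", "binary3pl", a = 0.6, b = 0.2, c = 0)))
  rk <- rank_components(bank, pop)
  expect_equal(rk$component, c("memory", "language"))
  expect_equal(sum(rk$pct_total), 100, tolerance = 0.1)
  bank2 <- bank
  bank2$items$a <- bank2$items$a * 2
  rk2 <- rank_components(bank2, pop)
  expect_equal(rk2$component, rk$component)
  ## separated difficulties flip the ranking between populations
  sep <- item_bank(dplyr::bind_rows(
    item_spec("easy", "early", "binary3pl", a = 1.5, b = -1.5, c = 0),
    item_spec("hard", "late", "binary3pl", a = 1.5, b = 1.5, c = 0)))
  early_pop <- population_spec("mci", -1.5, 0.4)
  late_pop <- population_spec("ad", 1.5, 0.4)
  expect_equal(rank_components(sep, early_pop)$component[1], "early")
  expect_equal(rank_components(sep, late_pop)$component[1], "late")
  ## total information larger where curves are steep than in the asymptotes
  mid_pop <- population_spec("mid", 0, 0.4)
  out_pop <- population_spec("out", 6, 0.4)
  expect_gt(sum(rank_components(sep, mid_pop)$information),
            sum(rank_components(sep, out_pop)$information))
})

test_that("information is additive over items and matches the marginal curvature", {
  ## total information = sum over items because D is the only random
  ## effect; check against the posterior curvature from estimate_ebe at
  ## an interior mode on near-balanced data
  bank <- item_bank(dplyr::bind_rows(
    toy_binary("b1", a = 1, b = 0, c = 0),
    toy_binary("b2", a = 1, b = 0, c = 0),
    toy_recall("r1", a = 1.1, b = 0, c = 0)))
  rec <- tibble::tibble(subject_id = "s",
                        item_id = c("b1", "b2", "r1"),
                        value = c(1L, 0L, 5L))
  eb <- estimate_ebe(rec, bank)
  ## at the mode the curvature is prior (1) + observed item information;
  ## for these symmetric outcomes observed = expected information
  tot_info <- sum(vapply(seq_len(3), function(j)
    item_information(bank$items[j, ], eb$d_hat), 0))
  expect_equal(unname(1 / eb$d_sd^2), 1 + tot_info, tolerance = 0.02)
})

test_that("information curves cover the default grid with non-negative values", {
  ic <- information_curve(mixed_toy_bank())
  expect_s3_class(ic, "information_curves")
  expect_true(all(ic$info >= 0))
  expect_equal(range(ic$D), c(-6, 6))
  p <- autoplot(ic)
  expect_s3_class(p, "ggplot")
})
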