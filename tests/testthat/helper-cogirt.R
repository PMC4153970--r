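## Shared fixtures: toy items/banks built in code, plus brute-force
## oracles (dense-grid integration, finite-difference information).

toy_binary <- function(id = "bin1", a = 1, b = 0, c = 0)
  item_spec(id, "task", "binary3pl", a = a, b = b, c = c)

toy_recall <- function(id = "rec1", a = 1.2, b = -0.5, c = 0.05, n = 10)
  item_spec(id, "recall", "binomial_words", a = a, b = b, c = c, n_words = n)

toy_recognition <- function(id = "wrg1", a = 1, b = 0.2, c = 0.1, d = 0.9,
                            n = 12, max_count = NA)
  item_spec(id, "recognition", "word_recognition", a = a, b = b, c = c,
            d = d, n_words = n, max_count = max_count)

toy_count <- function(id = "nc1", a = 0.9, b = 1.5, d = 25, delta = 0.1)
  item_spec(id, "cancellation", "gen_poisson_count", a = a, b = b, d = d,
            delta = delta, max_count = 40)

toy_ordered <- function(id = "ord1", a = 1, th = c(-1, 0, 1, 2))
  item_spec(id, "rater", "ordered_categorical", a = a, thresholds = th)

## one item of every family
mixed_toy_bank <- function() {
  item_bank(dplyr::bind_rows(
    toy_binary("bin1", a = 1.3, b = 0.4, c = 0.05),
    toy_binary("bin2", a = 0.9, b = 1.2, c = 0.1),
    toy_recall(), toy_recognition(), toy_count(), toy_ordered()
  ))
}

## single cheap binary item bank (for large-n simulation properties)
one_item_bank <- function() item_bank(toy_binary())

## dense-grid (trapezoid) oracle for the 1-D baseline marginal likelihood
grid_marginal_oracle <- function(records, bank, lo = -10, hi = 10,
                                 n = 20001) {
  grid <- seq(lo, hi, length.out = n)
  h <- grid[2] - grid[1]
  out <- vapply(unique(records$subject_id), function(sid) {
    rec <- records[records$subject_id == sid, ]
    f <- rep(0, length(grid))
    for (i in seq_len(nrow(rec))) {
      it <- bank_item(bank, rec$item_id[i])
      f <- f + vapply(grid, function(g) item_loglik(rec$value[i], g, it), 0)
    }
    log(sum(exp(f) * dnorm(grid)) * h)
  }, 0)
  tibble::tibble(subject_id = unique(records$subject_id), loglik = out)
}

## finite-difference Fisher information oracle:
## -E[d^2 log pmf / dD^2] by central differences (step 1e-4)
fd_information_oracle <- function(item, D, h = 1e-4) {
  item <- cogirt:::as_item(item)
  sup <- item_support(item)
  vapply(D, function(dd) {
    pr <- item_pmf(sup, dd, item)
    d2 <- (item_loglik(sup, dd + h, item) - 2 * item_loglik(sup, dd, item) +
             item_loglik(sup, dd - h, item)) / h^2
    -sum(pr * d2)
  }, 0)
}

## item_loglik vectorized over support needs scalar D per call for some
## families; helper evaluating elementwise
item_loglik_vec <- function(values, D, item) {
  vapply(seq_along(values), function(i)
    item_loglik(values[i], D, item), 0)
}

## small longitudinal dataset simulated outside simulate_trial (manual,
## independent construction) for grid oracles
manual_two_visit_records <- function() {
  tibble::tibble(
    subject_id = "A", study_id = "X",
    time_months = c(0, 0, 12, 12), arm = "placebo",
    item_id = c("bin1", "rec1", "bin1", "rec1"),
    value = c(1L, 3L, 1L, 6L))
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%g within %g of %g", x, tol, target))
}
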