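## Item response models: probability curves, pmfs, log-likelihood and
## samplers for every assessment item family, as functions of latent
## cognitive disability D. Orientation: larger D = greater disability =
## higher failure probability / fewer cancellation points.

as_item <- function(item) {
  if (is.data.frame(item)) {
    check_that(nrow(item) == 1, "expected a single item (one row)")
    item <- as.list(item)
    item$thresholds <- item$thresholds[[1]]
  }
  item
}

#' Failure probability of a binary task (3PL)
#'
#' `c + (1 - c) * logistic(a * (D - b))`: the probability to fail a
#' pass/fail task as a function of latent cognitive disability.
#'
#' @param D Latent cognitive disability (numeric vector).
#' @param item A `binary3pl` item ([item_spec()] row).
#' @return Failure probabilities in `(c, 1)`, strictly increasing in `D`.
#' @export
prob_fail_3pl <- function(D, item) {
  item <- as_item(item)
  check_that(item$family == "binary3pl",
             paste0("prob_fail_3pl requires family binary3pl, got ", item$family))
  item$c + (1 - item$c) * logistic(item$a * (D - item$b))
}

#' Per-word failure probability of the word-recognition test
#'
#' Four-parameter curve `c + (d - c) * logistic(a * (D - b))`: `d` is the
#' maximal probability for a severely impaired subject to misclassify a
#' word, `c` the floor for an unimpaired subject.
#'
#' @inheritParams prob_fail_3pl
#' @param item A `word_recognition` item.
#' @return Probabilities in `(c, d)`.
#' @export
prob_fail_word_recognition <- function(D, item) {
  item <- as_item(item)
  check_that(item$family == "word_recognition",
             "prob_fail_word_recognition requires family word_recognition")
  check_that(item$c < item$d, "`c` must be smaller than `d`")
  item$c + (item$d - item$c) * logistic(item$a * (D - item$b))
}

## per-word failure probability for any binomial-family item
word_fail_prob <- function(D, item) {
  if (item$family == "word_recognition")
    item$c + (item$d - item$c) * logistic(item$a * (D - item$b))
  else
    item$c + (1 - item$c) * logistic(item$a * (D - item$b))
}

#' Pmf of a word-list error count
#'
#' Binomial over `n_words` with per-word failure probability from the
#' item's curve; renormalized over `0..max_count` for study variants that
#' store the count truncated (e.g. recognition truncated at 12).
#'
#' @param k Error count(s), in `0..min(n_words, max_count)`.
#' @param D Latent cognitive disability (scalar or same length as `k`).
#' @param item A `binomial_words` or `word_recognition` item.
#' @return Probabilities; a valid pmf over the support for fixed `D`.
#' @export
pmf_word_count <- function(k, D, item) {
  item <- as_item(item)
  check_that(item$family %in% c("binomial_words", "word_recognition"),
             "pmf_word_count requires a binomial-family item")
  n <- item$n_words
  kmax <- if (is.na(item$max_count)) n else min(item$max_count, n)
  check_that(all(k >= 0 & k <= kmax & k == floor(k)),
             paste0("word count outside support 0..", kmax))
  p <- word_fail_prob(D, item)
  val <- dbinom(k, n, p)
  if (kmax < n) val <- val / pbinom(kmax, n, p)
  val
}

## generalized Poisson, log unnormalized term; zero-probability beyond the
## positivity boundary when delta < 0
gp_log_terms <- function(kk, p, delta) {
  out <- rep(-Inf, length(kk))
  lam <- p + delta * kk
  ok <- lam > 0 | kk == 0
  kkok <- kk[ok]
  out[ok] <- log(p) + (kkok - 1) * log(p + delta * kkok) -
    p - delta * kkok - lgamma(kkok + 1)
  out[kk == 0] <- -p
  out
}

#' Pmf of the number-cancellation points
#'
#' Generalized Poisson with mean curve `p(D) = d * (1 - logistic(a(D - b)))`
#' and dispersion `delta`, renormalized over the support `0..max_count`
#' (default 0..40) so all probability mass lies on attainable scores.
#'
#' @param k Points scored, in `0..max_count`.
#' @param D Latent cognitive disability (scalar; or a vector when `k` is scalar).
#' @param item A `gen_poisson_count` item.
#' @return Probabilities summing to 1 over the support.
#' @export
pmf_cancellation <- function(k, D, item) {
  item <- as_item(item)
  check_that(item$family == "gen_poisson_count",
             "pmf_cancellation requires family gen_poisson_count")
  check_that(length(D) == 1 || length(k) == 1,
             "vectorize over `k` or over `D`, not both")
  kmax <- item$max_count
  check_that(all(k >= 0 & k <= kmax & k == floor(k)),
             paste0("points outside support 0..", kmax))
  if (length(D) > 1)
    return(vapply(D, function(dd) pmf_cancellation(k, dd, item), 0))
  p <- item$d * (1 - logistic(item$a * (D - item$b)))
  lt <- gp_log_terms(0:kmax, p, item$delta)
  lz <- logsumexp(lt)
  exp(gp_log_terms(k, p, item$delta) - lz)
}

## cumulative P(Y >= k) for k = 1..K-1 of a proportional-odds item
ordered_cum <- function(D, item) {
  vapply(item$thresholds, function(th) logistic(item$a * (D - th)),
         numeric(length(D)))
}

#' Pmf of a rater-assessed ordered category
#'
#' Proportional-odds model: `P(Y >= k) = logistic(a * (D - b_k))` with
#' non-decreasing thresholds `b_k`; category probabilities by cumulative
#' differences.
#'
#' @param k Category (0-based), in `0..n_categories - 1`.
#' @param D Latent cognitive disability (scalar; or a vector when `k` is scalar).
#' @param item An `ordered_categorical` item.
#' @return Probabilities; non-negative, summing to 1 over categories.
#' @export
pmf_ordered <- function(k, D, item) {
  item <- as_item(item)
  check_that(item$family == "ordered_categorical",
             "pmf_ordered requires family ordered_categorical")
  check_that(!is.unsorted(item$thresholds), "`thresholds` must be non-decreasing")
  K <- item$n_categories
  check_that(all(k >= 0 & k <= K - 1 & k == floor(k)),
             paste0("category outside 0..", K - 1))
  check_that(length(D) == 1 || length(k) == 1,
             "vectorize over `k` or over `D`, not both")
  if (length(D) == 1) {
    cum <- c(1, logistic(item$a * (D - item$thresholds)), 0)
    return(pmax(cum[k + 1] - cum[k + 2], 0))
  }
  th <- item$thresholds
  upper <- if (k == 0) rep(1, length(D))
           else logistic(item$a * (D - th[k]))
  lower <- if (k == K - 1) rep(0, length(D))
           else logistic(item$a * (D - th[k + 1]))
  pmax(upper - lower, 0)
}

#' Support of an item's outcome
#' @param item An [item_spec()] row.
#' @return Integer vector of attainable outcome values.
#' @export
item_support <- function(item) {
  item <- as_item(item)
  switch(item$family,
         binary3pl = 0:1,
         binomial_words = ,
         word_recognition = 0:min(item$n_words, item$max_count, na.rm = TRUE),
         gen_poisson_count = 0:item$max_count,
         ordered_categorical = 0:(item$n_categories - 1L))
}

#' Pmf of an item outcome (family dispatch)
#'
#' @param value Outcome value(s) in the item's support.
#' @param D Latent cognitive disability (scalar).
#' @param item An [item_spec()] row.
#' @return Probabilities.
#' @export
item_pmf <- function(value, D, item) {
  item <- as_item(item)
  switch(item$family,
         binary3pl = {
           check_that(all(value %in% 0:1), "binary outcome must be 0/1")
           p <- prob_fail_3pl(D, item)
           n_out <- max(length(value), length(D))
           v <- rep_len(value, n_out)
           p <- rep_len(p, n_out)
           ifelse(v == 1, p, 1 - p)
         },
         binomial_words = ,
         word_recognition = pmf_word_count(value, D, item),
         gen_poisson_count = pmf_cancellation(value, D, item),
         ordered_categorical = pmf_ordered(value, D, item))
}

#' Log-likelihood of one observed item outcome
#'
#' @inheritParams item_pmf
#' @return Log probability, finite for valid inputs.
#' @export
item_loglik <- function(value, D, item) {
  log(item_pmf(value, D, item))
}

#' Expected item outcome as a function of disability
#'
#' E(Y | D); computed from the pmf. Errors and categories increase with
#' disability, cancellation points decrease.
#'
#' @param D Vector of latent disability values.
#' @param item An [item_spec()] row.
#' @return Numeric vector of expected outcomes.
#' @export
expected_item_score <- function(D, item) {
  item <- as_item(item)
  sup <- item_support(item)
  vapply(D, function(dd) sum(sup * item_pmf(sup, dd, item)), 0)
}

#' Sample an item outcome
#'
#' Draws from the item's pmf at the given disability using R's RNG stream
#' (seed with `set.seed()` for reproducibility).
#'
#' @param D Vector of latent disability values (one draw per element).
#' @param item An [item_spec()] row.
#' @return Integer outcomes, one per element of `D`.
#' @export
sample_item <- function(D, item) {
  item <- as_item(item)
  switch(
    item$family,
    binary3pl = rbinom(length(D), 1, prob_fail_3pl(D, item)),
    binomial_words = ,
    word_recognition = {
      n <- item$n_words
      kmax <- if (is.na(item$max_count)) n else min(item$max_count, n)
      k <- rbinom(length(D), n, word_fail_prob(D, item))
      if (kmax < n) { # truncated storage: inverse-cdf within 0..kmax
        idx <- which(k > kmax)
        for (i in idx) {
          p <- word_fail_prob(D[i], item)
          pr <- dbinom(0:kmax, n, p)
          k[i] <- sample(0:kmax, 1, prob = pr)
        }
      }
      k
    },
    gen_poisson_count = {
      ## vectorized inverse-CDF over the truncated support
      kmax <- item$max_count
      p <- item$d * (1 - logistic(item$a * (D - item$b)))
      lt <- vapply(0:kmax, function(k) {
        lam <- p + item$delta * k
        out <- rep(-Inf, length(p))
        ok <- lam > 0 | k == 0
        if (k == 0) out[ok] <- -p[ok]
        else out[ok] <- log(p[ok]) + (k - 1) * log(lam[ok]) - p[ok] -
          item$delta * k - lgamma(k + 1)
        out
      }, numeric(length(p)))            # n x (kmax+1)
      lt <- matrix(lt, nrow = length(p))
      lt <- lt - apply(lt, 1, max)
      w <- exp(lt)
      cs <- w %*% upper.tri(diag(kmax + 1), diag = TRUE) # row cumsums
      u <- runif(length(p)) * cs[, kmax + 1]
      as.integer(rowSums(cs < u))
    },
    ordered_categorical = {
      cum <- vapply(item$thresholds,
                    function(th) logistic(item$a * (D - th)),
                    numeric(length(D)))  # n x (K-1), P(Y >= k)
      u <- runif(length(D))
      as.integer(rowSums(matrix(cum, nrow = length(D)) > u))
    })
}
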