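## Fisher information of each item for the latent cognitive disability:
## minus the expected curvature of the item log-likelihood in D. Because
## D is the only random effect, information is additive over items.

#' Population specification on the latent scale
#'
#' @param label Population label (e.g. "MCI", "mildAD").
#' @param mean Latent disability mean.
#' @param sd Latent disability SD (> 0).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(label, mean, sd) {
  check_that(sd > 0, "`sd` must be > 0")
  structure(list(label = label, mean = mean, sd = sd),
            class = "population_spec")
}

## per-word failure curve and its derivative
word_p_deriv <- function(D, item) {
  u <- if (item$family == "word_recognition") item$d else 1
  q <- logistic(item$a * (D - item$b))
  list(p = item$c + (u - item$c) * q,
       dp = (u - item$c) * item$a * q * (1 - q))
}

#' Fisher information of one item
#'
#' Closed forms for the binary, binomial and ordered-categorical
#' families; numeric expectation over the truncated support (via the
#' squared-score identity) for the generalized Poisson and truncated
#' binomial variants.
#'
#' @param item An [item_spec()] row.
#' @param D Latent disability values (vector).
#' @return Information values (1 / latent-variance units), `>= 0`.
#' @export
item_information <- function(item, D) {
  item <- as_item(item)
  switch(
    item$family,
    binary3pl = {
      pd <- word_p_deriv(D, item)
      pd$dp^2 / (pd$p * (1 - pd$p))
    },
    binomial_words = ,
    word_recognition = {
      n <- item$n_words
      kmax <- if (is.na(item$max_count)) n else min(item$max_count, n)
      pd <- word_p_deriv(D, item)
      if (kmax >= n) {
        n * pd$dp^2 / (pd$p * (1 - pd$p))
      } else {
        ## truncated storage: E[(d log P / dD)^2] over 0..kmax
        vapply(seq_along(D), function(i) {
          p <- pd$p[i]
          kk <- 0:kmax
          pr <- dbinom(kk, n, p) / pbinom(kmax, n, p)
          dlogS <- -n * dbinom(kmax, n - 1, p) / pbinom(kmax, n, p)
          sc <- (kk / p - (n - kk) / (1 - p) - dlogS) * pd$dp[i]
          sum(pr * sc^2)
        }, 0)
      }
    },
    gen_poisson_count = {
      kmax <- item$max_count
      vapply(D, function(dd) {
        q <- logistic(item$a * (dd - item$b))
        p <- max(item$d * (1 - q), 1e-10)
        dp <- -item$d * item$a * q * (1 - q)
        kk <- 0:kmax
        lt <- gp_log_terms(kk, p, item$delta)
        pr <- exp(lt - logsumexp(lt))
        u1 <- ifelse(kk == 0, -1, 1 / p + (kk - 1) / (p + item$delta * kk) - 1)
        m1 <- sum(pr * u1)
        sum(pr * ((u1 - m1) * dp)^2)
      }, 0)
    },
    ordered_categorical = {
      th <- item$thresholds
      vapply(D, function(dd) {
        gam <- c(1, logistic(item$a * (dd - th)), 0)
        dgam <- c(0, item$a * gam[-c(1, length(gam))] *
                    (1 - gam[-c(1, length(gam))]), 0)
        P <- pmax(gam[-length(gam)] - gam[-1], 1e-300)
        dP <- dgam[-length(dgam)] - dgam[-1]
        sum(dP^2 / P)
      }, 0)
    })
}

#' Information curves over a latent grid
#'
#' @param bank An [item_bank()] (or an item tibble).
#' @param grid Latent grid (default `seq(-6, 6, 0.05)`).
#' @return Tibble of class `information_curves`: `item_id`, `component`,
#'   `D`, `info`.
#' @export
information_curve <- function(bank, grid = seq(-6, 6, by = 0.05)) {
  items <- if (inherits(bank, "item_bank")) bank$items else bank
  out <- purrr::map_dfr(seq_len(nrow(items)), function(j) {
    tibble(item_id = items$item_id[j], component = items$component[j],
           D = grid, info = item_information(items[j, ], grid))
  })
  class(out) <- c("information_curves", class(out))
  out
}

#' Average item or component information in a population
#'
#' Gauss-Hermite average of the item information against a normal latent
#' distribution; a component's average information is the sum of its
#' items' averages.
#'
#' @param item An [item_spec()] row (or item tibble: summed).
#' @param pop A [population_spec()].
#' @param n_nodes Quadrature nodes (>= 5; default 41).
#' @return Scalar average information.
#' @export
average_information <- function(item, pop, n_nodes = 41) {
  check_that(n_nodes >= 5, "`n_nodes` must be >= 5")
  nq <- normal_quadrature(n_nodes, pop$mean, pop$sd)
  if (is.data.frame(item) && nrow(item) > 1)
    return(sum(vapply(seq_len(nrow(item)), function(j)
      average_information(item[j, ], pop, n_nodes), 0)))
  sum(nq$weights * item_information(item, nq$nodes))
}

#' Rank assessment components by population-average information
#'
#' @param bank An [item_bank()].
#' @param pop A [population_spec()].
#' @param n_nodes Quadrature nodes for the population average.
#' @return Tibble sorted by decreasing information: `rank`, `component`,
#'   `information`, `pct_total` (sums to 100); ties broken alphabetically.
#' @export
rank_components <- function(bank, pop, n_nodes = 41) {
  items <- bank$items
  check_that(nrow(items) > 0, "empty bank")
  comp <- items |>
    group_by(.data$component) |>
    summarise(information = sum(vapply(seq_along(.data$item_id), function(j)
      average_information(items[items$item_id == .data$item_id[j], ],
                          pop, n_nodes), 0)), .groups = "drop") |>
    arrange(desc(.data$information), .data$component) |>
    mutate(pct_total = 100 * .data$information / sum(.data$information),
           rank = dplyr::row_number(),
           population = pop$label) |>
    select("rank", "component", "information", "pct_total", "population")
  comp
}

#' @export
autoplot.information_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$D, y = .data$info,
                               colour = .data$item_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "cognitive disability",
                  y = "Fisher information", colour = "item") +
    ggplot2::theme_minimal()
}
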