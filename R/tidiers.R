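#' Tidy a cogirt fit
#'
#' One row per parameter with estimate, standard error (when available)
#' and Wald 95% bounds. Baseline fits report the natural-scale item
#' parameters, longitudinal fits the population progression (and, where
#' present, drug-effect and hazard) parameters.
#'
#' @param x A `cogirt_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cogirt_fit <- function(x, ...) {
  if (x$type == "baseline") {
    items <- x$bank$items
    out <- purrr::map_dfr(seq_len(nrow(items)), function(j) {
      row <- items[j, ]
      pars <- switch(row$family,
                     binary3pl = c(a = row$a, b = row$b, c = row$c),
                     binomial_words = c(a = row$a, b = row$b, c = row$c),
                     word_recognition = c(a = row$a, b = row$b, c = row$c,
                                          d = row$d),
                     gen_poisson_count = c(a = row$a, b = row$b, d = row$d,
                                           delta = row$delta),
                     ordered_categorical = c(
                       a = row$a,
                       setNames(row$thresholds[[1]],
                                paste0("b", seq_along(row$thresholds[[1]])))))
      tibble(item_id = row$item_id, component = row$component,
             term = names(pars), estimate = unname(pars))
    })
    return(out)
  }
  est <- x$estimates
  out <- tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$se)) {
    out$std.error <- unname(x$se[out$term])
    out$conf.low <- out$estimate - 1.96 * out$std.error
    out$conf.high <- out$estimate + 1.96 * out$std.error
  }
  out
}

#' One-line fit summary
#'
#' @param x A `cogirt_fit`.
#' @param ... Unused.
#' @return One-row tibble: type, log-likelihood, convergence, sizes,
#'   estimation method.
#' @export
glance.cogirt_fit <- function(x, ...) {
  tibble(type = x$type, logLik = x$loglik, converged = x$converged,
         n_subjects = x$n_subjects, n_obs = x$n_obs,
         method = x$settings$method %||% NA_character_,
         nodes = x$settings$nodes %||% NA_real_)
}

#' Item characteristic curves of a bank
#'
#' Expected item outcome (or failure probability for binary items) as a
#' function of latent disability, ready for plotting.
#'
#' @param bank An [item_bank()] or item tibble.
#' @param grid Latent grid.
#' @return Tibble of class `icc_curves`: `item_id`, `component`, `D`,
#'   `value`, `kind`.
#' @export
icc_curve <- function(bank, grid = seq(-6, 6, by = 0.05)) {
  items <- if (inherits(bank, "item_bank")) bank$items else bank
  out <- purrr::map_dfr(seq_len(nrow(items)), function(j) {
    row <- items[j, ]
    v <- if (row$family == "binary3pl") prob_fail_3pl(grid, row)
    else expected_item_score(grid, row)
    tibble(item_id = row$item_id, component = row$component, D = grid,
           value = v,
           kind = if (row$family == "binary3pl") "P(fail)" else "E[score]")
  })
  class(out) <- c("icc_curves", class(out))
  out
}

#' @export
autoplot.icc_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$D, y = .data$value,
                                       colour = .data$item_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "cognitive disability", y = NULL, colour = "item") +
    ggplot2::theme_minimal()
}
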