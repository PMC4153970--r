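## Model-checking outputs: item-characteristic-curve vs nonparametric
## smoother comparison at baseline, and simulation-based visual
## predictive checks (VPCs) at the item, total-score and dropout levels.

#' Compare a model ICC with a nonparametric smoother
#'
#' Plots (as data) the model item characteristic curve against a
#' penalized cubic-regression-spline smoother (GCV-selected smoothness)
#' of the observed outcome versus the empirical Bayes disability
#' estimates, with a pointwise 95% band. Binary outcomes are smoothed on
#' the logit scale; counts and categories on the identity scale. Per-study
#' stratification is supported to expose study-specific deviations.
#'
#' @param records Response records for the item (may contain other items;
#'   they are filtered out).
#' @param ebes Empirical Bayes estimates ([estimate_ebe()] output).
#' @param item The [item_spec()] row (or an item id resolved in `bank`).
#' @param bank Optional [item_bank()] used to resolve `item` by id.
#' @param grid Latent grid for the curves.
#' @param by_study Stratify the smoother by `study_id`?
#' @return Tibble: `stratum`, `D`, `model`, `smooth`, `lo`, `hi`
#'   (smoother columns are `NA` outside the observed disability range).
#' @export
icc_vs_smoother <- function(records, ebes, item, bank = NULL,
                            grid = seq(-6, 6, by = 0.05),
                            by_study = FALSE) {
  if (is.character(item)) {
    check_that(!is.null(bank), "supply `bank` to resolve an item id")
    item <- bank_item(bank, item)
  }
  item <- as_item(item)
  rec <- records[records$item_id == item$item_id, ]
  check_that(nrow(rec) > 0, "no records for this item")
  df <- inner_join(rec, ebes, by = "subject_id")
  if (nrow(df) < 30)
    warn("fewer than 30 observations; the smoother band will be wide")
  model_curve <- if (item$family == "binary3pl")
    prob_fail_3pl(grid, item) else expected_item_score(grid, item)
  strata <- if (by_study) split(df, df$study_id) else list(pooled = df)
  purrr::map_dfr(names(strata), function(snm) {
    d <- strata[[snm]]
    rng <- range(d$d_hat)
    fam <- if (item$family == "binary3pl") stats::binomial() else
      stats::gaussian()
    kk <- max(3, min(10, length(unique(d$d_hat)) - 1))
    sm <- try(mgcv::gam(value ~ s(d_hat, bs = "cr", k = kk), data = d,
                        family = fam, method = "GCV.Cp"), silent = TRUE)
    out <- tibble(stratum = snm, D = grid, model = model_curve,
                  smooth = NA_real_, lo = NA_real_, hi = NA_real_)
    if (!inherits(sm, "try-error")) {
      inside <- grid >= rng[1] & grid <= rng[2]
      pr <- predict(sm, newdata = data.frame(d_hat = grid[inside]),
                    se.fit = TRUE)
      inv <- fam$linkinv
      out$smooth[inside] <- inv(pr$fit)
      out$lo[inside] <- inv(pr$fit - 1.96 * pr$se.fit)
      out$hi[inside] <- inv(pr$fit + 1.96 * pr$se.fit)
    }
    out
  })
}

## statistic tables per level; `trial` is a list with responses and
## (for dropout) a dropout tibble
vpc_statistic <- function(trial, bank, level, sched, items = NULL) {
  if (level == "total") {
    tot <- total_score(trial$responses, bank)
    tot |>
      group_by(time_months = .data$time_months) |>
      summarise(median = median(.data$total),
                p2.5 = quantile(.data$total, 0.025, names = FALSE),
                p97.5 = quantile(.data$total, 0.975, names = FALSE),
                .groups = "drop") |>
      tidyr::pivot_longer(c("median", "p2.5", "p97.5"),
                          names_to = "statistic", values_to = "value") |>
      mutate(stratum = paste0("total:", .data$statistic)) |>
      select("stratum", "time_months", "value")
  } else if (level == "item") {
    rsp <- trial$responses
    if (!is.null(items)) rsp <- rsp[rsp$item_id %in% items, ]
    rsp |>
      group_by(.data$item_id, .data$time_months, .data$value) |>
      summarise(nn = dplyr::n(), .groups = "drop_last") |>
      mutate(value_frac = .data$nn / sum(.data$nn)) |>
      ungroup() |>
      mutate(stratum = paste0(.data$item_id, "=", .data$value)) |>
      select("stratum", "time_months", value = "value_frac")
  } else { # dropout: fraction still in study at each scheduled visit
    drp <- trial$dropout
    purrr::map_dfr(sched, function(tt)
      tibble(stratum = "retention", time_months = tt,
             value = mean(drp$last_seen_months >= tt)))
  }
}

#' Simulation-based visual predictive check
#'
#' Simulates `n_replicates` datasets under the design and given
#' parameters, computes the observed summary statistic per stratum and
#' the 95% percentile band of the same statistic across replicates.
#' Levels: `"total"` (median and outer percentiles of the total score per
#' visit), `"item"` (fraction of subjects with each item outcome per
#' visit), `"dropout"` (retention curve).
#'
#' @param trial Observed trial: a [simulate_trial()] object or a list
#'   with `responses` (+ `dropout` for the dropout level).
#' @param bank An [item_bank()].
#' @param params [progression_params()] of the fitted (or generating)
#'   model used for the predictive simulations.
#' @param design A [trial_design()]; defaults to the design echoed in
#'   `trial`. Its schedule must match the observed visit times.
#' @param hazard Optional [hazard_spec()] for the simulations (needed for
#'   the dropout level).
#' @param level `"total"`, `"item"` or `"dropout"`.
#' @param n_replicates Number of predictive replicates (default 200).
#' @param seed Master seed for the replicates.
#' @param items Optional item subset for the item level.
#' @return Tibble of class `cogirt_vpc`: `stratum`, `time_months`,
#'   `observed`, `lo`, `hi`, `n_replicates`.
#' @export
vpc <- function(trial, bank, params, design = NULL, hazard = NULL,
                level = c("total", "item", "dropout"), n_replicates = 200,
                seed = 1, items = NULL) {
  level <- match.arg(level)
  if (is.null(design)) design <- trial$design
  check_that(!is.null(design), "supply `design` (not present in `trial`)")
  obs_times <- sort(unique(trial$responses$time_months))
  check_that(all(obs_times %in% design$schedule_months),
             "observed visit times are not part of the design schedule")
  if (level == "dropout")
    check_that(!is.null(trial$dropout) && !is.null(hazard %||% design$hazard),
               "dropout level needs observed dropout data and a hazard")
  design$params <- params
  if (!is.null(hazard)) design$hazard <- hazard
  design$bank <- bank
  sched <- design$schedule_months
  obs <- vpc_statistic(trial, bank, level, sched, items) |>
    rename(observed = "value")
  seeds <- derive_seeds(seed, n_replicates, "vpc")
  sims <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    design$seed <- seeds[r]
    sims[[r]] <- vpc_statistic(simulate_trial(design), bank, level, sched,
                               items) |>
      mutate(replicate = r)
  }
  band <- bind_rows(sims) |>
    group_by(.data$stratum, .data$time_months) |>
    summarise(lo = quantile(.data$value, 0.025, names = FALSE),
              hi = quantile(.data$value, 0.975, names = FALSE),
              .groups = "drop")
  out <- left_join(obs, band, by = c("stratum", "time_months")) |>
    mutate(lo = ifelse(is.na(.data$lo), 0, .data$lo),
           hi = ifelse(is.na(.data$hi), 0, .data$hi),
           n_replicates = n_replicates)
  class(out) <- c("cogirt_vpc", class(out))
  attr(out, "replicates") <- bind_rows(sims)
  out
}

#' @export
autoplot.cogirt_vpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_months)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey75", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                       colour = "darkred") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "darkred", size = 0.8) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "time (months)", y = "statistic") +
    ggplot2::theme_minimal()
}

#' Power-curve plot
#'
#' @param power_results Rows from [estimate_power()] over sample sizes
#'   (and possibly methods).
#' @return A ggplot.
#' @export
plot_power_curve <- function(power_results) {
  ggplot2::ggplot(power_results,
                  ggplot2::aes(x = .data$n_total, y = .data$power,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "total number of subjects", y = "power") +
    ggplot2::theme_minimal()
}
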