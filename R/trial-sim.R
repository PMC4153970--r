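## Clinical-trial and multi-study synthetic data generation: item-level
## datasets with the statistical structure the models assume (latent
## N(0,1) disability at baseline; correlated baseline/slope random
## effects, arm-specific slope and monotone interval-censored dropout in
## trials).

#' Trial design
#'
#' @param n_total Total number of subjects (>= 2).
#' @param params A [progression_params()]; its `beta_drug` is the
#'   simulated treatment effect.
#' @param bank An [item_bank()].
#' @param schedule_months Ordered visit times in months, starting at 0
#'   (default the 7-assessment 18-month phase-III schedule).
#' @param allocation Fraction of subjects in the treated arm (0.5 =
#'   balanced parallel arms).
#' @param hazard A [hazard_spec()] for dropout, or `NULL` for no dropout.
#' @param variant Optional study variant id (see [item_bank()]
#'   `study_variants`) restricting the administered items.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_total, params, bank,
                         schedule_months = c(0, 3, 6, 9, 12, 15, 18),
                         allocation = 0.5, hazard = NULL, variant = NULL,
                         seed = NULL) {
  check_that(n_total >= 2, "`n_total` must be >= 2")
  check_that(allocation >= 0 && allocation <= 1,
             "`allocation` must lie in [0, 1]")
  check_that(schedule_months[1] == 0 && all(diff(schedule_months) > 0),
             "`schedule_months` must start at 0 and be strictly increasing")
  if (!is.null(variant))
    check_that(variant %in% names(bank$study_variants),
               paste0("unknown study variant: ", variant))
  structure(list(n_total = n_total, params = params, bank = bank,
                 schedule_months = schedule_months, allocation = allocation,
                 hazard = hazard, variant = variant, seed = seed),
            class = "trial_design")
}

## correlated bivariate normal random effects
draw_effects <- function(n, params) {
  z <- matrix(rnorm(2 * n), n, 2)
  e1 <- params$omega1 * z[, 1]
  e2 <- params$omega2 * (params$rho * z[, 1] +
                           sqrt(1 - params$rho^2) * z[, 2])
  cbind(eta1 = e1, eta2 = e2)
}

## inverse-CDF dropout time (years); Inf = never drops
draw_dropout_time <- function(sc, hazard) {
  e <- -log(runif(length(sc$d0)))
  th3 <- hazard$theta3; th4 <- hazard$theta4
  switch(hazard$kind,
         constant = e / exp(th3),
         progression_rate = e / exp(th3 + th4 * sc$slope),
         baseline_disability = e / exp(th3 + th4 * sc$d0),
         disability = {
           cc <- th4 * sc$slope
           h0 <- exp(th3 + th4 * sc$d0)
           out <- ifelse(abs(cc) < 1e-10, e / h0, {
             arg <- 1 + e * cc / h0
             ifelse(arg > 0, log(pmax(arg, 1e-300)) / cc, Inf)
           })
           out
         })
}

#' Simulate a parallel-arm clinical trial at the item level
#'
#' Draws correlated subject random effects, applies the arm-specific
#' slope (a fractional reduction of the subject progression rate in the
#' treated arm), samples every administered item at each attended visit,
#' and samples an interval-censored dropout time from the subject-specific
#' hazard when the design carries one.
#'
#' @param design A [trial_design()].
#' @return Object of class `simulated_trial`: `responses` (long tibble),
#'   `dropout` (per-subject last seen / first missed visit),
#'   `truth` (subject random effects and latent coefficients) and the
#'   design echo.
#' @export
simulate_trial <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n_total
  params <- design$params
  bank <- design$bank
  sched <- design$schedule_months
  n_trt <- round(n * design$allocation)
  x <- sample(rep(c(1, 0), c(n_trt, n - n_trt)))
  eff <- draw_effects(n, params)
  d0 <- params$theta1 + eff[, 1]
  slope <- (1 - params$beta_drug * x) * (params$theta2 + eff[, 2])
  sc <- list(d0 = d0, slope = slope)
  ids <- sprintf("S%04d", seq_len(n))
  if (!is.null(design$hazard)) t_drop <- draw_dropout_time(sc, design$hazard)
  else t_drop <- rep(Inf, n)
  ## attended visits: strictly before the dropout time
  attend <- outer(sched / 12, t_drop, `<`) # visits x subjects
  attend[1, ] <- TRUE                      # baseline always observed
  item_ids <- if (is.null(design$variant)) bank$items$item_id
              else study_items(bank, design$variant)
  vis_idx <- which(attend, arr.ind = TRUE)
  sub_i <- vis_idx[, 2]
  tim <- sched[vis_idx[, 1]]
  Dv <- d0[sub_i] + slope[sub_i] * tim / 12
  res <- vector("list", length(item_ids))
  for (k in seq_along(item_ids)) {
    it <- bank_item(bank, item_ids[k])
    res[[k]] <- tibble(subject_id = ids[sub_i],
                       time_months = tim,
                       arm = ifelse(x[sub_i] == 1, "treatment", "placebo"),
                       item_id = item_ids[k],
                       value = as.integer(sample_item(Dv, it)))
  }
  responses <- bind_rows(res) |>
    mutate(study_id = "SIM", .after = "subject_id") |>
    arrange(.data$subject_id, .data$time_months, .data$item_id)
  last_seen <- vapply(seq_len(n), function(i) max(sched[attend[, i]]), 0)
  first_missed <- vapply(seq_len(n), function(i) {
    miss <- sched[!attend[, i]]
    if (length(miss) == 0) NA_real_ else min(miss)
  }, 0)
  dropout <- tibble(subject_id = ids, last_seen_months = last_seen,
                    first_missed_months = first_missed)
  truth <- tibble(subject_id = ids, arm = ifelse(x == 1, "treatment",
                                                 "placebo"),
                  x_grp = x, eta1 = eff[, 1], eta2 = eff[, 2],
                  d0 = d0, slope = slope, dropout_years = t_drop)
  structure(list(responses = responses, dropout = dropout, truth = truth,
                 design = design),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat("<simulated_trial> ", x$design$n_total, " subjects, ",
      length(x$design$schedule_months), " visits, ",
      nrow(x$responses), " item responses, ",
      sum(!is.na(x$dropout$first_missed_months)), " dropouts\n", sep = "")
  invisible(x)
}

#' Simulate cross-sectional multi-study baseline data
#'
#' One latent disability per subject drawn from the standard normal, each
#' administered item sampled once, emulating pooled clinical databases in
#' which studies differ in their assessment variant (additional or
#' excluded components, truncated word-recognition storage, repeated
#' recognition trials).
#'
#' @param bank An [item_bank()].
#' @param studies Tibble/data frame with columns `study_id` and `n`
#'   (subjects per study); each `study_id` may have a variant mask in the
#'   bank, otherwise the full bank is administered.
#' @param seed Integer seed.
#' @return Long response tibble (`time_months = 0`) with the per-subject
#'   latent truth attached as attribute `"truth"`.
#' @export
simulate_baseline_studies <- function(bank, studies, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(studies))
  truths <- vector("list", nrow(studies))
  for (s in seq_len(nrow(studies))) {
    sid <- studies$study_id[s]
    if (length(bank$study_variants) > 0 &&
        !sid %in% names(bank$study_variants))
      abort(paste0("unknown study variant: ", sid))
    ns <- studies$n[s]
    if (ns == 0) next
    ids <- sprintf("%s_%05d", sid, seq_len(ns))
    D <- rnorm(ns)
    items <- study_items(bank, sid)
    res <- vector("list", length(items))
    for (k in seq_along(items)) {
      it <- bank_item(bank, items[k])
      res[[k]] <- tibble(subject_id = ids, study_id = sid, time_months = 0,
                         arm = "none", item_id = items[k],
                         value = as.integer(sample_item(D, it)))
    }
    out[[s]] <- bind_rows(res)
    truths[[s]] <- tibble(subject_id = ids, study_id = sid, D = D)
  }
  responses <- bind_rows(out)
  if (nrow(responses) > 0)
    responses <- arrange(responses, .data$study_id, .data$subject_id,
                         .data$item_id)
  attr(responses, "truth") <- bind_rows(truths)
  responses
}

#' Roll item responses up to component and total scores
#'
#' Deterministic mapping from item outcomes to the familiar total score:
#' task components contribute failure counts, rater items their category,
#' word-list components their error counts (multi-trial recall: mean
#' errors over the trials, rounded half up), and count components are
#' mapped through decreasing point bins. Partially missing components are
#' prorated by default (configurable through the bank's score map).
#'
#' @param responses Long response tibble.
#' @param bank An [item_bank()] whose `score_map` covers every component.
#' @return Tibble with one row per subject-visit: `subject_id`,
#'   `time_months`, `arm` (if present), `total` and `n_component_missing`.
#' @export
total_score <- function(responses, bank) {
  items <- bank$items
  sm <- bank$score_map
  idx <- match(responses$item_id, items$item_id)
  check_that(!anyNA(idx), "responses contain items not in the bank")
  has_arm <- "arm" %in% names(responses)
  if (!"time_months" %in% names(responses)) responses$time_months <- 0
  df <- tibble(subject_id = responses$subject_id,
               time_months = responses$time_months,
               component = items$component[idx],
               value = responses$value)
  ## base rowsum aggregation: ~10x faster than grouped summarise here
  key <- paste(df$subject_id, df$time_months, df$component, sep = "\r")
  agg <- rowsum(cbind(df$value, 1), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  comp_scores <- tibble(
    subject_id = vapply(parts, `[`, "", 1),
    time_months = as.numeric(vapply(parts, `[`, "", 2)),
    component = vapply(parts, `[`, "", 3),
    value_sum = agg[, 1], n_items = agg[, 2],
    value_mean = agg[, 1] / agg[, 2])
  ## vectorized scoring via a per-component rule lookup
  comps <- names(sm$components)
  meth <- vapply(sm$components, function(z) z$method, "")
  maxs <- vapply(sm$components, function(z) z$max, 0)
  ndef <- vapply(comps, function(cp) sum(items$component == cp), 0)
  ci <- match(comp_scores$component, comps)
  mth <- meth[ci]
  score <- comp_scores$value_sum
  i <- mth == "failures" & comp_scores$n_items < ndef[ci]
  score[i] <- round(comp_scores$value_mean[i] * ndef[ci][i])
  i <- mth == "mean_errors_rounded"
  score[i] <- floor(comp_scores$value_mean[i] + 0.5)
  for (cp in comps[meth == "binned_points"]) {
    ii <- comp_scores$component == cp
    score[ii] <- findInterval(-comp_scores$value_sum[ii],
                              -sm$components[[cp]]$bins)
  }
  comp_scores$score <- score
  comp_scores$comp_max <- maxs[ci]
  key2 <- paste(comp_scores$subject_id, comp_scores$time_months, sep = "\r")
  agg2 <- rowsum(cbind(comp_scores$score, comp_scores$comp_max, 1), key2)
  parts2 <- strsplit(rownames(agg2), "\r", fixed = TRUE)
  out <- tibble(
    subject_id = vapply(parts2, `[`, "", 1),
    time_months = as.numeric(vapply(parts2, `[`, "", 2)),
    raw = as.numeric(agg2[, 1]), present_max = as.numeric(agg2[, 2]),
    n_component_missing = length(sm$components) - as.numeric(agg2[, 3]))
  out$total <- out$raw
  i <- out$n_component_missing > 0
  if (any(i)) {
    if (sm$missing == "prorate")
      out$total[i] <- round(out$raw[i] * sm$total_max / out$present_max[i])
    else out$total[i] <- NA_real_
  }
  out <- select(out, "subject_id", "time_months", "total",
                "n_component_missing")
  if (has_arm) {
    arms <- responses |> distinct(.data$subject_id, .data$arm)
    out <- left_join(out, arms, by = "subject_id")
  }
  arrange(out, .data$subject_id, .data$time_months)
}

component_item_count <- function(items, component) {
  sum(items$component == component)
}
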