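## Power and type-I-error estimation across analysis methods and sample
## sizes, with common random numbers: each simulated trial is analyzed by
## every requested method.

#' Analyze one simulated trial with one or more methods
#'
#' @param trial A [simulate_trial()] result (or a list with `responses`).
#' @param methods Any of `"irt"`, `"total_score"`, `"ls_means"`.
#' @param level Confidence level of the decision intervals.
#' @param ... Passed to [irt_analysis()] (e.g. `method`, `nodes`).
#' @return Decision tibble, one row per method.
#' @export
analyze_trial <- function(trial, methods = c("irt", "total_score",
                                             "ls_means"),
                          level = 0.95, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  bank <- trial$design$bank
  out <- list()
  if (any(methods %in% c("total_score", "ls_means")))
    totals <- total_score(trial$responses, bank)
  for (m in methods) {
    dec <- tryCatch(
      switch(m,
             irt = irt_analysis(trial$responses, bank, level = level, ...),
             total_score = fit_total_score_model(totals, level = level),
             ls_means = ls_means_analysis(totals, level = level)),
      error = function(e) {
        d <- decision_row(m, NA_real_, NA_real_, NA_real_)
        d$significant <- NA
        attr(d, "error") <- conditionMessage(e)
        d
      })
    attr(dec, "fit") <- NULL
    out[[m]] <- dec
  }
  bind_rows(out)
}

#' Estimate power by clinical trial simulation
#'
#' Simulates `n_replicates` trials under the design, analyzes each with
#' every requested method (common random numbers across methods) and
#' reports the fraction of replicates with a significant drug effect,
#' with a Wilson 95% interval. Replicate-level fit failures are counted
#' and, by default, treated as non-significant (conservative).
#'
#' @param design A [trial_design()]; its `params$beta_drug` is the
#'   simulated effect.
#' @param methods Analysis methods (see [analyze_trial()]).
#' @param n_replicates Number of simulated trials (>= 1).
#' @param seed Master seed; per-replicate seeds are derived
#'   deterministically from it.
#' @param level Decision confidence level (5% two-sided test by default).
#' @param keep_decisions Attach the per-replicate decision table as
#'   attribute `"decisions"` (needed for paired method comparisons).
#' @param ... Passed to [analyze_trial()].
#' @return Tibble with one row per method: `method`, `n_total`,
#'   `n_replicates`, `n_significant`, `n_failed`, `power`, `ci_low`,
#'   `ci_high`, `seed`.
#' @export
estimate_power <- function(design, methods = "irt", n_replicates = 100,
                           seed = 1, level = 0.95, keep_decisions = FALSE,
                           ...) {
  check_that(n_replicates >= 1, "`n_replicates` must be >= 1")
  seeds <- derive_seeds(seed, n_replicates, "trial-replicates")
  decs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- design
    d$seed <- seeds[r]
    trial <- simulate_trial(d)
    decs[[r]] <- analyze_trial(trial, methods, level = level, ...) |>
      mutate(replicate = r)
  }
  decisions <- bind_rows(decs)
  out <- decisions |>
    group_by(.data$method) |>
    summarise(n_replicates = dplyr::n(),
              n_significant = sum(.data$significant, na.rm = TRUE),
              n_failed = sum(is.na(.data$significant)),
              .groups = "drop") |>
    mutate(n_total = design$n_total,
           power = .data$n_significant / .data$n_replicates,
           ci_low = purrr::map2_dbl(.data$n_significant, .data$n_replicates,
                                    ~ wilson_ci(.x, .y)[1]),
           ci_high = purrr::map2_dbl(.data$n_significant, .data$n_replicates,
                                     ~ wilson_ci(.x, .y)[2]),
           seed = seed) |>
    select("method", "n_total", "n_replicates", "n_significant", "n_failed",
           "power", "ci_low", "ci_high", "seed")
  if (keep_decisions) attr(out, "decisions") <- decisions
  out
}

#' Estimate the type I error under the null
#'
#' As [estimate_power()] but with the drug effect forced to zero in the
#' generating model, so the rejection fraction estimates the type I error
#' of each analysis method.
#'
#' @inheritParams estimate_power
#' @return As [estimate_power()].
#' @export
estimate_type1 <- function(design, methods = "irt", n_replicates = 100,
                           seed = 1, level = 0.95, keep_decisions = FALSE,
                           ...) {
  design$params$beta_drug <- 0
  estimate_power(design, methods, n_replicates, seed, level,
                 keep_decisions, ...)
}

#' Subjects needed to reach a target power
#'
#' Isotonic regression of power against sample size (to iron out
#' Monte-Carlo jitter) followed by linear interpolation at the target.
#'
#' @param power_curve Tibble with columns `n_total` and `power` (one
#'   method), e.g. rows of [estimate_power()] over a grid of sizes.
#' @param target Target power (default 0.8).
#' @return Interpolated number of subjects `n*`.
#' @export
subjects_for_power <- function(power_curve, target = 0.8) {
  check_that(nrow(power_curve) >= 2, "need at least two grid points")
  pc <- arrange(power_curve, .data$n_total)
  iso <- isoreg(pc$n_total, pc$power)
  p <- iso$yf
  if (target < min(p) - 1e-12 || target > max(p) + 1e-12)
    abort(paste0("target ", target, " outside observed power range [",
                 round(min(p), 3), ", ", round(max(p), 3), "]"))
  ## linear interpolation after isotonic smoothing; tie groups resolve to
  ## their largest sample size (conservative)
  target <- min(max(target, min(p)), max(p)) # guard one-ulp isoreg drift
  approx(p, pc$n_total, xout = target, ties = max)$y
}
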