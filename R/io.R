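## Readers/writers and the pipeline runner binding the modules together.
## Tabular data travel as CSV; item banks and run configurations as YAML.

#' Read long-format responses from CSV
#'
#' Expected columns: `subject_id`, `study_id`, `time_months`, `arm`,
#' `item_id`, `value`. When a bank is supplied, every row is validated
#' against the item's support and offending data lines are reported
#' (header = line 1).
#'
#' @param path CSV file path.
#' @param bank Optional [item_bank()] for validation.
#' @return Response tibble.
#' @export
read_responses <- function(path, bank = NULL) {
  check_that(file.exists(path), paste0("no such file: ", path))
  check_that(file.size(path) > 0, paste0("empty file: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           study_id = readr::col_character(),
                           item_id = readr::col_character(),
                           time_months = readr::col_double(),
                           arm = readr::col_character(),
                           value = readr::col_integer(),
                           .default = readr::col_guess()))
  check_that(nrow(out) > 0, paste0("no data rows in ", path))
  if (!is.null(bank))
    validate_responses(out, bank, file_lines = seq_len(nrow(out)) + 1L)
  out
}

#' Write responses to CSV
#' @param responses Response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

#' Write an item bank to YAML
#'
#' One entry per item with its family and named parameters, plus the
#' `study_variants` and `score_map` blocks.
#'
#' @param bank An [item_bank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  items <- purrr::map(seq_len(nrow(bank$items)), function(j) {
    row <- as.list(bank$items[j, ])
    row$thresholds <- row$thresholds[[1]]
    keep <- !vapply(row, function(v) is.null(v) ||
                      (length(v) == 1 && is.na(v)), TRUE)
    row[keep]
  })
  yaml::write_yaml(list(items = items,
                        study_variants = bank$study_variants,
                        score_map = bank$score_map), path)
  invisible(path)
}

#' Read an item bank from YAML
#'
#' @param path YAML file written by [write_item_bank()] (or hand-edited
#'   in the same structure).
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  check_that(file.exists(path), paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  check_that(!is.null(raw$items), "item bank file has no `items` block")
  items <- purrr::map_dfr(raw$items, function(it) {
    do.call(item_spec, it[names(it) %in%
                            c("item_id", "component", "family", "a", "b",
                              "c", "d", "delta", "n_words", "max_count",
                              "n_categories", "thresholds")])
  })
  sv <- purrr::map(raw$study_variants %||% list(), unlist)
  sm <- raw$score_map
  if (!is.null(sm)) {
    sm$components <- purrr::map(sm$components, function(z) {
      if (!is.null(z$bins)) z$bins <- unlist(z$bins)
      z
    })
  }
  item_bank(items, study_variants = sv, score_map = sm)
}

#' Validate a user-supplied external item-estimate file
#'
#' Published item estimates for the full assessment (from a supplementary
#' source outside this package) can be dropped in as an item-bank YAML to
#' re-rank components or drive simulations with those values. This gated
#' checker validates such a file and errors informatively when it is
#' absent, so downstream comparisons only run when the external estimates
#' are genuinely available.
#'
#' @param path Path to the external item-bank YAML.
#' @return The validated [item_bank()].
#' @export
check_external_estimates <- function(path) {
  if (!file.exists(path))
    abort(paste0("external item-estimate file not found: ", path,
                 "\nThese estimates are not bundled (they are not ",
                 "redistributable); supply them as an item-bank YAML."),
          class = "cogirt_external_data_error")
  bank <- read_item_bank(path)
  check_that(length(unique(bank$items$component)) >= 2,
             "external estimates must cover at least two components")
  bank
}

#' Run a configured pipeline stage
#'
#' Executes one stage (`simulate`, `fit_baseline`, `fit_longitudinal`,
#' `information`, `analyze`, `evaluate_power`, `vpc`) from a configuration
#' list or YAML file, writes its artifacts into `outdir` and a
#' `manifest.json` recording inputs, settings, seed, package version and
#' output hashes. Existing outputs are not overwritten unless
#' `overwrite: true`.
#'
#' @param config Named list or path to a YAML file. Required fields
#'   depend on the command; common fields: `command`, `outdir`, `seed`,
#'   `bank` (path or "default"/"reduced"), `overwrite`.
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_that(!is.null(config$command), "config needs a `command`")
  check_that(!is.null(config$outdir), "config needs an `outdir`")
  cmd <- config$command
  outdir <- config$outdir
  seed <- config$seed %||% 1L
  bank <- resolve_bank(config$bank)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(obj, name) {
    p <- file.path(outdir, name)
    if (file.exists(p) && !isTRUE(config$overwrite))
      abort(paste0("output exists (use overwrite: true): ", p))
    if (is.data.frame(obj)) readr::write_csv(obj, p)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    artifacts <<- c(artifacts, p)
    p
  }
  if (cmd == "simulate") {
    params <- do.call(progression_params, config$params)
    design <- trial_design(config$n_total, params, bank,
                           schedule_months = unlist(config$schedule_months %||%
                                                      c(0, 3, 6, 9, 12, 15, 18)),
                           seed = seed)
    trial <- simulate_trial(design)
    emit(trial$responses, "responses.csv")
    emit(trial$truth, "truth.csv")
    emit(trial$dropout, "dropout.csv")
  } else if (cmd == "fit_baseline") {
    data <- read_responses(config$responses, bank)
    fit <- fit_baseline(data, bank)
    emit(tidy(fit), "item_estimates.csv")
    emit(glance(fit), "fit_summary.csv")
  } else if (cmd == "fit_longitudinal") {
    data <- read_responses(config$responses, bank)
    dropout <- if (!is.null(config$dropout))
      readr::read_csv(config$dropout, show_col_types = FALSE) else NULL
    fit <- fit_longitudinal(data, bank, hazard = config$hazard,
                            dropout = dropout,
                            drug_effect = isTRUE(config$drug_effect))
    emit(tidy(fit), "estimates.csv")
    emit(fit$ebe, "subject_trajectories.csv")
  } else if (cmd == "information") {
    pop <- population_spec(config$population$label %||% "population",
                           config$population$mean, config$population$sd)
    emit(rank_components(bank, pop), "component_ranking.csv")
    emit(information_curve(bank), "information_curves.csv")
  } else if (cmd == "analyze") {
    totals <- readr::read_csv(config$totals, show_col_types = FALSE)
    dec <- if (config$method == "ls_means") ls_means_analysis(totals)
    else fit_total_score_model(totals)
    emit(dec, "decision.csv")
  } else if (cmd == "evaluate_power") {
    params <- do.call(progression_params, config$params)
    res <- purrr::map_dfr(unlist(config$n_grid), function(n) {
      design <- trial_design(n, params, bank)
      f <- if (isTRUE(config$null)) estimate_type1 else estimate_power
      f(design, methods = unlist(config$methods %||% "irt"),
        n_replicates = config$n_replicates %||% 100, seed = seed)
    })
    emit(res, "power.csv")
  } else if (cmd == "vpc") {
    data <- read_responses(config$responses, bank)
    params <- do.call(progression_params, config$params)
    design <- trial_design(config$n_total %||%
                             length(unique(data$subject_id)), params, bank,
                           schedule_months = sort(unique(data$time_months)))
    res <- vpc(list(responses = data), bank, params, design = design,
               level = config$level %||% "total",
               n_replicates = config$n_replicates %||% 200, seed = seed)
    emit(as_tibble(res), "vpc.csv")
  } else abort(paste0("unknown command: ", cmd))
  manifest <- list(command = cmd, seed = seed,
                   package_version = as.character(utils::packageVersion("cogirt")),
                   settings = config,
                   artifacts = as.list(setNames(
                     unname(tools::md5sum(artifacts)), basename(artifacts))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

resolve_bank <- function(bank) {
  if (is.null(bank) || identical(bank, "default")) return(default_item_bank())
  if (identical(bank, "reduced")) return(reduced_item_bank())
  if (is.character(bank)) return(read_item_bank(bank))
  bank
}
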