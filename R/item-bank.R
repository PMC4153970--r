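#' Define a single assessment item
#'
#' Constructs the specification of one assessment item: the response-model
#' family linking the outcome to latent cognitive disability, and its
#' parameters. Returned as a one-row tibble so that banks are ordinary
#' tabular data.
#'
#' Families and their required parameters:
#' \describe{
#'   \item{`binary3pl`}{pass/fail task; discrimination `a`, difficulty `b`,
#'     lower asymptote `c` (failure probability of an unimpaired subject).}
#'   \item{`binomial_words`}{word-list test; error count out of `n_words`
#'     with per-word failure probability from the 3PL curve (`a`, `b`, `c`).
#'     `max_count` optionally truncates the stored count.}
#'   \item{`word_recognition`}{like `binomial_words` but with an upper
#'     asymptote `d` on the per-word failure probability (`c < d <= 1`).}
#'   \item{`gen_poisson_count`}{number-cancellation points 0..`max_count`
#'     (default 40); generalized Poisson with mean curve
#'     `d * (1 - logistic(a (D - b)))` and dispersion `delta`.}
#'   \item{`ordered_categorical`}{rater item with `n_categories` ordered
#'     categories; proportional-odds with common slope `a` and
#'     non-decreasing `thresholds` (length `n_categories - 1`).}
#' }
#'
#' @param item_id Unique item identifier.
#' @param component Assessment component the item belongs to
#'   (e.g. "orientation", "word_recall").
#' @param family One of the five families above.
#' @param a Discrimination (> 0).
#' @param b Difficulty, on the latent scale. For `ordered_categorical`
#'   use `thresholds` instead.
#' @param c Lower asymptote probability in `[0, 1)` where applicable.
#' @param d Upper asymptote: probability in `(c, 1]` for
#'   `word_recognition`; maximum count mean (> 0) for `gen_poisson_count`.
#' @param delta Generalized-Poisson dispersion (gen_poisson_count only).
#' @param n_words Number of words for the binomial families.
#' @param max_count Support bound: truncation point for truncated binomial
#'   variants; support maximum (default 40) for `gen_poisson_count`.
#' @param n_categories Number of ordered categories (default 5).
#' @param thresholds Non-decreasing numeric vector of per-threshold
#'   difficulties for `ordered_categorical`.
#' @return One-row tibble with a list-column `thresholds`.
#' @export
#' @examples
#' item_spec("orient_year", "orientation", "binary3pl", a = 1.4, b = 0.3, c = 0.02)
item_spec <- function(item_id, component, family,
                      a, b = NA_real_, c = NA_real_, d = NA_real_,
                      delta = NA_real_, n_words = NA_integer_,
                      max_count = NA_integer_, n_categories = NA_integer_,
                      thresholds = NULL) {
  family <- match.arg(family, item_families())
  check_that(is.finite(a) && a > 0, "`a` must be a positive number")
  if (family == "ordered_categorical") {
    if (is.na(n_categories)) n_categories <- length(thresholds) + 1L
    check_that(!is.null(thresholds) &&
                 length(thresholds) == n_categories - 1L,
               "ordered_categorical needs `thresholds` of length n_categories - 1")
    check_that(!is.unsorted(thresholds),
               "`thresholds` must be non-decreasing")
    b <- NA_real_
  } else {
    check_that(is.finite(b), "`b` (difficulty) is required")
    thresholds <- NULL
  }
  if (family %in% c("binary3pl", "binomial_words", "word_recognition")) {
    if (is.na(c)) c <- 0
    check_that(c >= 0 && c < 1, "`c` must lie in [0, 1)")
  }
  if (family == "word_recognition") {
    check_that(is.finite(d) && d > c && d <= 1,
               "`d` must lie in (c, 1] for word_recognition")
  }
  if (family == "gen_poisson_count") {
    check_that(is.finite(d) && d > 0, "`d` (maximum count mean) must be > 0")
    if (is.na(delta)) delta <- 0
    if (is.na(max_count)) max_count <- 40L
    check_that(gp_delta_valid(d, delta, max_count),
               "`delta` makes the generalized-Poisson pmf invalid on its support")
  }
  if (family %in% c("binomial_words", "word_recognition")) {
    check_that(is.finite(n_words) && n_words >= 1, "`n_words` must be >= 1")
    if (!is.na(max_count))
      check_that(max_count >= 1, "`max_count` must be >= 1")
  }
  tibble(
    item_id = as.character(item_id), component = as.character(component),
    family = family, a = a, b = b, c = c, d = d, delta = delta,
    n_words = as.integer(n_words), max_count = as.integer(max_count),
    n_categories = as.integer(n_categories),
    thresholds = list(thresholds)
  )
}

item_families <- function() {
  c("binary3pl", "binomial_words", "word_recognition",
    "gen_poisson_count", "ordered_categorical")
}

## delta validity: p(D) + delta * k > 0 for all k <= max_count over D in
## [-6, 6]; with p > 0 everywhere this only bites for delta < 0.
gp_delta_valid <- function(d, delta, max_count) {
  if (delta >= 0) return(delta < 1)
  p_min <- d * (1 - logistic(6 * 6)) # worst case over a(D-b) grid is ~0
  ## conservative: require positivity even at negligible mean
  p_min > -delta * max_count
}

#' Assemble an item bank
#'
#' An item bank bundles the item specifications with per-study variant
#' masks (which items a given study administered) and the score map used
#' to roll item outcomes up to component and total assessment scores.
#'
#' @param items Tibble of item specifications, usually `dplyr::bind_rows()`
#'   of [item_spec()] calls.
#' @param study_variants Named list: study id -> character vector of
#'   administered item ids. Empty list means every study uses all items.
#' @param score_map Score map as produced by [default_score_map()]; built
#'   automatically from `items` when `NULL`.
#' @return Object of class `item_bank`.
#' @export
item_bank <- function(items, study_variants = list(), score_map = NULL) {
  check_that(nrow(items) >= 1, "an item bank needs at least one item")
  check_that(!anyDuplicated(items$item_id), "item_ids must be unique")
  for (sv in names(study_variants)) {
    bad <- setdiff(study_variants[[sv]], items$item_id)
    check_that(length(bad) == 0,
               paste0("study variant '", sv, "' references unknown items: ",
                      paste(bad, collapse = ", ")))
  }
  if (is.null(score_map)) score_map <- default_score_map(items)
  miss <- setdiff(unique(items$component), names(score_map$components))
  check_that(length(miss) == 0,
             paste0("score_map misses components: ", paste(miss, collapse = ", ")))
  structure(list(items = items, study_variants = study_variants,
                 score_map = score_map),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("<item_bank> ", nrow(x$items), " items, ",
      length(unique(x$items$component)), " components, ",
      length(x$study_variants), " study variants\n", sep = "")
  print(count(x$items, .data$component, .data$family))
  invisible(x)
}

#' Extract one item from a bank
#'
#' @param bank An [item_bank()].
#' @param item_id Item identifier.
#' @return One-row item tibble.
#' @export
bank_item <- function(bank, item_id) {
  i <- match(item_id, bank$items$item_id)
  check_that(!is.na(i), paste0("unknown item_id: ", item_id))
  bank$items[i, ]
}

#' Item ids administered by a study
#'
#' Falls back to the full bank when the study has no recorded variant.
#'
#' @inheritParams bank_item
#' @param study_id Study identifier.
#' @return Character vector of item ids.
#' @export
study_items <- function(bank, study_id) {
  if (study_id %in% names(bank$study_variants))
    bank$study_variants[[study_id]]
  else bank$items$item_id
}

#' Default component score map
#'
#' The total-score arithmetic is configuration, not code: each component
#' maps its item outcomes to a component score via a named method, and the
#' total is the sum of component scores. Methods: `failures` (sum of binary
#' failures), `mean_errors_rounded` (mean error count over the component's
#' word-list trials, rounded half up), `errors` (error count),
#' `category` (rater category), `binned_points` (count outcome mapped
#' through decreasing point bins, e.g. number cancellation).
#'
#' @param items Item tibble.
#' @param nc_bins For `binned_points`: lower bin edges of achieved points,
#'   decreasing; the score is the index of the first edge the points reach,
#'   minus one (fewer points -> higher score).
#' @param missing One of "prorate" (default) or "na": what to do when a
#'   component's items are partially missing at a visit.
#' @return List with `components`, `missing`, `total_max`.
#' @export
default_score_map <- function(items, nc_bins = c(30, 25, 20, 15, 10, -1),
                              missing = c("prorate", "na")) {
  missing <- match.arg(missing)
  comps <- list()
  for (comp in unique(items$component)) {
    sub <- items[items$component == comp, ]
    fam <- sub$family[1]
    comps[[comp]] <- switch(
      fam,
      binary3pl = list(method = "failures", max = nrow(sub)),
      binomial_words =
        if (nrow(sub) > 1)
          list(method = "mean_errors_rounded",
               max = max(sub$n_words))
        else list(method = "errors",
                  max = min(sub$n_words, sub$max_count, na.rm = TRUE)),
      word_recognition = list(
        method = "errors",
        max = min(sub$n_words[1], sub$max_count[1], na.rm = TRUE)),
      gen_poisson_count = list(method = "binned_points", bins = nc_bins,
                               max = length(nc_bins) - 1),
      ordered_categorical = list(method = "category",
                                 max = sub$n_categories[1] - 1)
    )
  }
  list(components = comps, missing = missing,
       total_max = sum(vapply(comps, function(z) z$max, 0)))
}
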