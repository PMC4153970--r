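## Internal: flatten responses + bank into the flat arrays the compiled
## kernels consume. Family codes: 1 binomial/Bernoulli, 2 generalized
## Poisson, 3 ordered categorical.

fam_code <- function(family) {
  c(binary3pl = 1L, binomial_words = 1L, word_recognition = 1L,
    gen_poisson_count = 2L, ordered_categorical = 3L)[family]
}

## per-item parameter arrays (one row per item, in bank order)
item_arrays <- function(items) {
  J <- nrow(items)
  fam <- unname(fam_code(items$family))
  a <- items$a
  b <- ifelse(is.na(items$b), 0, items$b)
  cc <- ifelse(is.na(items$c), 0, items$c)
  d <- dplyr::case_when(
    items$family == "word_recognition" ~ items$d,
    items$family == "gen_poisson_count" ~ items$d,
    TRUE ~ 1
  )
  delta <- ifelse(is.na(items$delta), 0, items$delta)
  n <- ifelse(items$family == "binary3pl", 1L,
              ifelse(is.na(items$n_words), 0L, items$n_words))
  m <- ifelse(is.na(items$max_count), 0L, items$max_count)
  ncat <- ifelse(is.na(items$n_categories), 0L, items$n_categories)
  maxth <- max(c(1L, ncat - 1L))
  th <- matrix(0, J, maxth)
  for (j in seq_len(J)) {
    tj <- items$thresholds[[j]]
    if (!is.null(tj)) th[j, seq_along(tj)] <- tj
  }
  sup <- integer(J)
  for (j in seq_len(J)) {
    sup[j] <- switch(items$family[j],
                     binary3pl = 1L,
                     binomial_words = ,
                     word_recognition = min(n[j], if (m[j] > 0) m[j] else n[j]),
                     gen_poisson_count = m[j],
                     ordered_categorical = ncat[j] - 1L)
  }
  list(fam = as.integer(fam), a = a, b = b, c = cc, d = d, delta = delta,
       n = as.integer(n), m = as.integer(m), ncat = as.integer(ncat),
       th = th, sup = sup)
}

## flat per-observation arrays, sorted by subject (and time within subject)
obs_arrays <- function(responses, bank) {
  items <- bank$items
  idx <- match(responses$item_id, items$item_id)
  check_that(!anyNA(idx),
             paste0("unknown item_id(s): ",
                    paste(unique(responses$item_id[is.na(idx)]), collapse = ", ")))
  has_time <- "time_months" %in% names(responses)
  ord <- if (has_time) order(responses$subject_id, responses$time_months)
         else order(responses$subject_id)
  responses <- responses[ord, ]
  idx <- idx[ord]
  ia <- item_arrays(items)
  J <- nrow(items)
  subj <- unique(responses$subject_id)
  si <- match(responses$subject_id, subj)
  off <- c(0L, cumsum(tabulate(si, nbins = length(subj))))
  n_o <- ia$n[idx]
  y <- as.integer(responses$value)
  lch <- ifelse(ia$fam[idx] == 1L, lchoose(n_o, y), 0)
  list(off = as.integer(off), subjects = subj,
       y = y, fam = ia$fam[idx], a = ia$a[idx], b = ia$b[idx], c = ia$c[idx],
       d = ia$d[idx], delta = ia$delta[idx], n = as.integer(n_o),
       m = as.integer(ia$m[idx]), lch = as.numeric(lch),
       th = ia$th[idx, , drop = FALSE], ncat = as.integer(ia$ncat[idx]),
       t_years = if (has_time) responses$time_months / 12 else rep(0, length(y)),
       responses = responses, item_idx = idx)
}

## response validation with row provenance (line = data row index)
validate_responses <- function(responses, bank, file_lines = NULL) {
  req <- c("subject_id", "item_id", "value")
  miss <- setdiff(req, names(responses))
  check_that(length(miss) == 0,
             paste0("responses lack required column(s): ",
                    paste(miss, collapse = ", ")))
  items <- bank$items
  idx <- match(responses$item_id, items$item_id)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    lines <- if (is.null(file_lines)) bad else file_lines[bad]
    abort(paste0("unknown item_id at line(s) ",
                 paste(head(lines, 10), collapse = ", "), ": ",
                 paste(unique(responses$item_id[bad]), collapse = ", ")),
          class = "cogirt_validation_error")
  }
  ia <- item_arrays(items)
  sup <- ia$sup[idx]
  v <- responses$value
  bad <- which(!is.finite(v) | v < 0 | v > sup | v != floor(v))
  if (length(bad) > 0) {
    lines <- if (is.null(file_lines)) bad else file_lines[bad]
    abort(paste0("response value outside item support at line(s) ",
                 paste(head(lines, 10), collapse = ", ")),
          class = "cogirt_validation_error")
  }
  invisible(responses)
}
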