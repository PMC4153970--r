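## Marginal-likelihood machinery for the cross-sectional (baseline) model:
## latent cognitive disability D ~ N(0, 1), item responses conditionally
## independent given D.

#' Per-subject marginal log-likelihood at baseline
#'
#' Approximates `log integral prod_j P(Y_ij | D) phi(D) dD` for each
#' subject by the Laplace approximation or adaptive Gauss-Hermite
#' quadrature centred at the posterior mode.
#'
#' @param records Response data frame (columns `subject_id`, `item_id`,
#'   `value`, optionally more).
#' @param bank An [item_bank()] supplying item parameters.
#' @param method `"agh"` (adaptive Gauss-Hermite, default) or `"laplace"`.
#' @param nodes Number of quadrature nodes per dimension (AGH only).
#' @return Tibble with `subject_id` and `loglik`; the total marginal
#'   log-likelihood is `sum(loglik)`.
#' @export
marginal_loglik <- function(records, bank, method = c("agh", "laplace"),
                            nodes = 7) {
  method <- match.arg(method)
  check_that(nrow(records) > 0, "no records supplied")
  check_that(nodes >= 1, "`nodes` must be >= 1")
  validate_responses(records, bank)
  oa <- obs_arrays(records, bank)
  gh <- gauss_hermite(nodes)
  res <- cpp_baseline_marginal(oa$off, oa$y, oa$fam, oa$a, oa$b, oa$c, oa$d,
                               oa$delta, oa$n, oa$m, oa$lch, oa$th, oa$ncat,
                               if (method == "laplace") 0L else 1L,
                               gh$nodes, gh$weights,
                               numeric(length(oa$subjects)))
  if (any(!is.finite(res$subject)))
    abort(paste0("non-finite marginal likelihood for subject(s): ",
                 paste(head(oa$subjects[!is.finite(res$subject)], 5),
                       collapse = ", ")))
  tibble(subject_id = oa$subjects, loglik = as.numeric(res$subject))
}

#' Empirical Bayes estimates of latent disability
#'
#' Posterior mode of D for each subject given its responses and the item
#' parameters, with a curvature-based uncertainty (inverse square root of
#' the negative posterior curvature at the mode).
#'
#' @inheritParams marginal_loglik
#' @param subjects Optional vector of subject ids to report; subjects
#'   without records get the prior (`d_hat = 0`, `d_sd = 1`) with a warning.
#' @return Tibble with `subject_id`, `d_hat`, `d_sd`, `n_items`.
#' @export
estimate_ebe <- function(records, bank, subjects = NULL) {
  validate_responses(records, bank)
  oa <- obs_arrays(records, bank)
  eb <- cpp_ebe(oa$off, oa$y, oa$fam, oa$a, oa$b, oa$c, oa$d, oa$delta,
                oa$n, oa$m, oa$lch, oa$th, oa$ncat)
  out <- tibble(subject_id = oa$subjects, d_hat = as.numeric(eb[, 1]),
                d_sd = as.numeric(eb[, 2]), n_items = diff(oa$off))
  if (!is.null(subjects)) {
    extra <- setdiff(subjects, out$subject_id)
    if (length(extra) > 0) {
      warn(paste0(length(extra),
                  " subject(s) without records: returning the prior"))
      out <- bind_rows(out, tibble(subject_id = extra, d_hat = 0, d_sd = 1,
                                   n_items = 0L))
      out <- out[match(subjects, out$subject_id), ]
    }
  }
  out
}

## ---- parameter packing for joint item estimation -------------------------

## one entry per scalar free parameter: item row, field, transform
pack_items <- function(items, estimable, fix_fields = character()) {
  par0 <- numeric(0)
  add <- function(label, value) {
    par0[[label]] <<- value
  }
  for (j in seq_len(nrow(items))) {
    if (!estimable[j]) next
    id <- items$item_id[j]
    fam <- items$family[j]
    if (!"a" %in% fix_fields) add(paste0(id, "..loga"), log(items$a[j]))
    if (fam == "ordered_categorical") {
      if (!"thresholds" %in% fix_fields) {
        th <- items$thresholds[[j]]
        add(paste0(id, "..th1"), th[1])
        if (length(th) > 1)
          for (k in 2:length(th))
            add(paste0(id, "..loginc", k), log(max(th[k] - th[k - 1], 1e-3)))
      }
    } else if (!"b" %in% fix_fields) {
      add(paste0(id, "..b"), items$b[j])
    }
    if (fam %in% c("binary3pl", "binomial_words", "word_recognition") &&
        !"c" %in% fix_fields)
      add(paste0(id, "..zc"), qlogis(pmin(pmax(items$c[j], 1e-4), 0.999)))
    if (fam == "word_recognition" && !"d" %in% fix_fields) {
      zd <- (items$d[j] - items$c[j]) / (1 - items$c[j])
      add(paste0(id, "..zd"), qlogis(pmin(pmax(zd, 1e-4), 0.9999)))
    }
    if (fam == "gen_poisson_count") {
      if (!"d" %in% fix_fields) add(paste0(id, "..logd"), log(items$d[j]))
      if (!"delta" %in% fix_fields)
        add(paste0(id, "..zdelta"),
            qlogis(pmin(pmax(items$delta[j] / 0.95, 1e-4), 0.9999)))
    }
  }
  par0
}

unpack_items <- function(par, items, estimable) {
  nm <- names(par)
  getp <- function(label) if (label %in% nm) par[[label]] else NULL
  for (j in seq_len(nrow(items))) {
    if (!estimable[j]) next
    id <- items$item_id[j]
    fam <- items$family[j]
    v <- getp(paste0(id, "..loga"))
    if (!is.null(v)) items$a[j] <- exp(v)
    if (fam == "ordered_categorical") {
      v <- getp(paste0(id, "..th1"))
      if (!is.null(v)) {
        th <- items$thresholds[[j]]
        nt <- length(th)
        th[1] <- v
        if (nt > 1)
          for (k in 2:nt)
            th[k] <- th[k - 1] + exp(par[[paste0(id, "..loginc", k)]])
        items$thresholds[[j]] <- th
      }
    } else {
      v <- getp(paste0(id, "..b"))
      if (!is.null(v)) items$b[j] <- v
    }
    v <- getp(paste0(id, "..zc"))
    if (!is.null(v)) items$c[j] <- plogis(v)
    v <- getp(paste0(id, "..zd"))
    if (!is.null(v)) items$d[j] <- items$c[j] +
        (1 - items$c[j]) * plogis(v)
    v <- getp(paste0(id, "..logd"))
    if (!is.null(v)) items$d[j] <- exp(v)
    v <- getp(paste0(id, "..zdelta"))
    if (!is.null(v)) items$delta[j] <- 0.95 * plogis(v)
  }
  items
}

## chain rule from natural-parameter gradients (slots per item: see
## cpp_mml_nll_grad) to the transformed free-parameter vector
mml_chain_rule <- function(gnat, items, estimable, par_names) {
  g <- setNames(numeric(length(par_names)), par_names)
  for (j in seq_len(nrow(items))) {
    if (!estimable[j]) next
    id <- items$item_id[j]
    fam <- items$family[j]
    g[[paste0(id, "..loga")]] <- gnat[j, 1] * items$a[j]
    if (fam %in% c("binary3pl", "binomial_words", "word_recognition")) {
      g[[paste0(id, "..b")]] <- gnat[j, 2]
      cc <- items$c[j]
      if (fam == "word_recognition") {
        sd_ <- (items$d[j] - cc) / (1 - cc)
        g[[paste0(id, "..zc")]] <- (gnat[j, 3] + gnat[j, 4] * (1 - sd_)) *
          cc * (1 - cc)
        g[[paste0(id, "..zd")]] <- gnat[j, 4] * (1 - cc) * sd_ * (1 - sd_)
      } else {
        g[[paste0(id, "..zc")]] <- gnat[j, 3] * cc * (1 - cc)
      }
    } else if (fam == "gen_poisson_count") {
      g[[paste0(id, "..b")]] <- gnat[j, 2]
      g[[paste0(id, "..logd")]] <- gnat[j, 3] * items$d[j]
      sdel <- items$delta[j] / 0.95
      g[[paste0(id, "..zdelta")]] <- gnat[j, 4] * 0.95 * sdel * (1 - sdel)
    } else { # ordered: slots 2..K are th1..th(K-1)
      th <- items$thresholds[[j]]
      nt <- length(th)
      gth <- gnat[j, 1 + seq_len(nt)]
      g[[paste0(id, "..th1")]] <- sum(gth)
      if (nt > 1)
        for (k in 2:nt)
          g[[paste0(id, "..loginc", k)]] <-
            (th[k] - th[k - 1]) * sum(gth[k:nt])
    }
  }
  g[par_names]
}

## default starting values (overridable via `start`)
start_items <- function(items) {
  for (j in seq_len(nrow(items))) {
    fam <- items$family[j]
    items$a[j] <- 1
    if (fam == "ordered_categorical") {
      nt <- length(items$thresholds[[j]])
      items$thresholds[[j]] <- seq(-1, 2, length.out = nt)
    } else items$b[j] <- 0
    if (fam %in% c("binary3pl", "binomial_words", "word_recognition"))
      items$c[j] <- 0.05
    if (fam == "word_recognition") items$d[j] <- 0.95
    if (fam == "gen_poisson_count") { items$d[j] <- 30; items$delta[j] <- 0.02 }
  }
  items
}

#' Fit the baseline IRT model by marginal maximum likelihood
#'
#' Jointly estimates the item parameters of every estimable item with the
#' latent cognitive disability fixed to a standard normal (which sets the
#' location and scale of the latent trait). Multi-study data are pooled
#' with one shared parameter set; items a study did not administer are
#' simply absent from its subjects' likelihoods (missing by design).
#'
#' @param data Long-format responses (`subject_id`, `item_id`, `value`,
#'   optionally `study_id`, `time_months`, `arm`).
#' @param bank An [item_bank()] defining the items. Its parameter values
#'   are ignored unless `start = "bank"`.
#' @param method `"ghq"` (fixed-node Gauss-Hermite marginal, default),
#'   `"agh"` (adaptive Gauss-Hermite) or `"laplace"`.
#' @param nodes Quadrature nodes: 61 for `"ghq"`, 7 for `"agh"` by default.
#' @param start `"default"` for neutral starting values (a = 1, b = 0,
#'   c = 0.05, ...), `"bank"` to start at the bank's values.
#' @param fix_fields Character vector of item-parameter fields (e.g.
#'   `"c"`, `"delta"`) to hold at their starting values instead of
#'   estimating them (applies to every item).
#' @param min_subjects Items answered by fewer subjects are held at their
#'   starting values (named warning).
#' @param se Compute standard errors from the observed information
#'   (numerically differentiated Hessian); skipped with a warning when the
#'   Hessian is not positive definite.
#' @param control Passed to [stats::nlminb()].
#' @return A `cogirt_fit` of type `"baseline"`: the fitted bank, estimate
#'   vector, marginal log-likelihood, convergence flag, settings snapshot.
#' @export
fit_baseline <- function(data, bank, method = c("ghq", "agh", "laplace"),
                         nodes = NULL, start = c("default", "bank"),
                         fix_fields = character(), min_subjects = 10,
                         se = FALSE, control = list()) {
  method <- match.arg(method)
  start <- match.arg(start)
  if (is.null(nodes)) nodes <- if (method == "ghq") 61 else 7
  validate_responses(data, bank)
  items <- bank$items
  ## identify estimable items
  counts <- table(factor(data$item_id, levels = items$item_id))
  estimable <- as.integer(counts) >= min_subjects
  degenerate <- vapply(seq_len(nrow(items)), function(j) {
    if (items$family[j] != "binary3pl") return(FALSE)
    v <- data$value[data$item_id == items$item_id[j]]
    length(v) > 0 && (all(v == 0) || all(v == 1))
  }, TRUE)
  if (any(!estimable | degenerate)) {
    held <- items$item_id[!estimable | degenerate]
    warn(paste0("items held at starting values (too few or degenerate ",
                "responses): ", paste(held, collapse = ", ")),
         class = "cogirt_identifiability_warning")
  }
  estimable <- estimable & !degenerate
  check_that(any(estimable), "no estimable items")
  items0 <- if (start == "default") start_items(items) else items
  par0 <- pack_items(items0, estimable, fix_fields)
  oa <- obs_arrays(data, bank)
  n_subj <- length(oa$subjects)
  grf <- NULL
  if (method == "ghq") {
    nq <- normal_quadrature(nodes)
    cache <- new.env(parent = emptyenv())
    cache$par <- NULL
    ensure <- function(par) {
      if (!identical(cache$par, par)) {
        it <- unpack_items(par, items0, estimable)
        ia <- item_arrays(it)
        res <- cpp_mml_nll_grad(oa$off, as.integer(oa$item_idx - 1L), oa$y,
                                ia$fam, ia$a, ia$b, ia$c, ia$d, ia$delta,
                                ia$n, ia$m, ia$th, ia$ncat,
                                as.integer(ia$sup), nq$nodes, nq$weights)
        cache$par <- par
        cache$nll <- res$nll
        cache$grad <- mml_chain_rule(res$grad, it, estimable, names(par))
      }
      invisible(NULL)
    }
    obj <- function(par) { ensure(par); cache$nll }
    grf <- function(par) { ensure(par); cache$grad }
  } else {
    gh <- gauss_hermite(nodes)
    d_ws <- numeric(n_subj)
    obj <- function(par) {
      it <- unpack_items(par, items0, estimable)
      ia <- item_arrays(it)
      -cpp_baseline_marginal(oa$off, oa$y, ia$fam[oa$item_idx],
                             ia$a[oa$item_idx], ia$b[oa$item_idx],
                             ia$c[oa$item_idx], ia$d[oa$item_idx],
                             ia$delta[oa$item_idx], ia$n[oa$item_idx],
                             ia$m[oa$item_idx], oa$lch,
                             ia$th[oa$item_idx, , drop = FALSE],
                             ia$ncat[oa$item_idx],
                             if (method == "laplace") 0L else 1L,
                             gh$nodes, gh$weights, d_ws)$loglik
    }
  }
  ctl <- modifyList(list(iter.max = 1000, eval.max = 4000, rel.tol = 1e-9),
                    control)
  opt <- nlminb(par0, obj, gradient = grf, control = ctl)
  fitted_items <- unpack_items(opt$par, items0, estimable)
  fitted_bank <- item_bank(fitted_items, bank$study_variants, bank$score_map)
  ses <- NULL
  if (se) {
    H <- try(optimHess(opt$par, obj), silent = TRUE)
    ok <- !inherits(H, "try-error") &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
    if (ok) ses <- setNames(sqrt(diag(solve(H))), names(par0))
    else warn("observed-information Hessian not positive definite; standard errors skipped")
  }
  new_cogirt_fit(
    type = "baseline",
    estimates = setNames(opt$par, names(par0)),
    se = ses,
    loglik = -opt$objective,
    converged = opt$convergence == 0,
    n_subjects = n_subj,
    n_obs = nrow(data),
    settings = list(method = method, nodes = nodes, start = start,
                    min_subjects = min_subjects),
    bank = fitted_bank,
    optim = opt
  )
}

## shared fit container ------------------------------------------------------
new_cogirt_fit <- function(type, estimates, se, loglik, converged,
                           n_subjects, n_obs, settings, ...) {
  structure(c(list(type = type, estimates = estimates, se = se,
                   loglik = loglik, converged = converged,
                   n_subjects = n_subjects, n_obs = n_obs,
                   settings = settings), list(...)),
            class = "cogirt_fit")
}

#' @export
print.cogirt_fit <- function(x, ...) {
  cat("<cogirt_fit> type:", x$type,
      "| logLik:", format(x$loglik, digits = 8),
      "| converged:", x$converged,
      "| subjects:", x$n_subjects,
      "| observations:", x$n_obs, "\n")
  if (x$type != "baseline") {
    est <- x$estimates
    cat("estimates:\n")
    print(round(est, 4))
  }
  invisible(x)
}
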