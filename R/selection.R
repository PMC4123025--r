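#' Shortlist predictors with a LASSO path
#'
#' Walks a decreasing L1-penalty path (100 log-spaced values from the
#' smallest penalty that zeroes every coefficient down to 1e-4 of it) over
#' the screened covariates, their season interactions, the season indicator
#' and - in pooled scope - the city indicator and city interactions, all
#' entering as penalizable standardized columns. Returns the term support of
#' the largest-support path solution with at most `max_vars` nonzero terms.
#' The LASSO is used only to shortlist candidates for the exhaustive subset
#' search; its shrunken coefficients are discarded.
#'
#' @param data Analysis table (rows = valid samples).
#' @param outcome Outcome column name.
#' @param candidates Character vector of screened covariate names.
#' @param scope `"city"` (single-city model: season interactions offered) or
#'   `"pooled"` (adds city indicator and city interactions).
#' @param max_vars Maximum number of shortlisted terms.
#' @return Character vector of term labels (subset of mains, `"season"`,
#'   `"city"`, `"<cov>:season"`, `"<cov>:city"`).
#' @export
lasso_reduce <- function(data, outcome, candidates, scope = c("city", "pooled"),
                         max_vars = 15) {
  scope <- match.arg(scope)
  if (length(candidates) == 0) abort("no candidate covariates to shortlist")
  terms <- c(candidates, "season", paste0(candidates, ":season"))
  if (scope == "pooled") {
    terms <- c(terms, "city", paste0(candidates, ":city"))
  }
  m <- build_design(data, terms)
  tags <- attr(m, "term")
  keep <- apply(m, 2, function(col) sd(col) > 0)
  m <- m[, keep, drop = FALSE]
  tags <- tags[keep]
  y <- data[[outcome]]

  # penalty path: from the full-shrinkage penalty down by four decades
  xs <- scale(m)
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
  path <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))
  fit <- glmnet::glmnet(m, y, alpha = 1, lambda = path, standardize = TRUE)

  support_terms <- lapply(seq_len(ncol(fit$beta)), function(j) {
    unique(tags[fit$beta[, j] != 0])
  })
  sizes <- lengths(support_terms)
  ok <- which(sizes <= max_vars)
  if (length(ok) == 0) return(character(0))
  best <- ok[which.max(sizes[ok])]
  sort(support_terms[[best]])
}

#' Enumerate candidate models for exhaustive search
#'
#' Yields every subset of the shortlisted terms with at most `max_params`
#' parameters (each main effect, the season or city indicator, and each
#' interaction term counts one; the intercept is free). Any subset containing
#' an interaction without its main effects is repaired by forcing the main
#' effects in; the repair may exceed the cap, which applies to the subset as
#' enumerated. Repaired duplicates are removed.
#'
#' @param candidates Character vector of term labels (at most 15).
#' @param max_params Parameter cap for enumerated subsets.
#' @return List of character vectors, one per candidate model (the empty
#'   vector is the intercept-only model).
#' @export
#' @examples
#' length(enumerate_subsets(paste0("x", 1:15))) # sum(choose(15, 0:6))
enumerate_subsets <- function(candidates, max_params = 6) {
  candidates <- unique(candidates)
  if (length(candidates) > 15) {
    abort("exhaustive search expects at most 15 candidates; shortlist first")
  }
  specs <- list(character(0))
  for (k in seq_len(min(max_params, length(candidates)))) {
    combos <- combn(candidates, k, simplify = FALSE)
    specs <- c(specs, combos)
  }
  repaired <- lapply(specs, .repair_terms)
  keys <- vapply(repaired, paste, character(1), collapse = "\r")
  repaired[!duplicated(keys)]
}

#' Select the best model by 10-fold cross-validated RMSE
#'
#' Draws one random fold assignment (fold sizes differing by at most one)
#' and evaluates every candidate model on it: each is fit by ordinary least
#' squares on nine tenths of the data and predicts the held-out tenth;
#' held-out residuals are pooled over folds into a CV RMSE and CV R-squared.
#' The model with the lowest CV RMSE wins; ties (RMSE within 1e-10) go to
#' the model with fewer parameters, then to the lexicographically smaller
#' term set. Candidates that are rank-deficient in any training fold are
#' discarded and logged.
#'
#' @param specs List of term-label vectors, e.g. from [enumerate_subsets()].
#' @param data Analysis table.
#' @param outcome Outcome column name.
#' @param k Number of folds.
#' @param seed Integer seed for the fold draw (one draw shared by every
#'   candidate, for comparability).
#' @return An object of class `selection_result`.
#' @export
select_best <- function(specs, data, outcome, k = 10, seed = 1L) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < k) abort("need at least as many samples as folds")
  y <- data[[outcome]]
  if (is.null(y)) abort(paste0("outcome `", outcome, "` not found"))

  all_terms <- sort(unique(unlist(specs)))
  master <- build_design(data, all_terms)
  tags <- attr(master, "term")

  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))

  # OLS fit of one term set; .lm.fit pivots columns, so map back before use
  ols_coef <- function(x, yy) {
    fit <- stats::.lm.fit(x, yy)
    if (fit$rank < ncol(x)) return(NULL)
    b <- numeric(ncol(x))
    b[fit$pivot] <- fit$coefficients
    b
  }
  eval_one <- function(terms) {
    x <- cbind(`(Intercept)` = 1, master[, tags %in% terms, drop = FALSE])
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      tr <- fold != f
      b <- ols_coef(x[tr, , drop = FALSE], y[tr])
      if (is.null(b)) return(NULL)
      pred[!tr] <- drop(x[!tr, , drop = FALSE] %*% b)
    }
    pred
  }

  results <- vector("list", length(specs))
  discarded <- 0L
  for (i in seq_along(specs)) {
    p <- eval_one(specs[[i]])
    if (is.null(p)) {
      discarded <- discarded + 1L
      next
    }
    sse <- sum((y - p)^2)
    results[[i]] <- c(rmse = sqrt(sse / n), r2 = 1 - sse / sum((y - mean(y))^2))
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) abort("every candidate model was rank-deficient in some fold")
  tab <- tibble(
    spec_id = which(ok),
    terms = purrr::map_chr(specs[ok], paste, collapse = " + "),
    n_params = purrr::map_int(specs[ok], .count_params),
    cv_rmse = purrr::map_dbl(results[ok], "rmse"),
    cv_r2 = purrr::map_dbl(results[ok], "r2")
  )
  best_rmse <- min(tab$cv_rmse)
  tied <- tab |>
    filter(.data$cv_rmse < best_rmse + 1e-10) |>
    arrange(.data$n_params, .data$terms)
  best_id <- tied$spec_id[1]
  best_terms <- specs[[best_id]]

  # refit the winner on the full data for reporting
  xb <- cbind(`(Intercept)` = 1, master[, tags %in% best_terms, drop = FALSE])
  beta <- ols_coef(xb, y)
  names(beta) <- colnames(xb)

  structure(
    list(
      best_terms = best_terms,
      coefficients = beta,
      cv_rmse = tab$cv_rmse[tab$spec_id == best_id],
      cv_r2 = tab$cv_r2[tab$spec_id == best_id],
      ranking = arrange(tab, .data$cv_rmse, .data$n_params, .data$terms),
      n_candidates = length(specs),
      n_discarded = discarded,
      outcome = outcome,
      k = k,
      seed = seed,
      fold = fold
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> outcome %s: best of %d candidates (%d discarded)\n",
    x$outcome, x$n_candidates, x$n_discarded
  ))
  cat(sprintf(
    "  terms: %s\n  CV RMSE %.4g, CV R2 %.3f (k = %d, seed %d)\n",
    if (length(x$best_terms) == 0) "(intercept only)" else paste(x$best_terms, collapse = " + "),
    x$cv_rmse, x$cv_r2, x$k, x$seed
  ))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    outcome = x$outcome, n_params = .count_params(x$best_terms),
    cv_rmse = x$cv_rmse, cv_r2 = x$cv_r2,
    n_candidates = x$n_candidates, n_discarded = x$n_discarded,
    k = x$k, seed = x$seed
  )
}
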