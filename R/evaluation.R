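#' Root-mean-square error
#'
#' @param obs,pred Numeric vectors of equal, positive length.
#' @return `sqrt(mean((obs - pred)^2))`.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2)
rmse <- function(obs, pred) {
  if (length(obs) == 0 || length(obs) != length(pred)) {
    abort("`obs` and `pred` must have equal length >= 1")
  }
  sqrt(mean((obs - pred)^2))
}

#' Per-city R-squared with truncation at zero
#'
#' For a model pooled over several cities, the within-city explanatory power
#' is `1 - SSE / SS_citymean`: one minus the ratio of the sum of squared
#' prediction errors to the sum of squared deviations of the observations
#' from their own city's mean. A model that predicts worse than the
#' city-specific mean gives a negative value, reported as 0 (the raw value
#' is retained alongside). A city with zero variance around its mean has an
#' undefined R-squared, reported as missing.
#'
#' @param obs,pred Numeric vectors.
#' @param city Character/factor vector of city labels aligned with `obs`.
#' @return Tibble with `city`, `n`, `r2` (truncated), `r2_raw`, `rmse`.
#' @export
r2_city <- function(obs, pred, city) {
  if (length(obs) != length(pred) || length(obs) != length(city)) {
    abort("`obs`, `pred` and `city` must align")
  }
  tibble(obs = obs, pred = pred, city = as.character(city)) |>
    group_by(.data$city) |>
    summarise(
      n = dplyr::n(),
      ss_mean = sum((.data$obs - mean(.data$obs))^2),
      sse = sum((.data$obs - .data$pred)^2),
      rmse = sqrt(.data$sse / .data$n),
      .groups = "drop"
    ) |>
    mutate(
      r2_raw = ifelse(.data$ss_mean > 0, 1 - .data$sse / .data$ss_mean, NA_real_),
      r2 = pmax(.data$r2_raw, 0)
    ) |>
    select("city", "n", "r2", "r2_raw", "rmse")
}

#' Cross-validate a model specification
#'
#' Randomly divides the data into `k` near-equal folds (sizes differ by at
#' most one), fits the model on each nine-tenths and predicts the held-out
#' tenth, then assembles all held-out predictions before computing metrics
#' (pooled-residual convention). For universal kriging the variogram is
#' refit within each training fold. Overall CV R-squared is
#' `1 - SSE / SS_mean` on the pooled held-out residuals; for multi-city
#' data the per-city decomposition of [r2_city()] is also reported.
#'
#' @param data Analysis table.
#' @param outcome Outcome column name.
#' @param terms Character vector of model terms.
#' @param method `"lur"` or `"uk"`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold draw.
#' @param pooled_variogram Passed to [fit_uk()] for `method = "uk"`.
#' @return An object of class `eval_report`.
#' @export
cross_validate <- function(data, outcome, terms, method = c("lur", "uk"),
                           k = 10, seed = 1L, pooled_variogram = FALSE) {
  method <- match.arg(method)
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < k) abort("need at least as many samples as folds")
  y <- data[[outcome]]
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- if (method == "lur") {
      fit_lur(data[tr, , drop = FALSE], outcome, terms)
    } else {
      fit_uk(data[tr, , drop = FALSE], outcome, terms,
        pooled_variogram = pooled_variogram
      )
    }
    pred[!tr] <- predict(fit, data[!tr, , drop = FALSE])$pred
  }
  sse <- sum((y - pred)^2)
  ss_mean <- sum((y - mean(y))^2)
  per_city <- if ("city" %in% names(data)) r2_city(y, pred, data$city) else NULL
  structure(
    list(
      outcome = outcome, terms = terms, method = method,
      cv_rmse = sqrt(sse / n),
      cv_r2 = max(1 - sse / ss_mean, 0),
      cv_r2_raw = 1 - sse / ss_mean,
      cv_r2_corr = suppressWarnings(cor(y, pred))^2,
      per_city = per_city,
      predictions = tibble(obs = y, pred = pred, fold = fold),
      k = k, seed = seed, n = n
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s (%s): CV RMSE %.4g, CV R2 %.3f (k = %d, seed %d, n = %d)\n",
    x$outcome, x$method, x$cv_rmse, x$cv_r2, x$k, x$seed, x$n
  ))
  if (!is.null(x$per_city) && nrow(x$per_city) > 1) {
    for (i in seq_len(nrow(x$per_city))) {
      cat(sprintf(
        "  %s: R2 %.3f, RMSE %.4g (n = %d)\n",
        x$per_city$city[i], x$per_city$r2[i], x$per_city$rmse[i], x$per_city$n[i]
      ))
    }
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  if (is.null(x$per_city)) {
    tibble(
      city = "all", n = x$n, r2 = x$cv_r2, r2_raw = x$cv_r2_raw, rmse = x$cv_rmse
    )
  } else {
    x$per_city
  }
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    outcome = x$outcome, method = x$method, cv_rmse = x$cv_rmse,
    cv_r2 = x$cv_r2, cv_r2_raw = x$cv_r2_raw, cv_r2_corr = x$cv_r2_corr,
    k = x$k, seed = x$seed, n = x$n
  )
}

#' Observed-versus-predicted plot for a cross-validation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object$predictions, aes(x = .data$obs, y = .data$pred)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.7) +
    labs(
      x = paste("observed", object$outcome),
      y = "held-out prediction",
      title = sprintf(
        "%s: CV R2 = %.2f, RMSE = %.3g", toupper(object$method),
        object$cv_r2, object$cv_rmse
      )
    ) +
    theme_minimal()
}
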