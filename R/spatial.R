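#' Fit a land-use regression model
#'
#' Ordinary least squares of the outcome on the model's terms (geographic
#' covariates, season/city indicators and their interactions). The fitted
#' object retains residuals and training coordinates so a spatial residual
#' model can be layered on top (see [fit_uk()]).
#'
#' @param data Analysis table with the outcome, term covariates and
#'   coordinates `x_m`, `y_m`.
#' @param outcome Outcome column name.
#' @param terms Character vector of term labels (see [enumerate_subsets()]).
#' @return An object of class `lur_fit`.
#' @export
fit_lur <- function(data, outcome, terms) {
  data <- as_tibble(data)
  y <- data[[outcome]]
  if (is.null(y)) abort(paste0("outcome `", outcome, "` not found"))
  city_levels <- if ("city" %in% names(data)) sort(unique(as.character(data$city))) else character(0)
  x <- cbind(`(Intercept)` = 1, build_design(data, terms, city_levels = city_levels))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(paste0("design matrix is rank deficient; collinear terms: ", paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(x %*% beta)
  res <- y - fitted
  n <- nrow(x)
  p <- ncol(x)
  sigma2 <- sum(res^2) / max(n - p, 1)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  structure(
    list(
      outcome = outcome, terms = terms,
      coefficients = setNames(drop(beta), colnames(x)),
      std_errors = setNames(se, colnames(x)),
      fitted = fitted, residuals = res,
      sigma = sqrt(sigma2), df_residual = n - p,
      r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
      coords = cbind(x_m = data$x_m, y_m = data$y_m),
      city = if ("city" %in% names(data)) as.character(data$city) else rep("all", n),
      city_levels = city_levels,
      n = n
    ),
    class = "lur_fit"
  )
}

#' @export
print.lur_fit <- function(x, ...) {
  cat(sprintf(
    "<lur_fit> %s ~ %s\n  n = %d, sigma = %.4g, R2 = %.3f\n",
    x$outcome,
    if (length(x$terms) == 0) "1" else paste(x$terms, collapse = " + "),
    x$n, x$sigma, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.lur_fit <- function(x, ...) {
  est <- unname(x$coefficients)
  se <- unname(x$std_errors)
  stat <- est / se
  tibble(
    term = names(x$coefficients), estimate = est, std.error = se,
    statistic = stat,
    p.value = 2 * stats::pt(abs(stat), df = x$df_residual, lower.tail = FALSE)
  )
}

#' @export
glance.lur_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome, r.squared = x$r_squared, sigma = x$sigma,
    nobs = x$n, df.residual = x$df_residual
  )
}

#' Fit an exponential variogram to spatial residuals
#'
#' Computes the empirical semivariogram in (approximately) `n_bins`
#' equal-pair-count lag bins up to half the maximum pairwise distance, then
#' fits `gamma(h) = nugget + psill * (1 - exp(-h / range))` by weighted
#' least squares with pair counts as weights. The effective range of the
#' exponential model (lag at ~95% of the sill) is three times the fitted
#' `range_m` parameter.
#'
#' @param residuals Numeric vector of residuals.
#' @param coords Two-column matrix/data frame of coordinates (m).
#' @param n_bins Target number of lag bins.
#' @return An object of class `variogram_fit` with `nugget`, `psill`,
#'   `range_m` and the empirical `bins` tibble.
#' @export
fit_variogram <- function(residuals, coords, n_bins = 12) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 20) abort("variogram estimation needs at least 20 points")
  d <- dist(coords)
  if (max(d) == 0) abort("all points are coincident; no spatial structure to fit")
  g <- dist(matrix(residuals, ncol = 1))^2 / 2
  keep <- d <= max(d) / 2
  dv <- as.numeric(d)[keep]
  gv <- as.numeric(g)[keep]

  breaks <- unique(quantile(dv, probs = seq(0, 1, length.out = n_bins + 1), type = 7))
  bin <- cut(dv, breaks = breaks, include.lowest = TRUE)
  bins <- tibble(lag = dv, gamma = gv, bin = bin) |>
    group_by(.data$bin) |>
    summarise(
      lag = mean(.data$lag), gamma = mean(.data$gamma), n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$lag) |>
    select("lag", "gamma", "n_pairs")

  obj <- function(par) {
    fitg <- par[1] + par[2] * (1 - exp(-bins$lag / par[3]))
    sum(bins$n_pairs * (fitg - bins$gamma)^2)
  }
  s2 <- var(residuals)
  max_lag <- max(bins$lag)
  starts <- list(
    c(bins$gamma[1], max(s2 - bins$gamma[1], 1e-8), max_lag / 3),
    c(0.1 * s2, 0.9 * s2, max_lag / 6),
    c(0.9 * s2, 0.1 * s2, max_lag / 2)
  )
  best <- NULL
  for (st in starts) {
    st <- pmax(st, c(0, 1e-10, max_lag * 1e-4))
    fit <- tryCatch(
      optim(st, obj,
        method = "L-BFGS-B",
        lower = c(0, 0, max_lag * 1e-4),
        upper = c(10 * s2 + 1e-8, 10 * s2 + 1e-8, 100 * max_lag)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("variogram optimization failed from every start")
  structure(
    list(
      model = "exponential",
      nugget = best$par[1], psill = best$par[2], range_m = best$par[3],
      effective_range_m = 3 * best$par[3],
      bins = bins, objective = best$value, n = n
    ),
    class = "variogram_fit"
  )
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf(
    "<variogram_fit> exponential: nugget %.4g, partial sill %.4g, range %.4g m (effective %.4g m)\n",
    x$nugget, x$psill, x$range_m, x$effective_range_m
  ))
  invisible(x)
}

#' @export
tidy.variogram_fit <- function(x, ...) {
  tibble(
    term = c("nugget", "psill", "range_m"),
    estimate = c(x$nugget, x$psill, x$range_m)
  )
}

#' @export
autoplot.variogram_fit <- function(object, ...) {
  curve_df <- tibble(
    lag = seq(0, max(object$bins$lag), length.out = 200)
  ) |>
    mutate(gamma = object$nugget + object$psill * (1 - exp(-.data$lag / object$range_m)))
  ggplot(object$bins, aes(x = .data$lag, y = .data$gamma)) +
    geom_point(aes(size = .data$n_pairs), alpha = 0.7) +
    geom_line(data = curve_df, linewidth = 0.8, colour = "firebrick") +
    labs(
      x = "lag distance (m)", y = "semivariance",
      title = "Empirical semivariogram and fitted exponential model",
      size = "pairs"
    ) +
    theme_minimal()
}

#' Fit a universal kriging model
#'
#' Two-stage universal kriging: a land-use regression mean model by ordinary
#' least squares, then simple kriging of its residuals under an exponential
#' variogram fitted to those residuals. When the training data span several
#' cities the variogram (and kriging system) is city-specific by default,
#' falling back to the pooled variogram for cities with fewer than 20
#' residuals; `pooled_variogram = TRUE` forces one shared variogram.
#'
#' @inheritParams fit_lur
#' @param pooled_variogram Force a single variogram across cities.
#' @param variogram Optional pre-fitted [fit_variogram()] object used for
#'   every city (overrides fitting).
#' @return An object of class `uk_fit` (contains the `lur_fit`).
#' @export
fit_uk <- function(data, outcome, terms, pooled_variogram = FALSE, variogram = NULL) {
  lur <- fit_lur(data, outcome, terms)
  cities <- unique(lur$city)
  pooled_vg <- variogram
  if (is.null(pooled_vg) && (pooled_variogram || length(cities) == 1 ||
    any(table(lur$city) < 20))) {
    pooled_vg <- fit_variogram(lur$residuals, lur$coords)
  }
  vgs <- setNames(vector("list", length(cities)), cities)
  for (ct in cities) {
    idx <- lur$city == ct
    vgs[[ct]] <- if (!is.null(variogram)) {
      variogram
    } else if (pooled_variogram || length(cities) == 1 || sum(idx) < 20) {
      pooled_vg
    } else {
      fit_variogram(lur$residuals[idx], lur$coords[idx, , drop = FALSE])
    }
  }
  structure(
    list(lur = lur, variograms = vgs, pooled_variogram = pooled_variogram),
    class = "uk_fit"
  )
}

#' @export
print.uk_fit <- function(x, ...) {
  print(x$lur)
  for (ct in names(x$variograms)) {
    vg <- x$variograms[[ct]]
    cat(sprintf(
      "  variogram [%s]: nugget %.4g, psill %.4g, range %.4g m\n",
      ct, vg$nugget, vg$psill, vg$range_m
    ))
  }
  invisible(x)
}

#' @export
tidy.uk_fit <- function(x, ...) tidy(x$lur, ...)

#' @export
glance.uk_fit <- function(x, ...) glance(x$lur, ...)

# simple kriging of mean-zero residuals at new points; residuals at exactly
# duplicated training coordinates are averaged first (duplicates make the
# covariance matrix singular when the nugget vanishes)
.krige_residuals <- function(vg, train_xy, train_res, new_xy) {
  if (vg$psill <= 0) return(numeric(nrow(new_xy)))
  key <- paste(train_xy[, 1], train_xy[, 2])
  if (anyDuplicated(key)) {
    agg <- rowsum(cbind(train_res, 1), key, reorder = FALSE)
    first <- !duplicated(key)
    train_xy <- train_xy[first, , drop = FALSE]
    train_res <- agg[, 1] / agg[, 2]
  }
  d_tt <- as.matrix(dist(train_xy))
  cmat <- vg$psill * exp(-d_tt / vg$range_m)
  diag(cmat) <- vg$psill + vg$nugget
  d_nt <- sqrt(
    outer(new_xy[, 1], train_xy[, 1], "-")^2 +
      outer(new_xy[, 2], train_xy[, 2], "-")^2
  )
  c0 <- vg$psill * exp(-d_nt / vg$range_m)
  sol <- tryCatch(solve(cmat, train_res), error = function(e) NULL)
  if (is.null(sol)) {
    warn("singular kriging system; adding ridge jitter 1e-8 * sill")
    ridge <- 1e-8 * (vg$psill + vg$nugget)
    sol <- solve(cmat + diag(ridge, nrow(cmat)), train_res)
  }
  drop(c0 %*% sol)
}

#' Predict from a fitted LUR model
#'
#' @param object A `lur_fit`.
#' @param newdata Data frame containing every model covariate (plus `season`
#'   / `city` where the model uses them).
#' @param ... Unused.
#' @return Tibble with columns `pred` and `mode` (`"lur"`).
#' @export
predict.lur_fit <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  x <- cbind(
    `(Intercept)` = 1,
    build_design(newdata, object$terms, city_levels = object$city_levels)
  )
  tibble(pred = drop(x %*% object$coefficients), mode = "lur")
}

#' Predict from a fitted universal kriging model
#'
#' Linear predictor plus simple-kriging interpolation of the training
#' residuals under the fitted variogram. With a zero partial sill the
#' spatial term vanishes and predictions equal the LUR predictions exactly;
#' with a zero nugget, prediction at a training location reproduces the
#' training observation.
#'
#' @param object A `uk_fit`.
#' @param newdata Data frame with model covariates and `x_m`, `y_m` (and
#'   `city` for multi-city fits).
#' @param ... Unused.
#' @return Tibble with columns `pred` and `mode` (`"uk"`).
#' @export
predict.uk_fit <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  base <- predict(object$lur, newdata)$pred
  new_city <- if ("city" %in% names(newdata)) as.character(newdata$city) else rep(object$lur$city[1], nrow(newdata))
  spatial <- numeric(nrow(newdata))
  for (ct in unique(new_city)) {
    nidx <- new_city == ct
    tidx <- object$lur$city == ct
    vg <- object$variograms[[ct]]
    if (is.null(vg) || !any(tidx)) {
      warn(paste0("no training residuals for city ", ct, "; using regression surface only"))
      next
    }
    spatial[nidx] <- .krige_residuals(
      vg, object$lur$coords[tidx, , drop = FALSE],
      object$lur$residuals[tidx],
      cbind(newdata$x_m[nidx], newdata$y_m[nidx])
    )
  }
  tibble(pred = base + spatial, mode = "uk")
}

#' Build a prediction lattice over a city
#'
#' Rectangular lattice with dense spacing inside the urban core (default
#' 250 m) and coarse spacing elsewhere (default 1,000 m, configurable to
#' 2,000 m), for tabular export of model predictions.
#'
#' @param layout A [city_layout()].
#' @param spacing_urban_m,spacing_rural_m Lattice spacings in meters.
#' @return Tibble with `x_m`, `y_m`, `city`, `in_urban_core`.
#' @export
prediction_grid <- function(layout, spacing_urban_m = 250, spacing_rural_m = 1000) {
  in_core <- function(x, y) {
    x >= layout$urban_core[1] & x <= layout$urban_core[2] &
      y >= layout$urban_core[3] & y <= layout$urban_core[4]
  }
  rural <- expand.grid(
    x_m = seq(layout$domain[1], layout$domain[2], by = spacing_rural_m),
    y_m = seq(layout$domain[3], layout$domain[4], by = spacing_rural_m)
  ) |> filter(!in_core(.data$x_m, .data$y_m))
  urban <- expand.grid(
    x_m = seq(layout$urban_core[1], layout$urban_core[2], by = spacing_urban_m),
    y_m = seq(layout$urban_core[3], layout$urban_core[4], by = spacing_urban_m)
  )
  bind_rows(
    mutate(as_tibble(urban), in_urban_core = TRUE),
    mutate(as_tibble(rural), in_urban_core = FALSE)
  ) |>
    mutate(city = layout$city_id, .before = 1)
}
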