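#' Drop covariates with insufficient variability
#'
#' A covariate column is excluded when its 85th percentile equals its 15th
#' percentile on the analysis rows (exact equality of the two sample
#' quantiles, computed with the linear-interpolation convention,
#' `stats::quantile` type 7). Such columns are near-constant and carry no
#' contrast for regression.
#'
#' @param x Data frame of covariate columns (analysis rows only).
#' @return List with `x` (the retained columns) and `dropped` (names).
#' @export
variability_filter <- function(x) {
  x <- as_tibble(x)
  if (nrow(x) < 2) abort("variability screening needs at least 2 rows")
  q <- purrr::map_lgl(x, function(col) {
    qs <- quantile(col, c(0.15, 0.85), na.rm = TRUE, names = FALSE, type = 7)
    identical(qs[1], qs[2])
  })
  list(x = x[, !q, drop = FALSE], dropped = names(x)[q])
}

.buffer_range <- function(radius) {
  dplyr::case_when(
    is.na(radius) ~ "unbuffered",
    radius <= 500 ~ "short",
    TRUE ~ "long"
  )
}

.abs_cor <- function(x, y) {
  suppressWarnings(r <- cor(x, y))
  ifelse(is.na(r), -Inf, abs(r))
}

#' Select the best short- and long-range buffer per category
#'
#' Within each buffered covariate category, keeps at most one short-range
#' buffer (50-500 m) and one long-range buffer (over 500 m), the one with the
#' highest absolute univariate Pearson correlation with the exposure being
#' modelled. Ties are broken toward the smaller radius, then by name.
#' Unbuffered covariates pass through. A category whose buffers are all
#' constant (correlation undefined) is dropped and reported.
#'
#' @param x Data frame of covariate columns.
#' @param y Exposure vector aligned with the rows of `x`.
#' @param schema A [covariate_schema()] describing the columns.
#' @return List with `x` (reduced columns), `chosen` (tibble of category,
#'   range, name, radius, abs_r) and `dropped_categories`.
#' @export
select_buffers <- function(x, y, schema) {
  x <- as_tibble(x)
  if (length(y) != nrow(x)) abort("`y` must align with the rows of `x`")
  meta <- schema |>
    filter(.data$name %in% names(x)) |>
    mutate(range = .buffer_range(.data$buffer_radius_m))
  unknown <- setdiff(names(x), meta$name)

  buffered <- filter(meta, .data$range != "unbuffered")
  chosen <- buffered |>
    mutate(abs_r = purrr::map_dbl(.data$name, function(nm) .abs_cor(x[[nm]], y))) |>
    group_by(.data$category, .data$range) |>
    arrange(desc(.data$abs_r), .data$buffer_radius_m, .data$name, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    filter(is.finite(.data$abs_r))
  dropped_cats <- setdiff(unique(buffered$category), unique(chosen$category))
  if (length(dropped_cats) > 0) {
    warn(paste0(
      "buffered categories with no usable (non-constant) buffer dropped: ",
      paste(dropped_cats, collapse = ", ")
    ))
  }
  keep <- c(
    filter(meta, .data$range == "unbuffered")$name, unknown, chosen$name
  )
  keep <- names(x)[names(x) %in% keep]
  list(
    x = x[, keep, drop = FALSE],
    chosen = select(chosen, "category", "range", "name",
      radius = "buffer_radius_m", "abs_r"
    ),
    dropped_categories = dropped_cats
  )
}

#' Prune highly inter-correlated covariates
#'
#' Builds the graph whose edges connect covariate pairs with absolute
#' pairwise correlation above `rho_max` and resolves each connected component
#' greedily: repeatedly keep the best remaining member and delete its
#' still-present neighbours. "Best" is decided by preference class first
#' (positional coordinates are preferentially excluded; recent raster-based
#' land use is preferred over older aerial-photography land use), then by the
#' larger absolute correlation with the exposure, then smaller buffer radius,
#' then name.
#'
#' @inheritParams select_buffers
#' @param rho_max Pairwise-correlation threshold above which covariates are
#'   considered redundant.
#' @return List with `x` (reduced), `pruned` (tibble: name, kept_by, rho).
#' @export
prune_correlated <- function(x, y, schema, rho_max = 0.85) {
  x <- as_tibble(x)
  if (rho_max <= 0 || rho_max >= 1) abort("`rho_max` must lie in (0, 1)")
  nms <- names(x)
  if (length(nms) < 2) {
    return(list(x = x, pruned = tibble(name = character(), kept_by = character(), rho = numeric())))
  }
  suppressWarnings(rho <- abs(cor(as.matrix(x))))
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  adj <- rho > rho_max

  meta <- schema |> filter(.data$name %in% nms)
  pref <- setNames(rep(0L, length(nms)), nms)
  pref[meta$name[meta$source_vintage == "aerial197x"]] <- 1L
  pref[meta$name[meta$positional]] <- 2L
  radius <- setNames(rep(Inf, length(nms)), nms)
  radius[meta$name] <- ifelse(is.na(meta$buffer_radius_m), Inf, meta$buffer_radius_m)
  abs_r <- purrr::map_dbl(x, .abs_cor, y = y)

  ord <- order(pref[nms], -abs_r[nms], radius[nms], nms)
  rank_of <- setNames(seq_along(nms), nms[ord])

  # connected components under |rho| > rho_max, by breadth-first search
  comp <- rep(NA_integer_, length(nms))
  cid <- 0L
  for (i in seq_along(nms)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[j])) next
      comp[j] <- cid
      queue <- c(queue, which(adj[j, ] & is.na(comp)))
    }
  }

  kept <- character(0)
  pruned <- list()
  for (members in split(seq_along(nms), comp)) {
    remaining <- members
    while (length(remaining) > 0) {
      best <- remaining[which.min(rank_of[nms[remaining]])]
      kept <- c(kept, nms[best])
      neighbours <- remaining[adj[best, remaining]]
      for (nb in neighbours) {
        pruned[[length(pruned) + 1]] <- tibble(
          name = nms[nb], kept_by = nms[best], rho = rho[best, nb]
        )
      }
      remaining <- setdiff(remaining, c(best, neighbours))
    }
  }
  keep <- nms[nms %in% kept]
  list(
    x = x[, keep, drop = FALSE],
    pruned = if (length(pruned) > 0) bind_rows(pruned) else {
      tibble(name = character(), kept_by = character(), rho = numeric())
    }
  )
}

#' Full covariate-screening cascade
#'
#' Runs the three screening stages in order: variability filter (85th = 15th
#' percentile), best short/long buffer per category by univariate
#' correlation, and correlation pruning at `rho_max`. Screening is computed
#' on the pooled analysis rows supplied.
#'
#' @inheritParams prune_correlated
#' @return An object of class `screening`: list with `x` (surviving
#'   columns), `survivors` (names), and `trace` (per-stage records
#'   accounting for every input column).
#' @export
screen_covariates <- function(x, y, schema, rho_max = 0.85) {
  x <- as_tibble(x)
  input <- names(x)
  s1 <- variability_filter(x)
  s2 <- select_buffers(s1$x, y, schema)
  s3 <- prune_correlated(s2$x, y, schema, rho_max = rho_max)
  res <- structure(
    list(
      x = s3$x,
      survivors = names(s3$x),
      trace = list(
        input = input,
        variability_dropped = s1$dropped,
        buffers_chosen = s2$chosen,
        buffer_categories_dropped = s2$dropped_categories,
        buffers_not_selected = setdiff(names(s1$x), names(s2$x)),
        correlation_pruned = s3$pruned
      ),
      rho_max = rho_max
    ),
    class = "screening"
  )
  stopifnot(setequal(
    c(
      res$survivors, res$trace$variability_dropped,
      res$trace$buffers_not_selected, res$trace$correlation_pruned$name
    ),
    input
  ))
  res
}

#' @export
print.screening <- function(x, ...) {
  cat(sprintf(
    "<screening> %d -> %d covariates (variability -%d, buffers -%d, correlation -%d)\n",
    length(x$trace$input), length(x$survivors),
    length(x$trace$variability_dropped),
    length(x$trace$buffers_not_selected),
    nrow(x$trace$correlation_pruned)
  ))
  invisible(x)
}

#' @export
tidy.screening <- function(x, ...) {
  bind_rows(
    tibble(name = x$survivors, decision = "kept", detail = NA_character_),
    tibble(
      name = x$trace$variability_dropped, decision = "dropped_variability",
      detail = NA_character_
    ),
    tibble(
      name = x$trace$buffers_not_selected, decision = "dropped_buffer",
      detail = NA_character_
    ),
    tibble(
      name = x$trace$correlation_pruned$name, decision = "pruned_correlation",
      detail = paste0(
        "kept ", x$trace$correlation_pruned$kept_by,
        " (rho=", signif(x$trace$correlation_pruned$rho, 3), ")"
      )
    )
  )
}
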