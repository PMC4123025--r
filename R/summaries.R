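#' Stratified campaign summary statistics
#'
#' Sample size, mean, SD (n-1 denominator) and coefficient of variation
#' (SD / mean) of an outcome by city and season. The coefficient of
#' variation is reported as missing when the stratum mean is zero. Empty
#' strata are omitted with a warning.
#'
#' @param samples Samples table (needs `city`, `season` and the outcome).
#' @param outcome Outcome column name.
#' @param by Grouping columns (default city and season).
#' @return Tibble with one row per stratum: `city`, `season`, `outcome`,
#'   `n`, `mean`, `sd`, `cv`.
#' @export
stratum_stats <- function(samples, outcome, by = c("city", "season")) {
  samples <- as_tibble(samples)
  v <- samples[[outcome]]
  if (is.null(v)) abort(paste0("outcome `", outcome, "` not found"))
  out <- samples |>
    filter(!is.na(.data[[outcome]])) |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    summarise(
      outcome = outcome,
      n = dplyr::n(),
      mean = mean(.data[[outcome]]),
      sd = sd(.data[[outcome]]),
      .groups = "drop"
    ) |>
    mutate(cv = ifelse(.data$mean == 0, NA_real_, .data$sd / .data$mean))
  if (any(is.na(v))) {
    warn(sprintf("%d missing `%s` value(s) excluded from summaries", sum(is.na(v)), outcome))
  }
  out
}

#' Pool stratified summary statistics
#'
#' Combines per-stratum `(n, mean, sd)` triples into the pooled sample size,
#' mean and SD of the union of the strata, exactly: the pooled mean is the
#' sample-size-weighted mean, and the pooled SD recombines within-stratum
#' and between-stratum sums of squares,
#' `sqrt((sum((n_i - 1) s_i^2) + sum(n_i (m_i - m)^2)) / (sum(n_i) - 1))`.
#' Applied to the per-season rows of a campaign summary table this
#' reproduces the across-season "pooled" rows.
#'
#' @param strata Data frame with columns `n`, `mean`, `sd` (one row per
#'   stratum), or vectors via `...`.
#' @return One-row tibble with pooled `n`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' pooled_stats(tibble::tibble(
#'   n = c(33, 31), mean = c(5.54, 5.94), sd = c(1.98, 2.09)
#' ))
pooled_stats <- function(strata) {
  strata <- as_tibble(strata)
  if (nrow(strata) == 0) abort("at least one stratum is required")
  if (any(strata$n < 2)) abort("every stratum needs n >= 2 for an SD")
  n <- sum(strata$n)
  m <- sum(strata$n * strata$mean) / n
  ss_within <- sum((strata$n - 1) * strata$sd^2)
  ss_between <- sum(strata$n * (strata$mean - m)^2)
  s <- sqrt((ss_within + ss_between) / (n - 1))
  tibble(n = n, mean = m, sd = s, cv = ifelse(m == 0, NA_real_, s / m))
}

#' Campaign summary table with pooled rows
#'
#' Per-city, per-season summary of each outcome with an across-season
#' "pooled" row per city, in the shape of a campaign descriptive-statistics
#' table. Values are unrounded; round for display.
#'
#' @param samples Samples table.
#' @param outcomes Outcome column names.
#' @return Tibble with `city`, `season` (including `"pooled"`), `outcome`,
#'   `n`, `mean`, `sd`, `cv`.
#' @export
summary_table <- function(samples, outcomes = c("coarse", "copper", "phosphorus", "silicon", "zinc")) {
  outcomes <- intersect(outcomes, names(samples))
  per <- purrr::map(outcomes, function(oc) stratum_stats(samples, oc)) |>
    bind_rows() |>
    mutate(season = as.character(.data$season))
  pooled <- per |>
    group_by(.data$city, .data$outcome) |>
    group_modify(function(g, key) pooled_stats(g)) |>
    ungroup() |>
    mutate(season = "pooled")
  bind_rows(per, pooled) |>
    arrange(.data$city, .data$outcome, .data$season) |>
    select("city", "season", "outcome", "n", "mean", "sd", "cv")
}
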