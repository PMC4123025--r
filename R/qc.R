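#' Sample-validity rules for a snapshot campaign
#'
#' Thresholds under which a 2-week filter-pair sample is voided: sampling
#' duration under `min_duration_days`, pump-flow deviation beyond
#' `flow_tolerance`, coarse concentration more than `outlier_sd` standard
#' deviations from its city-season mean (mean and SD computed once on the
#' full candidate stratum), or coarse-fraction sulfur above
#' `coarse_sulfur_max` (sulfur should reside almost entirely in the fine
#' fraction, so coarse sulfur marks a compromised size cut).
#'
#' @param min_duration_days Minimum valid sampling duration (days).
#' @param flow_tolerance Maximum absolute fractional flow deviation.
#' @param outlier_sd Extreme-concentration threshold in stratum SDs.
#' @param coarse_sulfur_max Maximum coarse-fraction sulfur (ug/m3).
#' @param outlier_on Which measurements the SD screen applies to:
#'   `"mass"` (default) or `"mass_and_species"`.
#' @return An object of class `qc_rules`.
#' @export
qc_rules <- function(min_duration_days = 9,
                     flow_tolerance = 0.20,
                     outlier_sd = 5,
                     coarse_sulfur_max = 0.2,
                     outlier_on = c("mass", "mass_and_species")) {
  outlier_on <- match.arg(outlier_on)
  if (any(c(min_duration_days, flow_tolerance, outlier_sd, coarse_sulfur_max) <= 0)) {
    abort("all QC thresholds must be positive")
  }
  structure(
    list(
      min_duration_days = min_duration_days, flow_tolerance = flow_tolerance,
      outlier_sd = outlier_sd, coarse_sulfur_max = coarse_sulfur_max,
      outlier_on = outlier_on
    ),
    class = "qc_rules"
  )
}

#' Derive coarse PM from collocated PM10 and PM2.5
#'
#' Coarse particulate mass (PM10-2.5) is estimated by subtracting the PM2.5
#' measurement from the collocated PM10 measurement. Negative differences are
#' retained (the estimate is reported as computed) but flagged as invalid
#' pairs; rows missing either member of the pair get `NA` and are flagged.
#'
#' @param data A data frame of samples.
#' @param pm10,pm25 Column names (character) holding the two mass
#'   measurements in ug/m3.
#' @return `data` with two added columns: `coarse` (pm10 - pm25) and
#'   `valid_pair` (both members present and difference non-negative).
#' @export
#' @examples
#' compute_coarse(tibble::tibble(pm10 = c(10, 4, 3), pm25 = c(4, 4, 4)))
compute_coarse <- function(data, pm10 = "pm10", pm25 = "pm25") {
  data <- as_tibble(data)
  p10 <- data[[pm10]]
  p25 <- data[[pm25]]
  if (is.null(p10) || is.null(p25)) abort("`pm10` and `pm25` columns are required")
  coarse <- p10 - p25
  n_missing <- sum(is.na(coarse))
  if (n_missing > 0) {
    inform(sprintf("%d sample pair(s) missing a PM10 or PM2.5 member; excluded from valid pairs", n_missing))
  }
  data$coarse <- coarse
  data$valid_pair <- !is.na(coarse) & coarse >= 0
  data
}

#' Apply sample-validity rules to a campaign
#'
#' Screens every sample against the campaign's validity rules and derives
#' the coarse concentration if not already present. A sample is voided if its
#' duration is too short, its flow deviation is out of tolerance, its filter
#' is damaged, its coarse concentration lies more than `outlier_sd` SDs from
#' the city-season mean (single pass: mean/SD computed once on the full
#' candidate stratum, before any removal), or its coarse-fraction sulfur
#' exceeds the threshold. When several rules match, the recorded reason is
#' the first in the fixed order duration, flow, damage, outlier, sulfur.
#'
#' @param data Samples data frame (columns `pm10`, `pm25` or `coarse`,
#'   `duration_days`, `flow_deviation`, `coarse_sulfur`, optionally
#'   `damaged`, `city`, `season`).
#' @param rules A [qc_rules()] object.
#' @return An object of class `qc_result`: list with `samples` (input plus
#'   `coarse`, `valid_pair`, `qc_status`), `valid` (the valid subset),
#'   `counts` (voidings by reason), `n_valid_pairs`, `n_unique_locations`.
#' @export
apply_qc <- function(data, rules = qc_rules()) {
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    return(structure(
      list(
        samples = data, valid = data,
        counts = tibble(reason = character(), n = integer()),
        n_valid_pairs = 0L, n_unique_locations = 0L, rules = rules
      ),
      class = "qc_result"
    ))
  }
  if (!"coarse" %in% names(data)) data <- compute_coarse(data)
  if (!"valid_pair" %in% names(data)) data$valid_pair <- !is.na(data$coarse) & data$coarse >= 0
  if (!"damaged" %in% names(data)) data$damaged <- FALSE

  stratum <- if (all(c("city", "season") %in% names(data))) {
    paste(data$city, data$season)
  } else {
    rep("all", nrow(data))
  }
  z_of <- function(v) {
    out <- rep(NA_real_, length(v))
    for (idx in split(seq_along(v), stratum)) {
      m <- mean(v[idx], na.rm = TRUE)
      s <- sd(v[idx], na.rm = TRUE)
      out[idx] <- if (is.na(s) || s == 0) 0 else (v[idx] - m) / s
    }
    out
  }
  outlier <- abs(z_of(data$coarse)) > rules$outlier_sd
  if (rules$outlier_on == "mass_and_species") {
    for (sp in intersect(c("copper", "zinc", "phosphorus", "silicon"), names(data))) {
      outlier <- outlier | abs(z_of(data[[sp]])) > rules$outlier_sd
    }
  }

  reason <- rep(NA_character_, nrow(data))
  hit <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  hit(data$duration_days < rules$min_duration_days, "duration")
  hit(abs(data$flow_deviation) > rules$flow_tolerance, "flow")
  hit(data$damaged, "damaged")
  hit(outlier, "outlier")
  hit(data$coarse_sulfur > rules$coarse_sulfur_max, "sulfur")

  data$qc_status <- ifelse(is.na(reason), "valid", paste0("voided:", reason))
  valid <- filter(data, .data$qc_status == "valid")
  counts <- tibble(reason = reason[!is.na(reason)]) |>
    count(.data$reason, name = "n")
  structure(
    list(
      samples = data, valid = valid, counts = counts,
      n_valid_pairs = sum(valid$valid_pair),
      n_unique_locations = if ("site_id" %in% names(valid)) {
        dplyr::n_distinct(valid$site_id)
      } else {
        nrow(valid)
      },
      rules = rules
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<qc_result> %d samples: %d valid (%d valid pairs at %d unique locations), %d voided\n",
    n, nrow(x$valid), x$n_valid_pairs, x$n_unique_locations, n - nrow(x$valid)
  ))
  if (nrow(x$counts) > 0) {
    for (i in seq_len(nrow(x$counts))) {
      cat(sprintf("  voided:%s  %d\n", x$counts$reason[i], x$counts$n[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) {
  cols <- intersect(c("sample_id", "site_id", "city", "season"), names(x$samples))
  x$samples |> select(dplyr::all_of(cols), "qc_status", "valid_pair")
}

#' @export
glance.qc_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_valid = nrow(x$valid),
    n_voided = nrow(x$samples) - nrow(x$valid),
    n_valid_pairs = x$n_valid_pairs,
    n_unique_locations = x$n_unique_locations
  )
}

#' Precision of collocated duplicate samples
#'
#' Summarizes measurement precision as the median relative absolute
#' difference `|a - b| / mean(a, b)` over collocated duplicate pairs, per
#' metric. Pairs with a zero mean are skipped and counted.
#'
#' @param pairs A data frame with columns `metric`, `first`, `second` (one
#'   row per duplicate pair and metric).
#' @return A tibble with `metric`, `n_pairs`, `n_skipped`, `precision`.
#' @export
#' @examples
#' duplicate_precision(tibble::tibble(
#'   metric = "pm10", first = c(10, 9), second = c(10, 11)
#' ))
duplicate_precision <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) abort("at least one duplicate pair is required")
  pairs |>
    mutate(
      pair_mean = (.data$first + .data$second) / 2,
      rel = abs(.data$first - .data$second) / .data$pair_mean
    ) |>
    group_by(.data$metric) |>
    summarise(
      n_pairs = sum(.data$pair_mean != 0),
      n_skipped = sum(.data$pair_mean == 0),
      precision = median(.data$rel[.data$pair_mean != 0]),
      .groups = "drop"
    )
}
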