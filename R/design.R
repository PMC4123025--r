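# Model terms are character labels: a covariate name; "season" (summer
# indicator); "city" (city indicators, reference = first level); or an
# interaction "cov:season" / "cov:city". Each term counts as one parameter
# (the intercept is not counted), so "city" and "cov:city" count 1 even when
# they expand to several design columns.

.term_parts <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

.is_interaction <- function(term) grepl(":", term, fixed = TRUE)

# force main effects of any interaction into the term set
.repair_terms <- function(terms) {
  extra <- unlist(lapply(terms[vapply(terms, .is_interaction, logical(1))], .term_parts))
  sort(unique(c(terms, extra)))
}

.count_params <- function(terms) length(terms)

#' Build a numeric design matrix from model terms
#'
#' @param data Analysis table containing the covariate columns and, where
#'   used by the terms, `season` (levels winter/summer) and `city`.
#' @param terms Character vector of term labels (see Details in
#'   [enumerate_subsets()]).
#' @param city_levels City levels fixed at fit time; defaults to the sorted
#'   cities present in `data`. Prediction data must be expanded against the
#'   training levels, not its own.
#' @return Numeric matrix (no intercept column) whose columns are tagged
#'   with the generating term via the `"term"` attribute.
#' @keywords internal
build_design <- function(data, terms, city_levels = NULL) {
  n <- nrow(data)
  if (length(terms) == 0) {
    m <- matrix(numeric(0), nrow = n, ncol = 0)
    attr(m, "term") <- character(0)
    return(m)
  }
  summer <- if ("season" %in% names(data)) as.numeric(as.character(data$season) == "summer") else NULL
  if (is.null(city_levels)) {
    city_levels <- if ("city" %in% names(data)) sort(unique(as.character(data$city))) else character(0)
  }
  city_ind <- if (length(city_levels) > 1) {
    vapply(city_levels[-1], function(cl) as.numeric(data$city == cl), numeric(n))
  } else {
    NULL
  }
  cols <- list()
  tags <- character(0)
  for (tm in terms) {
    parts <- .term_parts(tm)
    if (length(parts) == 1) {
      if (tm == "season") {
        if (is.null(summer)) abort("term 'season' needs a `season` column")
        cols[[length(cols) + 1]] <- matrix(summer, ncol = 1, dimnames = list(NULL, "season"))
      } else if (tm == "city") {
        if (is.null(city_ind)) abort("term 'city' needs a `city` column with >1 level")
        colnames(city_ind) <- paste0("city", city_levels[-1])
        cols[[length(cols) + 1]] <- city_ind
      } else {
        v <- data[[tm]]
        if (is.null(v)) abort(paste0("covariate `", tm, "` is missing from the data"))
        cols[[length(cols) + 1]] <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, tm))
      }
    } else {
      cov <- parts[1]
      v <- data[[cov]]
      if (is.null(v)) abort(paste0("covariate `", cov, "` is missing from the data"))
      if (parts[2] == "season") {
        cols[[length(cols) + 1]] <- matrix(as.numeric(v) * summer,
          ncol = 1, dimnames = list(NULL, tm)
        )
      } else if (parts[2] == "city") {
        if (is.null(city_ind)) abort("term '<cov>:city' needs a `city` column with >1 level")
        m <- city_ind * as.numeric(v)
        colnames(m) <- paste0(cov, ":city", city_levels[-1])
        cols[[length(cols) + 1]] <- m
      } else {
        abort(paste0("unsupported interaction: ", tm))
      }
    }
    tags <- c(tags, rep(tm, ncol(cols[[length(cols)]])))
  }
  m <- do.call(cbind, cols)
  attr(m, "term") <- tags
  m
}

#' Join valid samples with site covariates into an analysis table
#'
#' @param samples Samples tibble (must carry `site_id`; typically the valid
#'   output of [apply_qc()], with `coarse` already derived).
#' @param covariates Site-level covariate tibble (keyed by `site_id`).
#' @return Tibble with one row per sample and all covariate columns joined.
#' @export
campaign_data <- function(samples, covariates) {
  samples <- as_tibble(samples)
  covariates <- as_tibble(covariates)
  dup <- intersect(setdiff(names(covariates), "site_id"), names(samples))
  if (length(dup) > 0) covariates <- select(covariates, -dplyr::all_of(dup))
  left_join(samples, covariates, by = "site_id")
}

#' Sensitivity switches: log transform and 3-SD outlier exclusion
#'
#' Two optional reruns of the identical pipeline: modelling the natural log
#' of concentrations, and excluding samples more than 3 SDs from their
#' city-specific outcome mean (computed once). With both switches off the
#' data are returned unchanged.
#'
#' @param data Analysis table.
#' @param outcome Outcome column name.
#' @param log_transform Replace the outcome by its natural log (non-positive
#'   rows are dropped with a warning).
#' @param drop_outliers_3sd Drop rows beyond 3 SDs from the city-specific
#'   mean of the outcome.
#' @return The (possibly) transformed analysis table.
#' @export
apply_sensitivity <- function(data, outcome, log_transform = FALSE,
                              drop_outliers_3sd = FALSE) {
  data <- as_tibble(data)
  if (drop_outliers_3sd) {
    grp <- if ("city" %in% names(data)) data$city else rep("all", nrow(data))
    keep <- rep(TRUE, nrow(data))
    for (idx in split(seq_len(nrow(data)), grp)) {
      v <- data[[outcome]][idx]
      s <- sd(v)
      if (!is.na(s) && s > 0) keep[idx] <- abs(v - mean(v)) <= 3 * s
    }
    data <- data[keep, , drop = FALSE]
  }
  if (log_transform) {
    pos <- data[[outcome]] > 0
    if (!all(pos)) {
      warn(sprintf("%d non-positive outcome value(s) dropped before log transform", sum(!pos)))
      data <- data[pos, , drop = FALSE]
    }
    data[[outcome]] <- log(data[[outcome]])
  }
  data
}
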