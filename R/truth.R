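#' Ground truth for a synthetic snapshot campaign
#'
#' Collects every generative parameter of the synthetic campaign: the sparse
#' linear signal (`beta`, on campaign-standardized covariates, in outcome
#' units per SD of the covariate), per-city summer offsets, predictor-by-
#' season interaction coefficients, the exponential-covariance parameters of
#' the spatially correlated residual field, the measurement-noise model, and
#' the quality-control defect injection rates. Keeping the truth explicit
#' makes every downstream stage testable: the generator returns a ledger
#' recording the realized linear predictor, spatial residual and injected
#' defects for each sample.
#'
#' @param beta Named numeric vector: covariate name -> coefficient for the
#'   coarse-mass outcome, applied to the campaign-standardized covariate.
#' @param intercept Mean coarse concentration (ug/m3) at covariate means.
#' @param season_main Named numeric vector of per-city summer offsets
#'   (ug/m3); cities absent from the vector get 0.
#' @param season_interactions Named numeric vector: covariate name ->
#'   additional slope in summer.
#' @param spatial_range_m,spatial_sill,nugget Exponential-covariance
#'   parameters of the residual field: `C(d) = sill * exp(-d / range)` plus a
#'   `nugget` variance at zero lag. Units of sill/nugget are (ug/m3)^2.
#' @param noise_model `"lognormal"` (multiplicative, default) or
#'   `"gaussian"` (additive) measurement noise.
#' @param noise_sd SD of log-noise (lognormal) or of additive noise
#'   (gaussian); 0 disables measurement noise.
#' @param outlier_rate Per-sample rate at which extreme concentrations are
#'   injected; realized as at most one extreme per city-season stratum (see
#'   vignette).
#' @param defect_rates Named list of per-sample Bernoulli rates for the
#'   other QC defects: `duration`, `flow`, `sulfur`, `damaged`.
#' @param species Named list of per-species generative settings (each a list
#'   with `beta`, `intercept`, `season_main`, `spatial_sill`, `nugget`,
#'   `noise_sd`); `NULL` uses small defaults for copper, zinc, phosphorus
#'   and silicon.
#' @param duplicate_fraction Fraction of site-seasons that receive a
#'   collocated duplicate sample (same location, independent noise).
#' @param seed Integer seed; identical seeds give bit-identical campaigns.
#'
#' @return An object of class `campaign_truth`.
#' @export
campaign_truth <- function(beta = NULL,
                           intercept = 4,
                           season_main = c(chicago = 0.4, st_paul = 3.3, winston_salem = 0.4),
                           season_interactions = NULL,
                           spatial_range_m = 2000,
                           spatial_sill = 0.5,
                           nugget = 0.2,
                           noise_model = c("lognormal", "gaussian"),
                           noise_sd = 0.08,
                           outlier_rate = 0,
                           defect_rates = list(duration = 0, flow = 0, sulfur = 0, damaged = 0),
                           species = NULL,
                           duplicate_fraction = 0,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(beta)) {
    beta <- c(
      lu_high_dev_300m = 0.9, rd_a2_len_100m = 0.7, imperviousness_1000m = 0.6,
      ndvi_q75_500m = -0.5, lu_crops_3000m = 0.4
    )
  }
  if (is.null(season_interactions)) {
    season_interactions <- c(lu_crops_3000m = 0.5)
  }
  defaults <- list(duration = 0, flow = 0, sulfur = 0, damaged = 0)
  defect_rates <- modifyList(defaults, as.list(defect_rates))
  rates <- c(unlist(defect_rates), outlier = outlier_rate, dup = duplicate_fraction)
  if (any(rates < 0 | rates > 1)) abort("defect/outlier/duplicate rates must lie in [0, 1]")
  if (spatial_range_m < 0 || spatial_sill < 0 || nugget < 0 || noise_sd < 0) {
    abort("spatial_range_m, spatial_sill, nugget and noise_sd must be non-negative")
  }
  if (is.null(species)) species <- default_species_truth()
  structure(
    list(
      beta = beta, intercept = intercept, season_main = season_main,
      season_interactions = season_interactions,
      spatial_range_m = spatial_range_m, spatial_sill = spatial_sill,
      nugget = nugget, noise_model = noise_model, noise_sd = noise_sd,
      outlier_rate = outlier_rate, defect_rates = defect_rates,
      species = species, duplicate_fraction = duplicate_fraction,
      seed = as.integer(seed)
    ),
    class = "campaign_truth"
  )
}

#' Default species-level generative settings
#'
#' Each coarse-PM species is generated by the same linear + spatial mechanism
#' as total mass, with species-specific sparse coefficients. Units follow the
#' campaign convention: copper, zinc and phosphorus in ng/m3, silicon in
#' ug/m3.
#'
#' @return Named list of per-species parameter lists.
#' @export
default_species_truth <- function() {
  list(
    copper = list(
      beta = c(rd_a1_len_300m = 1.2, lu_high_dev_150m = 1.0, dist_a1 = -0.6),
      intercept = 4.5, season_main = c(st_paul = -1.2),
      spatial_sill = 0.4, nugget = 0.3, noise_sd = 0.12
    ),
    zinc = list(
      beta = c(truck_len_300m = 2.5, lu_med_dev_300m = 2.0, imperviousness_500m = 1.5),
      intercept = 10, season_main = c(chicago = 2),
      spatial_sill = 4, nugget = 3, noise_sd = 0.15
    ),
    phosphorus = list(
      beta = c(lu_crops_5000m = 2.0, ndvi_q75_1000m = 1.5, lu_pasture_3000m = 1.0),
      intercept = 15, season_main = c(chicago = 4, st_paul = 10, winston_salem = 13),
      spatial_sill = 3, nugget = 2, noise_sd = 0.12
    ),
    silicon = list(
      beta = c(lu_barren_1500m = 0.08, rd_a3_len_500m = 0.05, lu_crops_3000m = 0.04),
      intercept = 0.4, season_main = c(st_paul = 0.45, chicago = -0.1),
      spatial_sill = 0.004, nugget = 0.003, noise_sd = 0.1
    )
  )
}

#' @export
print.campaign_truth <- function(x, ...) {
  cat(sprintf(
    "<campaign_truth> %d mass predictors; range %g m, sill %g, nugget %g; seed %d\n",
    length(x$beta), x$spatial_range_m, x$spatial_sill, x$nugget, x$seed
  ))
  invisible(x)
}
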