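# outcome ids exposed by the pipeline map to sample-table columns
.OUTCOME_COLS <- c(
  mass = "coarse", copper = "copper", zinc = "zinc",
  phosphorus = "phosphorus", silicon = "silicon"
)

#' Assemble a pipeline run configuration
#'
#' One configuration drives the whole simulate -> qc -> screen -> fit -> cv
#' -> predict -> summarize pipeline. Each stochastic stage derives its own
#' seed from the master seed by a fixed offset, so partial reruns are
#' reproducible stage by stage.
#'
#' @param seed Master integer seed.
#' @param n_sites Sites per city for the simulated campaign.
#' @param repeat_fraction Fraction of sites sampled in both seasons.
#' @param outcomes Outcome ids among `mass`, `copper`, `zinc`,
#'   `phosphorus`, `silicon`.
#' @param scopes Model scopes: `"city"` (one model per city) and/or
#'   `"pooled"`.
#' @param max_vars LASSO shortlist size (candidate terms offered to the
#'   exhaustive search).
#' @param max_params Parameter cap for enumerated subsets.
#' @param log_transform,drop_outliers_3sd Sensitivity switches; both off is
#'   the primary analysis.
#' @param grid Also export lattice predictions for each final model.
#' @param spacing_rural_m Rural lattice spacing (1000 or 2000 m).
#' @param clip_zero Truncate exported lattice predictions at zero.
#' @param truth Optional [campaign_truth()]; the default injects QC defects
#'   at moderate rates.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_sites = 40,
                       repeat_fraction = 1 / 3,
                       outcomes = "mass",
                       scopes = "city",
                       max_vars = 15,
                       max_params = 6,
                       log_transform = FALSE,
                       drop_outliers_3sd = FALSE,
                       grid = FALSE,
                       spacing_rural_m = 1000,
                       clip_zero = FALSE,
                       truth = NULL) {
  bad <- setdiff(outcomes, names(.OUTCOME_COLS))
  if (length(bad) > 0) abort(paste0("unknown outcome(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(scopes, c("city", "pooled"))
  if (length(bad) > 0) abort(paste0("unknown scope(s): ", paste(bad, collapse = ", ")))
  structure(
    list(
      seed = as.integer(seed), n_sites = n_sites,
      repeat_fraction = repeat_fraction, outcomes = outcomes, scopes = scopes,
      max_vars = max_vars, max_params = max_params,
      log_transform = log_transform, drop_outliers_3sd = drop_outliers_3sd,
      grid = grid, spacing_rural_m = spacing_rural_m, clip_zero = clip_zero,
      truth = truth
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Write campaign tables to disk
#'
#' Samples and covariates as UTF-8 CSV (missing values as empty fields) and
#' the truth ledger as a JSON sidecar.
#'
#' @param campaign A `campaign`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    covariates = file.path(dir, "covariates.csv"),
    ledger = file.path(dir, "truth_ledger.json")
  )
  readr::write_csv(campaign$samples, paths["samples"], na = "")
  readr::write_csv(campaign$covariates, paths["covariates"], na = "")
  jsonlite::write_json(
    list(
      beta = as.list(campaign$truth$beta),
      season_main = as.list(campaign$truth$season_main),
      season_interactions = as.list(campaign$truth$season_interactions),
      spatial = list(
        range_m = campaign$truth$spatial_range_m,
        sill = campaign$truth$spatial_sill, nugget = campaign$truth$nugget
      ),
      seed = campaign$truth$seed,
      defects = campaign$ledger$defects,
      n_truncated = as.list(campaign$ledger$n_truncated)
    ),
    paths["ledger"],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

# minimal GeoJSON point export (projected coordinates, not lon/lat)
.write_geojson_points <- function(df, path, props = setdiff(names(df), c("x_m", "y_m"))) {
  features <- purrr::map(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(df$x_m[i], df$y_m[i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
}

.fit_one_model <- function(data, outcome_col, scope, schema, cfg, seed) {
  xcols <- intersect(schema$name, names(data))
  scr <- screen_covariates(data[, xcols, drop = FALSE], data[[outcome_col]], schema)
  shortlist <- lasso_reduce(
    data, outcome_col, scr$survivors,
    scope = if (scope == "pooled") "pooled" else "city",
    max_vars = cfg$max_vars
  )
  specs <- enumerate_subsets(shortlist, max_params = cfg$max_params)
  sel <- select_best(specs, data, outcome_col, seed = seed)
  cv_lur <- cross_validate(data, outcome_col, sel$best_terms,
    method = "lur", seed = seed
  )
  cv_uk <- cross_validate(data, outcome_col, sel$best_terms,
    method = "uk", seed = seed
  )
  list(screening = scr, shortlist = shortlist, selection = sel,
       cv_lur = cv_lur, cv_uk = cv_uk)
}

#' Run the full modelling pipeline from one configuration
#'
#' Simulates a snapshot campaign (or consumes one passed explicitly),
#' applies quality control, screens covariates, shortlists with the LASSO,
#' exhaustively searches candidate models under 10-fold CV, evaluates the
#' winner with LUR and UK cross-validation, optionally exports lattice
#' predictions, and writes a stratified summary table. All artifacts land in
#' `out_dir` together with a manifest (config hash and stage seeds);
#' rerunning with the same configuration reproduces identical numeric
#' outputs.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @param out_dir Output directory.
#' @param campaign Optional pre-built `campaign` (skips simulation).
#' @return Invisibly, a list with the campaign, QC result, per-model fits
#'   and the artifact directory.
#' @export
run_pipeline <- function(config, out_dir, campaign = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = config$seed, selection = config$seed + 2000L)

  if (is.null(campaign)) {
    truth <- config$truth %||% campaign_truth(
      outlier_rate = 0.01,
      defect_rates = list(duration = 0.02, flow = 0.02, sulfur = 0.03, damaged = 0.01),
      duplicate_fraction = 0.05,
      seed = seeds$simulate
    )
    campaign <- generate_campaign(
      default_city_layouts(n_sites = config$n_sites),
      truth = truth,
      repeat_fraction = config$repeat_fraction
    )
  }
  write_campaign(campaign, out_dir)

  qc <- apply_qc(campaign$samples)
  jsonlite::write_json(
    c(as.list(glance(qc)), list(counts = qc$counts)),
    file.path(out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  analysis <- campaign_data(qc$valid, campaign$covariates)
  fits <- list()
  for (oc in config$outcomes) {
    col <- .OUTCOME_COLS[[oc]]
    adat <- apply_sensitivity(analysis, col,
      log_transform = config$log_transform,
      drop_outliers_3sd = config$drop_outliers_3sd
    )
    model_sets <- list()
    if ("city" %in% config$scopes) {
      for (ct in unique(adat$city)) {
        model_sets[[paste0(oc, "_", ct)]] <-
          list(data = filter(adat, .data$city == ct), scope = "city")
      }
    }
    if ("pooled" %in% config$scopes) {
      model_sets[[paste0(oc, "_pooled")]] <- list(data = adat, scope = "pooled")
    }
    for (nm in names(model_sets)) {
      ms <- model_sets[[nm]]
      fit <- .fit_one_model(ms$data, col, ms$scope, campaign$schema, config, seeds$selection)
      fits[[nm]] <- fit
      jsonlite::write_json(
        tidy(fit$screening),
        file.path(out_dir, paste0("screening_", nm, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      jsonlite::write_json(
        list(
          terms = fit$selection$best_terms,
          coefficients = as.list(fit$selection$coefficients),
          cv_rmse = fit$selection$cv_rmse, cv_r2 = fit$selection$cv_r2,
          seed = fit$selection$seed
        ),
        file.path(out_dir, paste0("selection_", nm, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      jsonlite::write_json(
        list(lur = as.list(glance(fit$cv_lur)), uk = as.list(glance(fit$cv_uk)),
             per_city_lur = fit$cv_lur$per_city, per_city_uk = fit$cv_uk$per_city),
        file.path(out_dir, paste0("eval_", nm, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      if (isTRUE(config$grid) && !is.null(campaign$generator_state)) {
        cities <- unique(ms$data$city)
        grid <- purrr::map(campaign$layouts[cities], prediction_grid,
          spacing_rural_m = config$spacing_rural_m
        ) |> bind_rows()
        gcov <- covariates_at(campaign, grid)
        gcov$season <- factor("winter", levels = .SEASONS)
        lur_full <- fit_lur(ms$data, col, fit$selection$best_terms)
        uk_full <- fit_uk(ms$data, col, fit$selection$best_terms)
        out <- grid |>
          mutate(
            pred_lur = predict(lur_full, gcov)$pred,
            pred_uk = predict(uk_full, gcov)$pred
          )
        if (isTRUE(config$clip_zero)) {
          out <- mutate(out,
            pred_lur = pmax(.data$pred_lur, 0),
            pred_uk = pmax(.data$pred_uk, 0)
          )
        }
        readr::write_csv(out, file.path(out_dir, paste0("grid_", nm, ".csv")), na = "")
        .write_geojson_points(
          out |> select("x_m", "y_m", "city", pred = "pred_lur") |> mutate(mode = "lur"),
          file.path(out_dir, paste0("grid_", nm, ".geojson"))
        )
      }
    }
  }

  qc_valid_with_coarse <- compute_coarse(qc$valid)
  readr::write_csv(
    summary_table(qc_valid_with_coarse),
    file.path(out_dir, "summary_table.csv"),
    na = ""
  )

  manifest <- list(
    config = unclass(config[setdiff(names(config), "truth")]),
    config_hash = rlang::hash(unclass(config)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("coarselur")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(campaign = campaign, qc = qc, fits = fits, dir = out_dir))
}
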