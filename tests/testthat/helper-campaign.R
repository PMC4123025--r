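# shared fixtures: all synthetic, built in code at test time

# a compact schema (two buffered categories + unbuffered + positional) for
# tests that do not need the full default library
small_schema <- function() {
  covariate_schema(dplyr::bind_rows(
    tibble::tibble(
      name = paste0("lu_dev_", c(50, 150, 300, 500, 1000, 5000), "m"),
      category = "lu_dev", buffer_radius_m = c(50, 150, 300, 500, 1000, 5000),
      positional = FALSE, source_vintage = "raster2000"
    ),
    tibble::tibble(
      name = paste0("rd_len_", c(100, 300, 1000, 3000), "m"),
      category = "rd_len", buffer_radius_m = c(100, 300, 1000, 3000),
      positional = FALSE, source_vintage = "other"
    ),
    tibble::tibble(
      name = c("dist_a1", "coord_x"),
      category = c("dist_a1", "coord_x"),
      buffer_radius_m = NA_real_,
      positional = c(FALSE, TRUE), source_vintage = "other"
    )
  ))
}

# a clean one-city campaign with no QC defects
quiet_campaign <- function(seed = 1, n_sites = 40, ...) {
  generate_campaign(
    city_layout("testville", n_sites = n_sites),
    truth = campaign_truth(seed = seed, ...)
  )
}

# analysis table (valid samples joined with covariates)
analysis_table <- function(campaign) {
  campaign_data(apply_qc(campaign$samples)$valid, campaign$covariates)
}

# truth ledger rows aligned to an analysis table
aligned_ledger <- function(campaign, analysis) {
  campaign$ledger$per_sample[
    match(analysis$sample_id, campaign$ledger$per_sample$sample_id),
  ]
}

# study conditions for selection-sanity checks: one city of 30 sites sampled
# in two seasons (~60 samples), 5 true predictors among 12 candidates, and
# residual variance set so the generator's oracle R2 is about 0.6
sanity_truth <- function(seed) {
  campaign_truth(
    seed = seed, season_main = c(testville = 0),
    season_interactions = c(lu_crops_3000m = 0),
    spatial_sill = 0.35, nugget = 0.35, noise_sd = 0.12
  )
}

sanity_decoys <- c(
  "lu_water_500m", "alu_residential_100m", "dist_a1", "pop_density_5000m",
  "ndvi_q25_1000m", "truck_len_1500m", "lu_trees_750m"
)

oracle_r2 <- function(campaign, analysis) {
  led <- aligned_ledger(campaign, analysis)
  1 - mean((analysis$coarse - led$lp_mass)^2) / stats::var(analysis$coarse)
}
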