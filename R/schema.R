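#' Build a covariate schema
#'
#' A covariate schema lists every geographic covariate the generator will
#' produce and the screening stages will see: its name, category (covariates
#' of one category at different buffer radii are nested aggregations of the
#' same underlying feature), buffer radius in meters (`NA` for unbuffered
#' covariates such as distances or coordinates), whether it is positional
#' (raw coordinates, preferentially dropped during correlation pruning), and
#' its source vintage (`"raster2000"` satellite land use is preferred over
#' `"aerial197x"` photography when the two are highly correlated).
#'
#' @param entries A data frame with columns `name`, `category`,
#'   `buffer_radius_m`, `positional`, `source_vintage`.
#' @return A tibble of class `covariate_schema`.
#' @export
covariate_schema <- function(entries) {
  entries <- as_tibble(entries)
  needed <- c("name", "category", "buffer_radius_m", "positional", "source_vintage")
  if (!all(needed %in% names(entries))) {
    abort(paste0("schema needs columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(entries$name)) {
    abort("covariate names must be unique")
  }
  class(entries) <- c("covariate_schema", class(entries))
  entries
}

# one schema block: a category expanded over its buffer radii
.schema_block <- function(category, radii, vintage = "other", positional = FALSE) {
  if (length(radii) == 1 && is.na(radii)) {
    tibble(
      name = category, category = category, buffer_radius_m = NA_real_,
      positional = positional, source_vintage = vintage
    )
  } else {
    tibble(
      name = paste0(category, "_", radii, "m"), category = category,
      buffer_radius_m = as.numeric(radii), positional = positional,
      source_vintage = vintage
    )
  }
}

#' Default covariate schema
#'
#' A covariate library patterned on the GIS variables typically offered to
#' coarse-PM land-use regressions: satellite-derived land-use percentages in
#' nested buffers from 50 m to 5 km, older aerial-photography land use at
#' 50-150 m, road and truck-route lengths in buffers, a dispersion-model
#' traffic surrogate at kilometer scales, population density, imperviousness,
#' vegetation-index quantiles, coarse-PM emissions, plus unbuffered distance
#' and positional covariates. Several hundred columns in total.
#'
#' @return A [covariate_schema()] tibble.
#' @export
default_covariate_schema <- function() {
  r_land <- c(50, 100, 150, 300, 400, 500, 750, 1000, 1500, 3000, 5000)
  sat_classes <- c(
    "lu_water", "lu_open_dev", "lu_low_dev", "lu_med_dev", "lu_high_dev",
    "lu_barren", "lu_trees", "lu_shrub", "lu_grass", "lu_pasture",
    "lu_crops", "lu_wetland"
  )
  aer_classes <- c(
    "alu_residential", "alu_commercial", "alu_industrial", "alu_urban_other",
    "alu_mixed_urban", "alu_mines", "alu_complexes", "alu_transitional"
  )
  blocks <- c(
    lapply(sat_classes, .schema_block, radii = r_land, vintage = "raster2000"),
    lapply(aer_classes, .schema_block, radii = c(50, 100, 150), vintage = "aerial197x"),
    lapply(c("rd_a1_len", "rd_a2_len", "rd_a3_len"), .schema_block, radii = r_land),
    list(.schema_block("truck_len",
      radii = c(100, 150, 300, 400, 500, 750, 1000, 1500, 3000, 5000, 10000, 15000)
    )),
    list(.schema_block("caline", radii = c(1500, 3000, 4500, 6000, 7500, 9000))),
    list(.schema_block("pop_density", radii = c(3000, 5000, 10000, 15000))),
    list(.schema_block("imperviousness",
      radii = c(50, 100, 150, 300, 400, 500, 750, 1000, 3000, 5000)
    )),
    list(.schema_block("ndvi_q25", radii = c(250, 500, 1000, 5000))),
    list(.schema_block("ndvi_q75", radii = c(250, 500, 1000, 5000))),
    list(.schema_block("emissions_pm_coarse", radii = c(3000, 15000, 30000))),
    lapply(
      c(
        "dist_a1", "dist_a2", "dist_a3", "dist_truck_route", "dist_railroad",
        "dist_airport", "dist_city_hall_main", "dist_city_hall_local"
      ),
      .schema_block,
      radii = NA
    ),
    list(
      .schema_block("coord_x", radii = NA, positional = TRUE),
      .schema_block("coord_y", radii = NA, positional = TRUE)
    )
  )
  covariate_schema(bind_rows(blocks))
}
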