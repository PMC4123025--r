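#' Simulate a mean-zero Gaussian field with exponential covariance
#'
#' Draws one realization of a spatially correlated Gaussian vector at the
#' given coordinates under `C(d) = sill * exp(-d / range) + nugget * 1{d=0}`.
#' A Cholesky factorization is used; if it fails numerically the diagonal is
#' jittered (escalating by factors of 10) and the retry is reported.
#'
#' @param coords Two-column matrix or data frame of projected coordinates (m).
#' @param range_m,sill,nugget Exponential-covariance parameters.
#' @return Numeric vector of field values, one per row of `coords`.
#' @export
sim_exp_field <- function(coords, range_m, sill, nugget = 0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0) abort("cannot simulate a field at zero sites")
  if (sill == 0 && nugget == 0) return(numeric(n))
  d <- as.matrix(dist(coords))
  sigma <- if (sill > 0 && range_m > 0) sill * exp(-d / range_m) else matrix(0, n, n)
  if (sill > 0 && range_m == 0) diag(sigma) <- sill
  diag(sigma) <- diag(sigma) + nugget
  jitter <- 0
  for (try in 0:6) {
    ch <- tryCatch(chol(sigma + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(ch)) {
      if (try > 0) {
        inform(sprintf("spatial covariance jittered by %.3g to reach positive definiteness", jitter))
      }
      return(drop(crossprod(ch, rnorm(n))))
    }
    jitter <- if (jitter == 0) 1e-10 * (sill + nugget + 1) else jitter * 10
  }
  abort("spatial covariance is not positive definite even after jittering")
}

# Latent-surface covariate generation: each category gets independent N(0,1)
# knot values scattered over the domain; the covariate at buffer radius r is a
# Gaussian-kernel average of the knots with bandwidth ~ r, so nested buffers of
# one category are positively correlated, more strongly the closer the radii.
.eval_category_latent <- function(sites_xy, radii, knots) {
  d2 <- outer(sites_xy[, 1], knots$kx, "-")^2 + outer(sites_xy[, 2], knots$ky, "-")^2
  vapply(radii, function(r) {
    h <- max(r, 300)
    w <- exp(-d2 / (2 * h^2))
    drop(w %*% knots$lat) / pmax(rowSums(w), 1e-12)
  }, numeric(nrow(sites_xy)))
}

# deterministic reference lattice used to calibrate latent surfaces so that
# sites and any later prediction grid see the identical transform
.reference_grid <- function(domain, n = 20) {
  gx <- seq(domain[1], domain[2], length.out = n)
  gy <- seq(domain[3], domain[4], length.out = n)
  as.matrix(expand.grid(x = gx, y = gy))
}

# draw the per-city random generator state: latent knots per buffered
# category (with calibration constants), feature points for distance
# covariates
.gen_city_state <- function(schema, layout, n_knots = 150) {
  ref <- .reference_grid(layout$domain)
  state <- list()
  for (cat in unique(schema$category)) {
    sub <- schema[schema$category == cat, ]
    if (all(is.na(sub$buffer_radius_m))) {
      if (cat %in% c("coord_x", "coord_y")) {
        state[[cat]] <- list(type = "coord", axis = if (cat == "coord_x") 1 else 2)
      } else {
        box <- if (cat == "dist_city_hall_main") layout$urban_core else layout$domain
        k <- if (grepl("^dist_city_hall", cat)) 1 else 3
        state[[cat]] <- list(
          type = "distance",
          px = runif(k, box[1], box[2]), py = runif(k, box[3], box[4])
        )
      }
    } else {
      knots <- list(
        kx = runif(n_knots, layout$domain[1], layout$domain[2]),
        ky = runif(n_knots, layout$domain[3], layout$domain[4]),
        lat = rnorm(n_knots)
      )
      zref <- .eval_category_latent(ref, sub$buffer_radius_m, knots)
      state[[cat]] <- list(
        type = "latent", knots = knots, radii = sub$buffer_radius_m,
        names = sub$name,
        center = colMeans(zref),
        scale = pmax(apply(zref, 2, sd), 1e-12)
      )
    }
  }
  state
}

# marginal transform of a standardized latent value into plausible units
.covariate_units <- function(z, category) {
  if (grepl("^(lu_|alu_)", category) || category == "imperviousness") {
    100 * stats::plogis(1.2 * z)                  # percent cover
  } else if (grepl("^(rd_|truck_)", category)) {
    500 * exp(0.7 * z)                            # road length, m
  } else if (category == "pop_density") {
    2000 * exp(0.8 * z)                           # persons / km^2
  } else if (grepl("^ndvi", category)) {
    2 * stats::plogis(1.5 * z) - 1                # NDVI, [-1, 1]
  } else if (grepl("^emissions", category)) {
    50 * exp(z)                                   # tons / year
  } else {
    z
  }
}

.point_dist <- function(sites_xy, px, py) {
  d2 <- outer(sites_xy[, 1], px, "-")^2 + outer(sites_xy[, 2], py, "-")^2
  sqrt(apply(d2, 1, min))
}

# evaluate the covariate matrix at arbitrary coordinates from a city state
.eval_city_covariates <- function(xy, state, schema) {
  out <- vector("list", length(state))
  names(out) <- names(state)
  for (cat in names(state)) {
    st <- state[[cat]]
    sub <- schema[schema$category == cat, ]
    if (st$type == "coord") {
      m <- matrix(xy[, st$axis], ncol = 1)
    } else if (st$type == "distance") {
      m <- matrix(.point_dist(xy, st$px, st$py), ncol = 1)
    } else {
      z <- .eval_category_latent(xy, st$radii, st$knots)
      z <- sweep(sweep(z, 2, st$center, "-"), 2, st$scale, "/")
      m <- apply(z, 2, .covariate_units, category = cat)
      if (nrow(xy) == 1) m <- matrix(m, nrow = 1)
    }
    colnames(m) <- sub$name
    out[[cat]] <- m
  }
  do.call(cbind, out)
}

#' Evaluate a campaign's covariate surfaces at new locations
#'
#' Covariates in a synthetic campaign are deterministic surfaces given the
#' campaign's generator state, so they can be evaluated at any point - for
#' example at a prediction lattice built with [prediction_grid()].
#'
#' @param campaign A `campaign` object.
#' @param points Data frame with `x_m`, `y_m` and `city`.
#' @return `points` with all covariate columns appended.
#' @export
covariates_at <- function(campaign, points) {
  points <- as_tibble(points)
  mats <- purrr::map(split(seq_len(nrow(points)), points$city), function(idx) {
    city <- points$city[idx[1]]
    st <- campaign$generator_state[[city]]
    if (is.null(st)) abort(paste0("no generator state for city ", city))
    cbind(idx = idx, .eval_city_covariates(
      cbind(points$x_m[idx], points$y_m[idx]), st, campaign$schema
    ))
  })
  mat <- do.call(rbind, mats)
  mat <- mat[order(mat[, "idx"]), , drop = FALSE]
  bind_cols(points, as_tibble(mat[, -1, drop = FALSE]))
}

# linear predictor + spatial residual + measurement noise for one outcome
.gen_outcome <- function(frame, xz, params, range_m, noise_model) {
  beta <- params$beta %||% numeric(0)
  missing <- setdiff(
    c(names(beta), names(params$season_interactions %||% numeric(0))),
    colnames(xz)
  )
  if (length(missing) > 0) {
    abort(paste0("truth coefficients name unknown covariates: ", paste(missing, collapse = ", ")))
  }
  summer <- as.numeric(frame$season == "summer")
  lp <- rep(params$intercept %||% 0, nrow(frame))
  if (length(beta) > 0) lp <- lp + drop(xz[, names(beta), drop = FALSE] %*% beta)
  sm <- params$season_main %||% numeric(0)
  if (length(sm) > 0) {
    offs <- ifelse(frame$city %in% names(sm), sm[frame$city], 0)
    lp <- lp + offs * summer
  }
  si <- params$season_interactions %||% numeric(0)
  if (length(si) > 0) {
    lp <- lp + drop(xz[, names(si), drop = FALSE] %*% si) * summer
  }

  # the smooth residual field is a long-term surface per city, shared by both
  # seasons; the nugget is independent micro-scale variation per sample
  spatial <- numeric(nrow(frame))
  sill <- params$spatial_sill %||% 0
  nug <- params$nugget %||% 0
  if (sill > 0) {
    for (grp in split(seq_len(nrow(frame)), frame$city)) {
      usite <- !duplicated(frame$site_id[grp])
      field <- sim_exp_field(cbind(frame$x_m[grp][usite], frame$y_m[grp][usite]),
                             range_m, sill, 0)
      names(field) <- frame$site_id[grp][usite]
      spatial[grp] <- field[frame$site_id[grp]]
    }
  }
  if (nug > 0) spatial <- spatial + rnorm(nrow(frame), 0, sqrt(nug))
  latent <- lp + spatial
  nsd <- params$noise_sd %||% 0
  y <- if (nsd == 0) {
    latent
  } else if (noise_model == "lognormal") {
    latent * exp(rnorm(length(latent), 0, nsd))
  } else {
    latent + rnorm(length(latent), 0, nsd)
  }
  n_trunc <- sum(y < 0)
  list(y = pmax(y, 0), lp = lp, spatial = spatial, n_truncated = n_trunc)
}

#' Generate a synthetic snapshot campaign with known ground truth
#'
#' Places monitoring sites uniformly over each city's domain, builds a
#' buffered covariate library from latent Gaussian surfaces (nested buffers of
#' one category are positively correlated by construction), and generates
#' coarse-PM mass and species concentrations as a sparse linear function of
#' campaign-standardized covariates, plus a per-city-season spatially
#' correlated Gaussian residual with exponential covariance, plus measurement
#' noise. PM10 is constructed as PM2.5 + coarse mass, so the downstream
#' subtraction recovers the generated coarse concentration exactly.
#' Quality-control defects (short durations, out-of-range flows, high coarse-
#' fraction sulfur, damaged filters, > 5 SD extreme concentrations) are
#' injected at the configured rates and recorded in the returned truth ledger.
#'
#' @param layouts A [city_layout()] or list of them.
#' @param schema A [covariate_schema()]; default [default_covariate_schema()].
#' @param truth A [campaign_truth()]; its `seed` fixes all randomness.
#' @param repeat_fraction Fraction of sites, per city, sampled in both
#'   seasons; the rest are sampled in one season only (alternating). The
#'   default 1 keeps every site in both seasons. Thinning happens before
#'   outcomes and QC defects are generated, so defects are injected into the
#'   samples actually "collected" (in particular, the one-extreme-per-stratum
#'   rule sees the final stratum sizes).
#'
#' @return An object of class `campaign`: a list with `samples` (tibble, one
#'   row per sample), `covariates` (tibble, one row per site), `schema`,
#'   `truth`, and `ledger` (injected defects, per-sample linear predictor and
#'   spatial residual, covariate standardization constants, truncation
#'   counts).
#' @export
#' @examples
#' camp <- generate_campaign(city_layout("demo", n_sites = 12),
#'   truth = campaign_truth(seed = 7)
#' )
#' dplyr::glimpse(camp$samples[1:6])
generate_campaign <- function(layouts,
                              schema = default_covariate_schema(),
                              truth = campaign_truth(),
                              repeat_fraction = 1) {
  if (inherits(layouts, "city_layout")) layouts <- list(layouts)
  if (length(layouts) == 0) abort("at least one city layout is required")
  if (nrow(schema) == 0) abort("the covariate schema is empty")
  set.seed(truth$seed)

  sites <- purrr::map(layouts, function(ly) {
    tibble(
      site_id = sprintf("%s_%03d", ly$city_id, seq_len(ly$n_sites)),
      city = ly$city_id,
      x_m = runif(ly$n_sites, ly$domain[1], ly$domain[2]),
      y_m = runif(ly$n_sites, ly$domain[3], ly$domain[4])
    )
  })
  states <- purrr::map(layouts, function(ly) .gen_city_state(schema, ly))
  names(states) <- purrr::map_chr(layouts, "city_id")
  covariates <- purrr::map2(sites, states, function(s, st) {
    bind_cols(
      tibble(site_id = s$site_id),
      as_tibble(.eval_city_covariates(cbind(s$x_m, s$y_m), st, schema))
    )
  }) |> bind_rows()
  sites <- bind_rows(sites)

  # campaign-wide standardization of the covariate matrix for the signal
  xmat <- as.matrix(covariates[, setdiff(names(covariates), "site_id")])
  mu <- colMeans(xmat)
  sig <- apply(xmat, 2, sd)
  xz <- sweep(xmat, 2, mu, "-")
  xz <- sweep(xz, 2, ifelse(sig < 1e-12, 1, sig), "/")
  rownames(xz) <- covariates$site_id

  # one sample per site per season, plus collocated duplicates
  frame <- tidyr::crossing(sites, season = factor(.SEASONS, levels = .SEASONS)) |>
    arrange(.data$city, .data$site_id, .data$season)
  if (repeat_fraction < 1) {
    frame <- repeat_subset(frame, repeat_fraction)
  }
  if (truth$duplicate_fraction > 0) {
    dup_rows <- which(runif(nrow(frame)) < truth$duplicate_fraction)
    dups <- frame[dup_rows, ] |> mutate(duplicate_flag = TRUE)
    frame <- bind_rows(mutate(frame, duplicate_flag = FALSE), dups)
  } else {
    frame$duplicate_flag <- FALSE
  }
  frame <- frame |>
    arrange(.data$city, .data$site_id, .data$season, .data$duplicate_flag) |>
    mutate(sample_id = paste0(
      .data$site_id, "_", .data$season, ifelse(.data$duplicate_flag, "_dup", "")
    ))
  xz_rows <- xz[frame$site_id, , drop = FALSE]

  mass <- .gen_outcome(
    frame, xz_rows,
    list(
      beta = truth$beta, intercept = truth$intercept,
      season_main = truth$season_main,
      season_interactions = truth$season_interactions,
      spatial_sill = truth$spatial_sill, nugget = truth$nugget,
      noise_sd = truth$noise_sd
    ),
    truth$spatial_range_m, truth$noise_model
  )
  species_out <- purrr::map(truth$species, function(sp) {
    .gen_outcome(frame, xz_rows, sp, truth$spatial_range_m, truth$noise_model)
  })

  n <- nrow(frame)
  samples <- frame |>
    mutate(
      pm25 = rlnorm(n, log(8), 0.25),
      coarse_true = mass$y,
      pm10 = .data$pm25 + .data$coarse_true,
      duration_days = runif(n, 13, 14.5),
      flow_deviation = runif(n, -0.1, 0.1),
      coarse_sulfur = runif(n, 0.02, 0.15),
      damaged = FALSE
    )
  for (sp in names(species_out)) samples[[sp]] <- species_out[[sp]]$y

  # --- QC defect injection (disjoint samples per defect class) ---
  available <- rep(TRUE, n)
  defects <- list()
  draw <- function(rate) {
    idx <- which(available & runif(n) < rate)
    available[idx] <<- FALSE
    idx
  }
  idx <- draw(truth$defect_rates$duration)
  samples$duration_days[idx] <- runif(length(idx), 5, 8)
  defects$duration <- idx
  idx <- draw(truth$defect_rates$flow)
  samples$flow_deviation[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
    runif(length(idx), 0.25, 0.4)
  defects$flow <- idx
  idx <- draw(truth$defect_rates$damaged)
  samples$damaged[idx] <- TRUE
  defects$damaged <- idx
  # extreme concentrations: at most one per city-season stratum, and only in
  # strata large enough (n >= 30) for a single point to exceed 5 stratum SDs
  out_idx <- integer(0)
  if (truth$outlier_rate > 0) {
    for (grp in split(seq_len(n), paste(samples$city, samples$season))) {
      cand <- grp[available[grp]]
      if (length(grp) < 30 || length(cand) == 0) next
      if (runif(1) < 1 - (1 - truth$outlier_rate)^length(grp)) {
        i <- if (length(cand) == 1) cand else sample(cand, 1)
        m <- mean(samples$coarse_true[grp])
        s <- sd(samples$coarse_true[grp])
        samples$coarse_true[i] <- m + 25 * max(s, 0.1)
        samples$pm10[i] <- samples$pm25[i] + samples$coarse_true[i]
        available[i] <- FALSE
        out_idx <- c(out_idx, i)
      }
    }
  }
  defects$outlier <- out_idx
  idx <- draw(truth$defect_rates$sulfur)
  samples$coarse_sulfur[idx] <- runif(length(idx), 0.25, 0.5)
  defects$sulfur <- idx

  defect_tbl <- purrr::imap(defects, function(ix, nm) {
    tibble(sample_id = samples$sample_id[ix], defect = nm)
  }) |> bind_rows()

  per_sample <- tibble(
    sample_id = samples$sample_id,
    lp_mass = mass$lp, spatial_mass = mass$spatial, coarse_true = samples$coarse_true
  )
  ledger <- list(
    defects = defect_tbl,
    per_sample = per_sample,
    standardization = tibble(name = colnames(xmat), mean = mu, sd = sig),
    n_truncated = c(
      mass = mass$n_truncated,
      purrr::map_int(species_out, function(o) as.integer(o$n_truncated))
    )
  )

  samples <- samples |>
    select(
      "sample_id", "site_id", "city", "season", "x_m", "y_m",
      "pm25", "pm10",
      dplyr::any_of(c("copper", "zinc", "phosphorus", "silicon")),
      "duration_days", "flow_deviation", "coarse_sulfur", "damaged",
      "duplicate_flag"
    )
  layouts_named <- setNames(layouts, purrr::map_chr(layouts, "city_id"))
  structure(
    list(
      samples = samples, covariates = covariates, schema = schema,
      truth = truth, ledger = ledger,
      layouts = layouts_named, generator_state = states
    ),
    class = "campaign"
  )
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(
    "<campaign> %d samples at %d sites in %d cities; %d covariates; %d injected defects\n",
    nrow(x$samples), dplyr::n_distinct(x$samples$site_id),
    dplyr::n_distinct(x$samples$city), ncol(x$covariates) - 1L,
    nrow(x$ledger$defects)
  ))
  invisible(x)
}

#' Thin a campaign to single-season sites with a repeated subset
#'
#' Field campaigns typically sample most homes in one season only, returning
#' to a fraction of them in the second season to assess temporal stability.
#' This keeps both seasons for `floor(fraction * n_sites)` randomly chosen
#' sites per city and a single season (alternating winter/summer) for the
#' rest.
#'
#' @param x A `campaign` or a samples tibble.
#' @param fraction Fraction of sites, per city, retaining both seasons.
#' @param seed Optional integer seed for the site draw.
#' @return Same type as `x`, with the samples table thinned.
#' @export
repeat_subset <- function(x, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1]")
  samples <- if (inherits(x, "campaign")) x$samples else as_tibble(x)
  if (!is.null(seed)) set.seed(seed)
  keep <- purrr::map(split(samples, samples$city), function(cs) {
    sites <- unique(cs$site_id)
    n_rep <- floor(fraction * length(sites))
    reps <- if (n_rep > 0) sample(sites, n_rep) else character(0)
    singles <- sample(setdiff(sites, reps))
    season_of <- setNames(
      rep(.SEASONS, length.out = length(singles)), singles
    )
    cs |>
      filter(.data$site_id %in% reps |
        as.character(.data$season) == season_of[.data$site_id])
  }) |> bind_rows()
  if (inherits(x, "campaign")) {
    x$samples <- keep
    x$ledger$defects <- filter(x$ledger$defects, .data$sample_id %in% keep$sample_id)
    x$ledger$per_sample <- filter(x$ledger$per_sample, .data$sample_id %in% keep$sample_id)
    x
  } else {
    keep
  }
}
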