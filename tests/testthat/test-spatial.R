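flat_data <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x_m = runif(n, 0, 20000), y_m = runif(n, 0, 20000),
    season = factor(sample(c("winter", "summer"), n, replace = TRUE),
      levels = c("winter", "summer")
    ),
    city = "c",
    x1 = rnorm(n), x2 = rnorm(n)
  )
}

test_that("noiseless OLS recovers the generating coefficients exactly", {
  df <- flat_data(50)
  df$y <- 2 + 1.5 * df$x1 - 0.7 * df$x2 + 0.3 * (df$season == "summer")
  fit <- fit_lur(df, "y", c("x1", "x2", "season"))
  expect_equal(unname(fit$coefficients), c(2, 1.5, -0.7, 0.3), tolerance = 1e-10)
  expect_equal(fit$residuals, rep(0, 50), tolerance = 1e-10)
})

test_that("the intercept-only model fits the mean", {
  df <- flat_data(30)
  df$y <- rnorm(30, 3)
  fit <- fit_lur(df, "y", character(0))
  expect_equal(unname(fit$coefficients), mean(df$y))
})

test_that("rank deficiency raises an error naming the collinear term", {
  df <- flat_data(30)
  df$x3 <- df$x1
  df$y <- rnorm(30)
  expect_error(fit_lur(df, "y", c("x1", "x3")), "x3")
})

test_that("coefficient scatter matches the closed-form OLS sampling SD", {
  # fixed design, known sigma: empirical SD of beta-hat over 50 draws should
  # match sigma * sqrt(diag((X'X)^-1)) within 20%
  df <- flat_data(500, seed = 2)
  x <- cbind(1, df$x1, df$x2)
  sigma <- 0.8
  se_theory <- sigma * sqrt(diag(solve(crossprod(x))))
  set.seed(3)
  betas <- vapply(1:100, function(i) {
    df$y <- 1 + 0.5 * df$x1 - 0.25 * df$x2 + rnorm(500, 0, sigma)
    fit_lur(df, "y", c("x1", "x2"))$coefficients
  }, numeric(3))
  emp_sd <- apply(betas, 1, sd)
  expect_true(all(abs(emp_sd - se_theory) / se_theory < 0.2))
  # and the reported analytic standard errors agree with the oracle
  df$y <- 1 + 0.5 * df$x1 - 0.25 * df$x2 + rnorm(500, 0, sigma)
  fit <- fit_lur(df, "y", c("x1", "x2"))
  expect_equal(unname(fit$std_errors), unname(se_theory) * fit$sigma / sigma,
    tolerance = 1e-8
  )
})

test_that("white-noise residuals fit as nugget-dominated variograms", {
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    xy <- cbind(runif(120, 0, 30000), runif(120, 0, 30000))
    vg <- fit_variogram(rnorm(120), xy)
    vg$nugget / (vg$nugget + vg$psill)
  }, numeric(1))
  expect_gt(median(frac), 0.8)
})

test_that("exponential variogram parameters are recovered from simulated fields", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    xy <- cbind(runif(500, 0, 30000), runif(500, 0, 30000))
    z <- sim_exp_field(xy, range_m = 2000, sill = 1, nugget = 0.1)
    vg <- fit_variogram(z, xy)
    c(abs(vg$range_m - 2000) / 2000, abs(vg$psill - 1))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.25)
  expect_lt(median(errs[2, ]), 0.25)
})

test_that("duplicated points give a finite variogram fit", {
  set.seed(6)
  xy <- cbind(runif(30, 0, 5000), runif(30, 0, 5000))
  z <- rnorm(30)
  vg <- fit_variogram(c(z, z), rbind(xy, xy))
  expect_true(is.finite(vg$nugget) && is.finite(vg$psill) && is.finite(vg$range_m))
  expect_error(fit_variogram(rnorm(25), matrix(1, 25, 2)), "coincident")
})

test_that("UK collapses to LUR exactly when the partial sill is zero", {
  df <- flat_data(40, seed = 7)
  df$y <- 1 + df$x1 + rnorm(40, 0, 0.5)
  vg0 <- structure(
    list(model = "exponential", nugget = 1, psill = 0, range_m = 1000),
    class = "variogram_fit"
  )
  uk <- fit_uk(df, "y", "x1", variogram = vg0)
  new <- flat_data(25, seed = 8)
  expect_identical(predict(uk, new)$pred, predict(uk$lur, new)$pred)
})

test_that("UK with zero nugget interpolates the training data exactly", {
  df <- flat_data(30, seed = 9)
  df$y <- 2 + 0.5 * df$x1 + sim_exp_field(cbind(df$x_m, df$y_m), 3000, 1, 0)
  vg <- structure(
    list(model = "exponential", nugget = 0, psill = 1, range_m = 3000),
    class = "variogram_fit"
  )
  uk <- fit_uk(df, "y", "x1", variogram = vg)
  pred <- predict(uk, df)$pred
  expect_equal(pred, unname(df$y), tolerance = 1e-6)
})

test_that("predictions are invariant to translating all coordinates", {
  df <- flat_data(40, seed = 10)
  df$y <- 1 + df$x1 + sim_exp_field(cbind(df$x_m, df$y_m), 2000, 0.5, 0.1)
  uk <- fit_uk(df, "y", "x1")
  new <- flat_data(15, seed = 11)
  p1 <- predict(uk, new)$pred
  shift <- function(d) dplyr::mutate(d, x_m = x_m + 5e4, y_m = y_m - 2e4)
  uk2 <- fit_uk(shift(df), "y", "x1")
  p2 <- predict(uk2, shift(new))$pred
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("UK beats LUR when the residual field is strongly spatial", {
  wins <- vapply(1:10, function(s) {
    tr <- campaign_truth(
      seed = 300 + s, spatial_range_m = 3000, spatial_sill = 1.5,
      nugget = 0.05, noise_sd = 0.05, species = list()
    )
    camp <- generate_campaign(
      city_layout("dense", 60, domain = c(0, 12000, 0, 12000)),
      truth = tr
    )
    an <- analysis_table(camp)
    terms <- names(tr$beta)
    u <- cross_validate(an, "coarse", terms, method = "uk", seed = s)
    l <- cross_validate(an, "coarse", terms, method = "lur", seed = s)
    u$cv_rmse < l$cv_rmse
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("the prediction lattice is dense in the core and sparse outside", {
  ly <- city_layout("g", 10, domain = c(0, 10000, 0, 10000))
  grid <- prediction_grid(ly)
  expect_true(all(c("x_m", "y_m", "city", "in_urban_core") %in% names(grid)))
  core <- dplyr::filter(grid, in_urban_core)
  rural <- dplyr::filter(grid, !in_urban_core)
  expect_equal(min(diff(sort(unique(core$x_m)))), 250)
  expect_equal(min(diff(sort(unique(rural$x_m)))), 1000)
  expect_true(all(rural$x_m < ly$urban_core[1] | rural$x_m > ly$urban_core[2] |
    rural$y_m < ly$urban_core[3] | rural$y_m > ly$urban_core[4]))
})

test_that("campaign covariate surfaces evaluate consistently at site locations", {
  camp <- quiet_campaign(seed = 44, n_sites = 15)
  pts <- camp$samples |>
    dplyr::distinct(site_id, city, x_m, y_m)
  re_eval <- covariates_at(camp, pts)
  for (nm in c("lu_trees_300m", "rd_a1_len_1000m", "dist_a1", "coord_x")) {
    orig <- camp$covariates[[nm]][match(pts$site_id, camp$covariates$site_id)]
    expect_equal(re_eval[[nm]], orig, tolerance = 1e-10)
  }
})
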