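test_that("variability filter drops columns whose 85th = 15th percentile", {
  x <- tibble::tibble(
    constant = rep(3, 12),
    rare_one = c(rep(0, 11), 1), # both quantiles 0 under linear interpolation
    increasing = 1:12
  )
  out <- variability_filter(x)
  expect_setequal(out$dropped, c("constant", "rare_one"))
  expect_named(out$x, "increasing")
  # oracle: the quantile convention itself
  q <- quantile(x$rare_one, c(0.15, 0.85), type = 7, names = FALSE)
  expect_identical(q[1], q[2])
})

test_that("buffer selection keeps the highest-|r| buffer per range", {
  set.seed(4)
  n <- 60
  y <- rnorm(n)
  mk <- function(r) y * r + rnorm(n) * sqrt(1 - r^2)
  x <- tibble::tibble(
    cat_50m = mk(0.1), cat_150m = mk(0.4), cat_300m = mk(0.3),
    cat_1000m = mk(0.2), cat_3000m = mk(0.6)
  )
  schema <- covariate_schema(tibble::tibble(
    name = names(x), category = "cat",
    buffer_radius_m = c(50, 150, 300, 1000, 3000),
    positional = FALSE, source_vintage = "other"
  ))
  out <- select_buffers(x, y, schema)
  # brute-force oracle over the short and long candidates
  short <- c("cat_50m", "cat_150m", "cat_300m")
  long <- c("cat_1000m", "cat_3000m")
  best_short <- short[which.max(abs(cor(as.matrix(x[short]), y)))]
  best_long <- long[which.max(abs(cor(as.matrix(x[long]), y)))]
  expect_setequal(names(out$x), c(best_short, best_long))
})

test_that("buffer ties break toward the smaller radius; singletons pass", {
  set.seed(5)
  n <- 8
  y <- rnorm(n)
  a <- rnorm(n)
  # exact |r| tie: the negated column has identical absolute correlation
  x <- tibble::tibble(a_100m = a, a_300m = -a, b_200m = rnorm(n))
  schema <- covariate_schema(tibble::tibble(
    name = names(x), category = c("a", "a", "b"),
    buffer_radius_m = c(100, 300, 200),
    positional = FALSE, source_vintage = "other"
  ))
  out <- select_buffers(x, y, schema)
  expect_true("a_100m" %in% names(out$x))
  expect_false("a_300m" %in% names(out$x))
  expect_true("b_200m" %in% names(out$x)) # only buffer in its range
})

test_that("correlation pruning keeps the preferred member of each group", {
  set.seed(7)
  n <- 50
  y <- rnorm(n)
  base <- rnorm(n)
  x <- tibble::tibble(
    raster_col = base, aerial_col = base, # identical pair
    lone = rnorm(n)
  )
  schema <- covariate_schema(tibble::tibble(
    name = names(x), category = names(x), buffer_radius_m = NA_real_,
    positional = FALSE,
    source_vintage = c("raster2000", "aerial197x", "other")
  ))
  out <- prune_correlated(x, y, schema)
  expect_true("raster_col" %in% names(out$x))
  expect_false("aerial_col" %in% names(out$x))
  expect_equal(out$pruned$kept_by, "raster_col")
})

test_that("pairs below the correlation threshold are both kept", {
  set.seed(8)
  n <- 2000
  a <- rnorm(n)
  b <- 0.8 * a + sqrt(1 - 0.8^2) * rnorm(n)
  x <- tibble::tibble(a = a, b = b)
  stopifnot(abs(cor(a, b)) < 0.85)
  schema <- covariate_schema(tibble::tibble(
    name = c("a", "b"), category = c("a", "b"), buffer_radius_m = NA_real_,
    positional = FALSE, source_vintage = "other"
  ))
  out <- prune_correlated(x, y = rnorm(n), schema)
  expect_setequal(names(out$x), c("a", "b"))
})

test_that("a correlated clique resolves to the member closest to the outcome", {
  # brute-force component resolution: three mutually correlated columns,
  # |r(x, y)| = 0.2, 0.5, 0.4 -> the 0.5 member is kept
  set.seed(9)
  n <- 400
  base <- rnorm(n)
  x <- tibble::tibble(
    u = base + rnorm(n, 0, 0.1),
    v = base + rnorm(n, 0, 0.1),
    w = base + rnorm(n, 0, 0.1)
  )
  y <- 0.2 * scale(x$u)[, 1] + 0.5 * scale(x$v)[, 1] + 0.4 * scale(x$w)[, 1]
  # engineer y so that v has the clearly largest |r|
  y <- scale(x$v)[, 1] + rnorm(n, 0, 0.8)
  schema <- covariate_schema(tibble::tibble(
    name = c("u", "v", "w"), category = c("u", "v", "w"),
    buffer_radius_m = NA_real_, positional = FALSE, source_vintage = "other"
  ))
  rs <- abs(cor(as.matrix(x), y))
  keeper <- rownames(rs)[which.max(rs)]
  out <- prune_correlated(x, y, schema)
  expect_equal(names(out$x), keeper)
  expect_equal(nrow(out$pruned), 2)
})

test_that("positional covariates are preferentially excluded", {
  set.seed(10)
  n <- 50
  base <- rnorm(n)
  x <- tibble::tibble(coord_x = base, road = base + rnorm(n, 0, 0.05))
  y <- x$coord_x + rnorm(n, 0, 0.1) # coordinate correlates *better*
  schema <- covariate_schema(tibble::tibble(
    name = c("coord_x", "road"), category = c("coord_x", "road"),
    buffer_radius_m = NA_real_, positional = c(TRUE, FALSE),
    source_vintage = "other"
  ))
  out <- prune_correlated(x, y, schema)
  expect_equal(names(out$x), "road")
})

test_that("the full cascade accounts for every column and lands at plausible size", {
  camp <- quiet_campaign(seed = 31, n_sites = 40)
  camp2 <- generate_campaign(
    default_city_layouts(40),
    truth = campaign_truth(seed = 31)
  )
  an <- analysis_table(camp2)
  xcols <- intersect(camp2$schema$name, names(an))
  scr <- screen_covariates(an[, xcols], an$coarse, camp2$schema)
  trace_names <- c(
    scr$survivors, scr$trace$variability_dropped,
    scr$trace$buffers_not_selected, scr$trace$correlation_pruned$name
  )
  expect_setequal(trace_names, xcols)
  expect_equal(length(trace_names), length(xcols)) # no double counting
  # a several-hundred-column library reduces to a few dozen survivors
  expect_gte(length(scr$survivors), 30)
  expect_lte(length(scr$survivors), 150)
})

test_that("screening decisions are invariant to positive rescaling", {
  camp <- quiet_campaign(seed = 32, n_sites = 50)
  an <- analysis_table(camp)
  xcols <- intersect(camp$schema$name, names(an))
  x <- an[, xcols]
  scr1 <- screen_covariates(x, an$coarse, camp$schema)
  x2 <- x
  set.seed(1)
  # powers of two keep the rescaling exact in floating point
  for (j in sample(ncol(x2), 40)) x2[[j]] <- x2[[j]] * 2^sample(-3:3, 1)
  scr2 <- screen_covariates(x2, an$coarse, camp$schema)
  expect_identical(scr1$survivors, scr2$survivors)
})
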