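winter_only <- function(df) {
  df$season <- factor("winter", levels = c("winter", "summer"))
  df
}

test_that("subset enumeration matches the binomial-sum oracle", {
  specs <- enumerate_subsets(paste0("x", 1:15), max_params = 6)
  expect_equal(length(specs), sum(choose(15, 0:6))) # 9949
  expect_equal(length(enumerate_subsets("x1")), 2)
  # oracle at other sizes
  for (p in c(3, 8)) {
    for (cap in c(2, 6)) {
      expect_equal(
        length(enumerate_subsets(paste0("v", 1:p), cap)),
        sum(choose(p, 0:min(cap, p)))
      )
    }
  }
})

test_that("interactions force their main effects into the model", {
  specs <- enumerate_subsets(c("x:season"), max_params = 6)
  keys <- vapply(specs, paste, character(1), collapse = "+")
  expect_true("season+x+x:season" %in% keys)
  expect_true("" %in% keys)
  # repair may exceed the cap: a 6-subset of interactions expands beyond 6
  specs2 <- enumerate_subsets(paste0("v", 1:6, ":season"), max_params = 6)
  sizes <- lengths(specs2)
  expect_gt(max(sizes), 6)
})

test_that("an infinite LASSO penalty gives empty support and the path shrinks it", {
  set.seed(11)
  n <- 200
  df <- winter_only(tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n), x5 = rnorm(n)
  ))
  df$y <- 2 * df$x1 - df$x2 + rnorm(n, 0, 0.5)
  out <- lasso_reduce(df, "y", paste0("x", 1:5), max_vars = 0)
  expect_length(out, 0)
  out_all <- lasso_reduce(df, "y", paste0("x", 1:5), max_vars = 50)
  expect_true(all(c("x1", "x2") %in% out_all))
})

test_that("the LASSO shortlist recovers a sparse true support", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    df <- as.data.frame(matrix(rnorm(n * 12), n, 12))
    names(df) <- paste0("x", 1:12)
    df <- winter_only(tibble::as_tibble(df))
    df$y <- 1.5 * df$x1 - 1.2 * df$x2 + 0.9 * df$x3 + rnorm(n, 0, 0.7)
    sel <- lasso_reduce(df, "y", paste0("x", 1:12), max_vars = 8)
    all(c("x1", "x2", "x3") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("intercept-only CV RMSE approximates the outcome SD", {
  set.seed(12)
  df <- winter_only(tibble::tibble(x1 = rnorm(300)))
  df$y <- rnorm(300, 5, 2)
  sel <- select_best(list(character(0)), df, "y", seed = 1)
  expect_equal(sel$cv_rmse, sd(df$y), tolerance = 0.1)
})

test_that("the generating model is selected in the noiseless limit", {
  set.seed(13)
  n <- 80
  df <- winter_only(tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n)
  ))
  df$y <- 1 + 2 * df$x1 - 3 * df$x2
  specs <- enumerate_subsets(paste0("x", 1:4), max_params = 3)
  sel <- select_best(specs, df, "y", seed = 2)
  expect_lt(sel$cv_rmse, 1e-10)
  expect_true(all(c("x1", "x2") %in% sel$best_terms))
  # ties at zero RMSE resolve to the most parsimonious spec
  expect_equal(sort(sel$best_terms), c("x1", "x2"))
})

test_that("selection is deterministic given data and seed", {
  camp <- quiet_campaign(seed = 41, n_sites = 30)
  an <- analysis_table(camp)
  specs <- enumerate_subsets(c(names(camp$truth$beta), "season"), max_params = 4)
  s1 <- select_best(specs, an, "coarse", seed = 99)
  s2 <- select_best(specs, an, "coarse", seed = 99)
  expect_identical(s1$best_terms, s2$best_terms)
  expect_identical(s1$cv_rmse, s2$cv_rmse)
  expect_identical(s1$fold, s2$fold)
})

test_that("adding pure-noise candidates does not buy meaningful CV gains", {
  deltas <- vapply(1:8, function(s) {
    camp <- generate_campaign(
      city_layout("g", 30),
      truth = sanity_truth(400 + s)
    )
    an <- analysis_table(camp)
    set.seed(s)
    an$pure_noise <- rnorm(nrow(an))
    base_cands <- names(camp$truth$beta)
    s0 <- select_best(enumerate_subsets(base_cands, 4), an, "coarse", seed = s)
    s1 <- select_best(
      enumerate_subsets(c(base_cands, "pure_noise"), 4), an, "coarse", seed = s
    )
    (s0$cv_rmse - s1$cv_rmse) / s0$cv_rmse
  }, numeric(1))
  expect_true(all(deltas >= 0)) # superset of specs can never do worse
  expect_lte(median(deltas), 0.02) # but the gain is only fold noise
})

test_that("rank-deficient candidates are discarded, not fitted", {
  set.seed(14)
  n <- 40
  df <- winter_only(tibble::tibble(x1 = rnorm(n)))
  df$x2 <- df$x1 # aliased
  df$y <- df$x1 + rnorm(n, 0, 0.1)
  sel <- select_best(
    list(c("x1"), c("x1", "x2")), df, "y",
    seed = 3
  )
  expect_equal(sel$n_discarded, 1L)
  expect_equal(sel$best_terms, "x1")
})

test_that("sensitivity switches off reproduce the primary data exactly", {
  camp <- quiet_campaign(seed = 42, n_sites = 25)
  an <- analysis_table(camp)
  expect_identical(
    apply_sensitivity(an, "coarse", log_transform = FALSE, drop_outliers_3sd = FALSE),
    an
  )
  logged <- apply_sensitivity(an, "coarse", log_transform = TRUE)
  expect_equal(logged$coarse, log(an$coarse[an$coarse > 0]))
  trimmed <- apply_sensitivity(an, "coarse", drop_outliers_3sd = TRUE)
  expect_lte(nrow(trimmed), nrow(an))
  z <- abs(an$coarse - mean(an$coarse)) / sd(an$coarse)
  expect_equal(nrow(trimmed), sum(z <= 3))
})
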