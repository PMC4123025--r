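test_that("coarse mass is the PM10 - PM2.5 difference, with negatives flagged", {
  out <- compute_coarse(tibble::tibble(pm10 = c(10, 4, 3), pm25 = c(4, 4, 4)))
  expect_equal(out$coarse, c(6, 0, -1))
  expect_equal(out$valid_pair, c(TRUE, TRUE, FALSE))
  # missing member of the pair: excluded from valid pairs, reported
  expect_message(
    out2 <- compute_coarse(tibble::tibble(pm10 = c(10, NA), pm25 = c(4, 4))),
    "missing"
  )
  expect_equal(out2$valid_pair, c(TRUE, FALSE))
})

clean_samples <- function(n, coarse = rep(5, n)) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)), site_id = paste0("site", seq_len(n)),
    city = "c", season = "winter",
    pm25 = 8, pm10 = 8 + coarse,
    duration_days = 14, flow_deviation = 0.05, coarse_sulfur = 0.1,
    damaged = FALSE
  )
}

test_that("each voiding rule fires at its threshold", {
  s <- clean_samples(5)
  s$duration_days[1] <- 8
  res <- apply_qc(s)
  expect_equal(nrow(res$valid), 4)
  expect_equal(res$samples$qc_status[1], "voided:duration")

  s <- clean_samples(5)
  s$coarse_sulfur[2] <- 0.25
  res <- apply_qc(s)
  expect_equal(res$samples$qc_status[2], "voided:sulfur")
  # exactly at the threshold is not voided (rule is strictly greater)
  s$coarse_sulfur[2] <- 0.2
  expect_equal(apply_qc(s)$samples$qc_status[2], "valid")

  s <- clean_samples(5)
  s$flow_deviation[3] <- -0.3
  expect_equal(apply_qc(s)$samples$qc_status[3], "voided:flow")

  s <- clean_samples(5)
  s$damaged[4] <- TRUE
  expect_equal(apply_qc(s)$samples$qc_status[4], "voided:damaged")

  s <- clean_samples(40, coarse = c(rep(5, 39), 5) + c(rnorm(39, 0, 0.1), 0))
  s$pm10[40] <- s$pm25[40] + 60 # far beyond 5 stratum SDs
  expect_equal(apply_qc(s)$samples$qc_status[40], "voided:outlier")
})

test_that("voiding reasons follow the fixed precedence order", {
  s <- clean_samples(5)
  s$duration_days[1] <- 5
  s$flow_deviation[1] <- 0.5
  s$coarse_sulfur[1] <- 0.9
  expect_equal(apply_qc(s)$samples$qc_status[1], "voided:duration")
  s$duration_days[1] <- 14
  expect_equal(apply_qc(s)$samples$qc_status[1], "voided:flow")
})

test_that("QC partitions the input and is idempotent on its valid output", {
  camp <- quiet_campaign(
    seed = 21, n_sites = 60,
    outlier_rate = 0.02,
    defect_rates = list(duration = 0.05, flow = 0.05, sulfur = 0.05, damaged = 0.02)
  )
  res <- apply_qc(camp$samples)
  expect_equal(nrow(res$valid) + sum(res$counts$n), nrow(camp$samples))
  again <- apply_qc(res$valid)
  expect_equal(nrow(again$valid), nrow(res$valid))
  expect_identical(again$valid$sample_id, res$valid$sample_id)
})

test_that("infinite thresholds pass every sample through", {
  camp <- quiet_campaign(
    seed = 22, n_sites = 30,
    defect_rates = list(duration = 0.2, flow = 0.2, sulfur = 0.2)
  )
  rules <- qc_rules(
    min_duration_days = 1e-9, flow_tolerance = Inf,
    outlier_sd = Inf, coarse_sulfur_max = Inf
  )
  res <- apply_qc(camp$samples, rules)
  expect_equal(nrow(res$valid), nrow(camp$samples))
})

test_that("the voided set matches the generator's defect ledger", {
  camp <- quiet_campaign(
    seed = 23, n_sites = 60,
    outlier_rate = 0.01,
    defect_rates = list(duration = 0.03, flow = 0.03, sulfur = 0.04, damaged = 0.01)
  )
  res <- apply_qc(camp$samples)
  voided <- res$samples$sample_id[res$samples$qc_status != "valid"]
  expect_setequal(voided, camp$ledger$defects$sample_id)
})

test_that("empty input produces an empty report", {
  res <- apply_qc(clean_samples(0))
  expect_equal(nrow(res$valid), 0)
  expect_equal(res$n_valid_pairs, 0L)
})

test_that("duplicate precision is the median relative absolute difference", {
  expect_equal(
    duplicate_precision(tibble::tibble(metric = "pm10", first = 10, second = 10))$precision,
    0
  )
  expect_equal(
    duplicate_precision(tibble::tibble(metric = "pm10", first = 9, second = 11))$precision,
    0.2
  )
  # zero-mean pairs are skipped and counted
  out <- duplicate_precision(tibble::tibble(
    metric = "x", first = c(1, 1), second = c(3, -1)
  ))
  expect_equal(out$n_skipped, 1)
  expect_equal(out$precision, 1)
})

test_that("duplicate precision tracks the simulated noise level", {
  prec <- vapply(1:50, function(s) {
    set.seed(s)
    a <- rlnorm(30, log(5), 0.05)
    b <- a * exp(rnorm(30, 0, 0.05))
    duplicate_precision(tibble::tibble(metric = "m", first = a, second = b))$precision
  }, numeric(1))
  expect_true(all(prec >= 0.01 & prec <= 0.12))
  expect_gt(median(prec), 0.03)
  expect_lt(median(prec), 0.09)
})
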