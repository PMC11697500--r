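# Independent variance-components oracle for ICC(A,1) built on stats::aov.
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b), subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- tab["subj", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + MSE + (2 / n) * (MSC - MSE))
}

toy_records <- function(n, seed = 1, jitter = 0) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    lm <- toy_landmarks(ey = 100 + 5 * i, mrd1_px = 15 + i, mrd2_px = 20 + i,
                        half_iicd = 45 + i, hpa_px = 55 + i)
    if (jitter > 0) lm <- landmark_set(lm + matrix(rnorm(20, 0, jitter), 10, 2))
    compute_measurements(lm, 0.2)
  })
  do.call(rbind, recs)
}

test_that("bilateral pooling emits two pairs per face, central one", {
  A <- toy_records(3); B <- toy_records(3, seed = 2, jitter = 1)
  pooled <- pool_bilateral(A, B)
  expect_equal(pooled$mrd1$n, 6)
  expect_equal(pooled$pfh$n, 6)
  expect_equal(pooled$ipd$n, 3)
  expect_equal(pooled$mrd1$pooling, "per-eye")
  expect_equal(pooled$ipd$pooling, "per-face")
  # one face: 2 MRD1 pairs, 1 IPD pair
  p1 <- pool_bilateral(A[1, ], B[1, ])
  expect_equal(p1$mrd1$n, 2)
  expect_equal(p1$ipd$n, 1)
  # flatten-and-average oracle
  expect_equal(mean(pooled$mrd1$a),
               mean(c(A$mrd1_right, A$mrd1_left)), tolerance = 1e-12)
  expect_error(pool_bilateral(A, B[1:2, ]), "misaligned")
})

test_that("mean absolute error matches its definition", {
  expect_equal(paired_mae(paired_measurements("x", 1:5, 1:5)),
               list(mae = 0, sd = 0))
  expect_equal(paired_mae(paired_measurements("x", c(1, 3), c(2, 1)))$mae, 1.5)
  set.seed(9)
  a <- rnorm(1000); b <- rnorm(1000)
  got <- paired_mae(paired_measurements("x", a, b))
  brute <- 0
  for (i in 1:1000) brute <- brute + abs(a[i] - b[i])
  expect_lt(abs(got$mae - brute / 1000), 1e-12)
  expect_error(paired_mae(paired_measurements("x", numeric(0), numeric(0))),
               "empty")
  expect_error(paired_measurements("x", c(1, NA), c(1, 2)), "missing")
})

test_that("Bland-Altman bias, limits and intervals follow the formulas", {
  p <- paired_measurements("x", c(1, 2, 3, 4), c(1, 2, 3, 4))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))

  # constant offset: bias = c, zero spread, zero-width intervals
  p2 <- paired_measurements("x", c(1, 2, 3, 4) + 0.7, c(1, 2, 3, 4))
  ba2 <- bland_altman(p2)
  expect_equal(ba2$bias, 0.7)
  expect_equal(ba2$sd, 0)
  expect_equal(ba2$bias_ci, c(0.7, 0.7))
  expect_equal(ba2$loa_upper_ci, c(0.7, 0.7))

  set.seed(12)
  a <- rnorm(40, 10, 2); b <- a - rnorm(40, 0.3, 0.5)
  ba3 <- bland_altman(paired_measurements("x", a, b))
  d <- a - b; n <- 40; s <- sd(d); tq <- qt(0.975, n - 1)
  expect_equal(ba3$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba3$loa_upper, mean(d) + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba3$bias_ci[2], mean(d) + tq * s / sqrt(n), tolerance = 1e-12)
  expect_equal(ba3$loa_lower_ci[1],
               mean(d) - 1.96 * s - tq * s * sqrt(3 / n), tolerance = 1e-12)
  expect_equal(nrow(ba3$plot_data), n)
  expect_error(bland_altman(paired_measurements("x", 1:2, 2:3)), "at least 3")
})

test_that("mae dominates the absolute bias", {
  set.seed(30)
  for (i in 1:20) {
    a <- rnorm(25); b <- rnorm(25)
    pm <- paired_measurements("x", a, b)
    expect_gte(paired_mae(pm)$mae + 1e-15, abs(bland_altman(pm)$bias))
  }
})

test_that("ICC(A,1) matches the ANOVA oracle and closed forms", {
  # identical raters with subject variance
  r <- icc_absolute_single(paired_measurements("x", 1:6, 1:6))
  expect_equal(r$icc, 1)

  # constant half-unit offset: closed form 7 / 7.25
  r2 <- icc_absolute_single(paired_measurements("x", 1:6, 1:6 + 0.5))
  expect_equal(r2$icc, 7 / 7.25, tolerance = 1e-12)
  expect_equal(r2$icc, icc_aov_oracle(1:6, 1:6 + 0.5), tolerance = 1e-8)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- rnorm(n, 10, 3)
    b <- a + rnorm(n, 0.2, 0.6)
    r <- icc_absolute_single(paired_measurements("x", a, b))
    expect_equal(r$icc, icc_aov_oracle(a, b), tolerance = 1e-8)
    expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
  }

  expect_error(icc_absolute_single(
    paired_measurements("x", rep(1, 5), rep(1, 5))), "degenerate")
})

test_that("reliability bands use the 0.5/0.75/0.9 thresholds", {
  band <- periometry:::icc_band
  expect_equal(band(0.49), "poor")
  expect_equal(band(0.6), "moderate")
  expect_equal(band(0.843), "good")
  expect_equal(band(0.906), "excellent")
})

test_that("absolute agreement penalises a single-rater offset only", {
  set.seed(19)
  a <- rnorm(30, 5, 2)
  b <- a + rnorm(30, 0, 0.3)
  base <- icc_absolute_single(paired_measurements("x", a, b))$icc
  both <- icc_absolute_single(paired_measurements("x", a + 3, b + 3))$icc
  one <- icc_absolute_single(paired_measurements("x", a + 3, b))$icc
  expect_equal(both, base, tolerance = 1e-10)
  expect_lt(one, base)
})

test_that("the agreement report aggregates all three statistics per metric", {
  A <- toy_records(6)
  B <- toy_records(6, seed = 5, jitter = 1.5)
  rep <- agreement_report(A, B)
  expect_setequal(rep$summary$metric,
                  c("mrd1", "mrd2", "pfh", "hpa", "ipd", "iicd", "oicd"))
  expect_true(all(rep$summary$n == ifelse(
    rep$summary$metric %in% c("mrd1", "mrd2", "pfh", "hpa"), 12, 6)))
  expect_true(all(rep$summary$icc >= -1 & rep$summary$icc <= 1))
  expect_true(all(rep$summary$loa_lower <= rep$summary$bias &
                    rep$summary$bias <= rep$summary$loa_upper))
  expect_true(all(rep$summary$mae + 1e-12 >= abs(rep$summary$bias)))
})
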