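test_that("early features follow the 14-day window arithmetic", {
  # two records: day 1 at 90 kg, day 14 at 88.6 kg -> X1 = 0.1 kg/day, X2 = 2
  rec <- make_records("a", c(1, 14, 50, 80, 100), c(90, 88.6, 87, 86, 85))
  ef <- early_features(rec)
  expect_equal(ef$X1, 0.1)
  expect_equal(ef$X2, 2)
  expect_equal(ef$X3, 99)
  expect_false(ef$sparse_window)

  # a single record in the window: X1 = 0 and the sparse flag is set
  rec1 <- make_records("b", c(1, 20, 50, 80, 100), c(90, 88, 87, 86, 85))
  ef1 <- early_features(rec1)
  expect_equal(ef1$X1, 0)
  expect_true(ef1$sparse_window)

  # the last record *within* the window is used, not the nearest to day 14
  rec2 <- make_records("c", c(1, 10, 16, 80, 100), c(90, 89.3, 88, 86, 85))
  ef2 <- early_features(rec2)
  expect_equal(ef2$X1, (90 - 89.3) / 14)
})

test_that("window record counts match a brute-force oracle on random series", {
  set.seed(501)
  for (i in 1:20) {
    days <- sort(sample(1:200, 30))
    rec <- make_records("r", days, 90 - 0.01 * days)
    ef <- early_features(rec)
    expect_equal(ef$X2, sum(days <= min(days) + 13))
    expect_equal(ef$X3, max(days) - min(days))
  }
})

test_that("two-category fits match glm() binary logistic regression exactly", {
  set.seed(502)
  n <- 400
  X1 <- rnorm(n, 0.08, 0.06)
  X2 <- 1 + rpois(n, 6)
  X3 <- runif(n, 77, 364)
  eta <- 1 - 8 * X1 + 0.05 * X2 + 0.002 * X3
  y <- ifelse(runif(n) < plogis(eta), "4-7", "1")
  feats <- tibble::tibble(participant_id = as.character(1:n), X1 = X1, X2 = X2, X3 = X3)
  asn <- tibble::tibble(participant_id = as.character(1:n), consolidated = y)

  fit <- fit_pattern_multinom(feats, asn, reference = "1")
  ref <- stats::glm(I(y == "4-7") ~ X1 + X2 + X3, family = stats::binomial())
  expect_equal(unname(coef(fit)[, "4-7"]), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$std_errors[, "4-7"]),
    unname(summary(ref)$coefficients[, "Std. Error"]),
    tolerance = 1e-4
  )
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("fitted probabilities normalize and odds ratios are exact transforms", {
  set.seed(503)
  true_b <- cbind(
    "2" = c(0.2, -2, 0.02, 0.001),
    "3" = c(-0.5, -1, 0.05, 0.004),
    "4-7" = c(0.5, -6, 0.00, 0.000)
  )
  dat <- simulate_prediction_cohort(n = 500, coefs = true_b, seed = 503)
  feats <- tibble::tibble(
    participant_id = as.character(seq_len(nrow(dat))),
    X1 = dat$X1, X2 = dat$X2, X3 = dat$X3
  )
  asn <- tibble::tibble(
    participant_id = feats$participant_id,
    consolidated = as.character(dat$label)
  )
  fit <- fit_pattern_multinom(feats, asn)

  P <- predict(fit, feats)
  expect_true(all(abs(rowSums(P) - 1) <= 1e-10))
  expect_true(all(P >= 0))

  td <- tidy(fit)
  expect_equal(td$OR, exp(td$estimate))
  z <- qnorm(0.975)
  expect_equal(td$conf.low, exp(td$estimate - z * td$std.error))
  expect_equal(td$conf.high, exp(td$estimate + z * td$std.error))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$df, 12)
})

test_that("duplicating every observation leaves point estimates unchanged", {
  set.seed(504)
  true_b <- cbind("2" = c(0.3, -3, 0.03, 0.002))
  dat <- simulate_prediction_cohort(n = 300, coefs = true_b, seed = 504)
  feats <- tibble::tibble(
    participant_id = as.character(seq_len(nrow(dat))),
    X1 = dat$X1, X2 = dat$X2, X3 = dat$X3
  )
  asn <- tibble::tibble(
    participant_id = feats$participant_id,
    consolidated = as.character(dat$label)
  )
  fit1 <- fit_pattern_multinom(feats, asn)
  feats2 <- dplyr::bind_rows(feats, dplyr::mutate(feats, participant_id = paste0("d", participant_id)))
  asn2 <- dplyr::bind_rows(asn, dplyr::mutate(asn, participant_id = paste0("d", participant_id)))
  fit2 <- fit_pattern_multinom(feats2, asn2)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-5)
  expect_true(all(fit2$std_errors < fit1$std_errors))
})

test_that("perfect separation is surfaced, not silently returned", {
  n <- 60
  X1 <- c(seq(-0.2, -0.01, length.out = n / 2), seq(0.01, 0.2, length.out = n / 2))
  feats <- tibble::tibble(
    participant_id = as.character(1:n),
    X1 = X1, X2 = rep(5, n), X3 = rep(100, n)
  )
  asn <- tibble::tibble(
    participant_id = feats$participant_id,
    consolidated = rep(c("1", "2"), each = n / 2)
  )
  expect_warning(fit <- fit_pattern_multinom(feats, asn), "separation|converge")
  expect_true(fit$separation_suspected || !fit$converged)
})

test_that("degenerate category structures are errors", {
  feats <- tibble::tibble(participant_id = as.character(1:10), X1 = rnorm(10), X2 = 1:10, X3 = 1:10)
  one_cat <- tibble::tibble(participant_id = feats$participant_id, consolidated = rep("1", 10))
  expect_error(fit_pattern_multinom(feats, one_cat), ">= 2 categories")
  tiny <- tibble::tibble(
    participant_id = feats$participant_id,
    consolidated = c(rep("1", 9), "2")
  )
  expect_error(fit_pattern_multinom(feats, tiny), ">= 2")
  expect_error(fit_pattern_multinom(feats, one_cat, reference = "9"), "reference")
})
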