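test_that("criteria arithmetic matches the annotated rules", {
  # linear fit with a 10 kg decline: C1.1 "+", C1.2 "-"
  f1 <- tibble::tibble(
    participant_id = "a", degree = 1L, beta0 = 90, beta1 = -10 / 119,
    beta2 = NA_real_, beta3 = NA_real_, t1 = 1, tz = 120, ttotal = 119,
    y_start = 90, y_end = 80, nadir = NA_real_, y_nadir = NA_real_,
    D = NA_real_, x1 = NA_real_, x2 = NA_real_, y_x1 = NA_real_, y_x2 = NA_real_
  )
  cr <- evaluate_criteria(f1)
  expect_true(cr$value[cr$criterion == "C1.1"])
  expect_false(cr$value[cr$criterion == "C1.2"])

  # quadratic with both landmark differences below K = 1: C2.1 "-" (flat)
  f2 <- f1
  f2$degree <- 2L
  f2$beta1 <- -0.01
  f2$beta2 <- 5e-5
  f2$nadir <- 100
  f2$y_nadir <- 89.5
  f2$y_start <- 90
  f2$y_end <- 89.9
  cr2 <- evaluate_criteria(f2)
  expect_false(cr2$value[cr2$criterion == "C2.1"])
  expect_true(cr2$value[cr2$criterion == "C2.2"])

  # cubic plateau width: x2 - x1 = 40 > ttotal/3 = 30 -> C3.7 "+"
  f3 <- f1
  f3$degree <- 3L
  f3$beta1 <- 1
  f3$beta2 <- -1
  f3$beta3 <- 0.01
  f3$ttotal <- 90
  f3$D <- 4
  f3$x1 <- 20
  f3$x2 <- 60
  f3$y_x1 <- 92
  f3$y_x2 <- 84
  cr3 <- evaluate_criteria(f3)
  expect_true(cr3$value[cr3$criterion == "C3.7"])
  # undefined-landmark criteria are NA, never a silent FALSE
  f3na <- f3
  f3na$D <- -1
  f3na$x1 <- NA_real_
  f3na$x2 <- NA_real_
  f3na$y_x1 <- NA_real_
  f3na$y_x2 <- NA_real_
  cr3na <- evaluate_criteria(f3na)
  expect_true(is.na(cr3na$value[cr3na$criterion == "C3.7"]))
  expect_true(is.na(cr3na$value[cr3na$criterion == "C3.1"]))
})

test_that("canonical shapes classify to their expected patterns", {
  days120 <- seq(1, 121, by = 4)
  # noise-free linear decline of 0.08 kg/day over 120 days
  expect_equal(classify_records(poly_records("p1", c(90, -0.08), days120))$pattern, 1L)
  # convex quadratic with interior minimum at day 70 of 140
  days140 <- seq(1, 141, by = 4)
  quad <- c(95, -2 * 8 / 70, 8 / 70^2) # nadir at t = 70, depth 8 kg
  expect_equal(classify_records(poly_records("p3", quad, days140))$pattern, 3L)
  # constant series
  expect_equal(classify_records(make_records("p6", days120, rep(85, length(days120))))$pattern, 6L)
  # linear rise
  expect_equal(classify_records(poly_records("p7", c(85, 0.03), days120))$pattern, 7L)
})

test_that("each noise-free archetype is a fixed point of the pipeline", {
  recs <- purrr::map(1:7, function(p) {
    archetype_records(paste0("arch", p), p, duration = 133, w0 = 89.4, regular_by = 2)
  }) |> purrr::list_rbind()
  asn <- classify_records(recs)
  asn$truth <- as.integer(sub("arch", "", asn$participant_id))
  expect_equal(asn$pattern, asn$truth)
  # the pattern-to-model routing is as designed: 1 and 7 from m1, 3 from m2,
  # 2 and 5 from m3
  expect_equal(asn$model[asn$truth == 1], "m1")
  expect_equal(asn$model[asn$truth == 7], "m1")
  expect_equal(asn$model[asn$truth == 3], "m2")
  expect_equal(asn$model[asn$truth == 2], "m3")
  expect_equal(asn$model[asn$truth == 5], "m3")
})

test_that("the tree is total and deterministic over randomized feature inputs", {
  set.seed(401)
  mk_feat <- function(i) {
    degree <- sample(1:3, 1)
    ttotal <- runif(1, 77, 364)
    b <- c(runif(1, 60, 120), rnorm(1, 0, 0.1), rnorm(1, 0, 1e-3), rnorm(1, 0, 1e-5))
    if (degree < 3) b[4] <- NA
    if (degree < 2) b[3] <- NA
    cf <- b[!is.na(b)]
    y_start <- predict_poly(cf, 1)
    y_end <- predict_poly(cf, ttotal + 1)
    nadir <- y_nadir <- D <- x1 <- x2 <- y_x1 <- y_x2 <- NA_real_
    if (degree == 2 && b[3] != 0) {
      nadir <- quadratic_nadir(b[2], b[3])
      y_nadir <- predict_poly(cf, nadir)
    }
    if (degree == 3 && b[4] != 0) {
      v <- cubic_vertices(b[2], b[3], b[4])
      D <- v$D
      x1 <- v$x1
      x2 <- v$x2
      if (!is.na(x1)) {
        y_x1 <- predict_poly(cf, x1)
        y_x2 <- predict_poly(cf, x2)
      }
    }
    tibble::tibble(
      participant_id = paste0("r", i), degree = degree,
      beta0 = b[1], beta1 = b[2], beta2 = b[3], beta3 = b[4],
      t1 = 1, tz = ttotal + 1, ttotal = ttotal,
      y_start = y_start, y_end = y_end, nadir = nadir, y_nadir = y_nadir,
      D = D, x1 = x1, x2 = x2, y_x1 = y_x1, y_x2 = y_x2
    )
  }
  feats <- purrr::map(1:300, mk_feat) |> purrr::list_rbind()
  a1 <- classify_trajectories(feats)
  a2 <- classify_trajectories(feats)
  expect_true(all(a1$pattern %in% 1:7))
  expect_identical(a1, a2)
  expect_false(any(is.na(a1$pattern)))
})

test_that("consolidation relabels 4-7 without changing counts", {
  x <- c(rep(1L, 10), 4L, 4L, 7L)
  cons <- consolidate_patterns(x)
  expect_equal(unname(table(cons)["1"]), 10)
  expect_equal(unname(table(cons)["4-7"]), 3)
  # identity when nothing >= 4 is present
  y <- c(1L, 2L, 3L, 3L)
  expect_equal(as.character(consolidate_patterns(y)), as.character(y))
  # counting oracle on a random label vector
  set.seed(402)
  z <- sample(1:7, 500, replace = TRUE)
  cz <- table(consolidate_patterns(z))
  expect_equal(unname(cz["4-7"]), sum(z >= 4))
  expect_equal(unname(cz["2"]), sum(z == 2))
})

test_that("pattern summaries compute losses and flag separated groups vs pattern 1", {
  # single participant arithmetic: 90 -> 81 kg is 9 kg, 10%
  rec <- make_records("solo", c(1, 40, 80, 100, 120), c(90, 88, 85, 83, 81))
  asn <- tibble::tibble(
    participant_id = "solo", model = "m1", pattern = 1L,
    consolidated = consolidate_patterns(1L), criteria_path = ""
  )
  s <- summarize_patterns(rec, asn)
  loss <- s$per_participant
  expect_equal(loss$weight_loss_kg, 9)
  expect_equal(loss$weight_loss_pct, 10)
  expect_null(s$anova) # one group: tests skipped

  # constructed separation: pattern-1 members lose ~10%, pattern-6 ~0%
  set.seed(403)
  recs <- dplyr::bind_rows(
    purrr::map(1:8, function(i) {
      archetype_records(paste0("a", i), 1, duration = 120, w0 = 90, noise_sd = 0.3)
    }),
    purrr::map(1:8, function(i) {
      archetype_records(paste0("b", i), 6, duration = 120, w0 = 90, noise_sd = 0.3)
    })
  )
  asn2 <- classify_records(recs)
  s2 <- summarize_patterns(recs, asn2, consolidated = FALSE)
  tk <- s2$tukey[s2$tukey$metric == "weight_loss_pct", ]
  expect_true(any(tk$significant))
  an <- s2$anova[s2$anova$metric == "weight_loss_pct", ]
  expect_lt(an$p_value, 0.001)
})

test_that("identical groups produce no spurious Tukey flags", {
  set.seed(404)
  mk <- function(id) {
    make_records(id, seq(1, 101, by = 10), 90 - 0.05 * seq(0, 100, by = 10) + rnorm(11, 0, 0.2))
  }
  recs <- dplyr::bind_rows(purrr::map(paste0("u", 1:6), mk))
  asn <- tibble::tibble(
    participant_id = paste0("u", 1:6), model = "m1",
    pattern = rep(c(1L, 2L), 3),
    consolidated = consolidate_patterns(rep(c(1L, 2L), 3)), criteria_path = ""
  )
  s <- summarize_patterns(recs, asn)
  expect_false(any(s$tukey$significant[s$tukey$metric == "weight_loss_kg"]))
})
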