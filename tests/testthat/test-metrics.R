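test_that("auroc matches hand-computed and degenerate cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 0, 0)), 0.5)
  # pairs: (.35,.1)+, (.35,.4)-, (.8,.1)+, (.8,.4)+ -> 3/4
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "at least one event")
})

test_that("auroc equals all-pairs enumeration on small random cohorts", {
  for (seed in 1:20) {
    co <- make_toy_cohort(sample(4:12, 1), seed)
    co$risk <- round(co$risk, 1) # force ties
    expect_equal(auroc(co$risk, co$outcome), brute_auroc(co$risk, co$outcome))
  }
})

test_that("auroc is invariant under strictly increasing transforms", {
  co <- make_toy_cohort(50, 99)
  base <- auroc(co$risk, co$outcome)
  expect_equal(auroc(qlogis(co$risk), co$outcome), base)
  expect_equal(auroc(co$risk^3, co$outcome), base)
  expect_equal(auroc(2.5 * co$risk, co$outcome), base)
})

test_that("calibration ratio matches hand computations and scales inversely", {
  expect_equal(calibration_ratio(c(1, 0, 0, 0), rep(0.2, 4)), 1.25)
  expect_equal(calibration_ratio(rep(c(1, 0), c(1, 9)), rep(0.1, 10)), 1.0)
  co <- make_toy_cohort(40, 5)
  base <- calibration_ratio(co$outcome, co$risk)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(calibration_ratio(co$outcome, k * co$risk), base / k)
  }
  expect_error(calibration_ratio(c(1, 0), c(0, 0)), "positive")
})

test_that("categorize uses half-open intervals with the boundary upward", {
  expect_equal(categorize(c(0.05, 0.20, 0.35), 0.20), c(1L, 2L, 2L))
  expect_equal(categorize(0.10, c(0.10, 0.20)), 2L)
  expect_equal(categorize(c(0, 0.999), c(0.10, 0.20)), c(1L, 3L))
  set.seed(8)
  x <- runif(1000)
  frac_low <- mean(categorize(x, 0.5) == 1L)
  expect_lt(abs(frac_low - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(categorize(0.5, c(0.3, 0.3)), "strictly increasing")
  expect_error(categorize(0.5, numeric(0)), "cutpoints")
})

test_that("reclassification table cross-tabulates and conserves strata", {
  old <- c(0.10, 0.15, 0.25, 0.05, 0.30)
  new <- c(0.22, 0.35, 0.25, 0.21, 0.30) # first two events move up, one
  out <- c(1, 1, 1, 0, 0)                # non-event moves up
  tab <- reclassification_table(old, new, out, 0.20)
  expect_equal(tab$events["1", "2"], 2L)
  expect_equal(tab$nonevents["1", "2"], 1L)
  expect_equal(sum(tab$events), 3L)
  expect_equal(sum(tab$nonevents), 2L)

  # identity reclassification -> purely diagonal tables
  co <- make_toy_cohort(30, 2)
  tab2 <- reclassification_table(co$risk, co$risk, co$outcome, c(0.3, 0.6))
  expect_equal(sum(tab2$events) + sum(tab2$nonevents), 30L)
  expect_equal(sum(tab2$events[upper.tri(tab2$events)]), 0L)
  expect_equal(sum(tab2$events[lower.tri(tab2$events)]), 0L)
  expect_equal(sum(tab2$nonevents[upper.tri(tab2$nonevents)]), 0L)

  # marginals conserve stratum counts under arbitrary movement
  co$new <- pmin(1, co$risk * 1.8)
  tab3 <- reclassification_table(co$risk, co$new, co$outcome, c(0.2, 0.5))
  expect_equal(sum(tab3$events), sum(co$outcome == 1))
  expect_equal(sum(tab3$nonevents), sum(co$outcome == 0))
})

test_that("nri matches hand-scored examples", {
  co <- make_toy_cohort(25, 4)
  expect_equal(nri(co$risk, co$risk, co$outcome, 0.2)$value, 0)

  # 4 events of which 2 move up; 6 non-events of which 3 move up; no
  # downward movement: (2/4) - (3/6) = 0
  old <- c(0.15, 0.18, 0.25, 0.10, 0.15, 0.19, 0.18, 0.05, 0.30, 0.25)
  new <- c(0.25, 0.22, 0.25, 0.10, 0.21, 0.23, 0.24, 0.05, 0.30, 0.25)
  out <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  fit <- nri(old, new, out, 0.2)
  expect_equal(fit$value, 0)
  expect_equal(unname(fit$components["p_up_event"]), 0.5)
  expect_equal(unname(fit$components["p_down_event"]), 0)
  expect_equal(unname(fit$components["p_up_nonevent"]), 0.5)

  # 1 of 2 events up, neither non-event moves -> 0.5
  fit2 <- nri(c(0.15, 0.25, 0.10, 0.30), c(0.25, 0.25, 0.10, 0.30),
              c(1, 1, 0, 0), 0.2)
  expect_equal(fit2$value, 0.5)
})

test_that("nri equals per-subject brute-force scoring, both estimators", {
  for (seed in 21:40) {
    co <- make_toy_cohort(sample(5:12, 1), seed)
    set.seed(seed + 500)
    new <- pmin(1, co$risk * runif(nrow(co), 0.5, 2))
    cuts <- c(0.25, 0.6)
    for (m in c("stratified", "unstratified")) {
      expect_equal(nri(co$risk, new, co$outcome, cuts, method = m)$value,
                   brute_nri(co$risk, new, co$outcome, cuts, method = m))
    }
  }
})

test_that("stratified nri stays in [-2,2], unstratified in [-1,1]", {
  for (seed in 41:60) {
    co <- make_toy_cohort(20, seed)
    set.seed(seed)
    new <- runif(20)
    s <- nri(co$risk, new, co$outcome, 0.3)$value
    u <- nri(co$risk, new, co$outcome, 0.3, method = "unstratified")$value
    expect_gte(s, -2); expect_lte(s, 2)
    expect_gte(u, -1); expect_lte(u, 1)
  }
})

test_that("idi matches arithmetic on toy inputs and the identity case", {
  co <- make_toy_cohort(30, 12)
  expect_equal(idi(co$risk, co$risk, co$outcome), 0)
  old <- c(0.3, 0.3, 0.1, 0.1)
  new <- c(0.4, 0.4, 0.1, 0.1)
  out <- c(1, 1, 0, 0)
  expect_equal(idi(old, new, out), 0.1)
})

test_that("realized idi under injection obeys the exact carrier identity", {
  for (seed in 61:75) {
    co <- make_toy_cohort(200, seed)
    rr <- runif(1, 1, 3.5)
    carriers <- draw_risk_factor(200, 0.4, seed = seed + 100)
    new <- apply_risk_factor(co$risk, carriers, rr)
    ev <- co$outcome == 1
    identity_value <- (rr - 1) *
      (mean(carriers[ev] * co$risk[ev]) - mean(carriers[!ev] * co$risk[!ev]))
    expect_equal(idi(co$risk, new, co$outcome), identity_value)
  }
})
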