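test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # all events at distinct times
  rec <- data.frame(time_months = 1:5, event = 1)
  km <- km_estimate(rec)
  expect_equal(km$surv, (4:0) / 5)
  expect_true(all(diff(km$surv) <= 0))

  # all censored
  rec2 <- data.frame(time_months = 1:5, event = 0)
  km2 <- km_estimate(rec2)
  expect_true(all(km2$surv == 1))

  # mixed toy set, hand-worked: deaths at 2 (n=6), 4 (n=4), 7 (n=2)
  rec3 <- data.frame(time_months = c(2, 3, 4, 5, 7, 8),
                     event = c(1, 0, 1, 0, 1, 0))
  km3 <- km_estimate(rec3)
  ev <- km3$n_event > 0
  expect_equal(km3$surv[ev], c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2))

  # without censoring KM equals the empirical survival function
  set.seed(51)
  t <- rexp(40)
  km4 <- km_estimate(data.frame(time_months = t, event = 1))
  expect_equal(km4$surv, 1 - seq_along(t) / length(t))
  expect_error(km_estimate(data.frame(time_months = c(1, -1), event = c(1, 1))),
               "positive")
})

test_that("log-rank test is symmetric, null on identical groups, powered", {
  rec <- data.frame(time_months = rep(c(1, 2, 3, 4), 2),
                    event = rep(c(1, 1, 0, 1), 2),
                    g = rep(c(0, 1), each = 4))
  lr <- logrank_test(rec, rec$g)
  expect_equal(lr$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)

  set.seed(52)
  hits <- 0
  for (i in 1:100) {
    ta <- rexp(200, 1); tb <- rexp(200, 3)
    rec2 <- data.frame(time_months = c(ta, tb), event = 1,
                       g = rep(0:1, each = 200))
    p <- logrank_test(rec2, rec2$g)$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # no events at all: degenerate, flagged
  rec3 <- data.frame(time_months = c(1, 2, 3, 4), event = 0, g = c(0, 0, 1, 1))
  lr3 <- logrank_test(rec3, rec3$g)
  expect_true(lr3$degenerate)
})

test_that("maxstat selects the separating cutoff and matches the oracle", {
  # early deaths have feature 10-12, censored long survivors 1-3
  rec <- data.frame(
    time_months = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11,
                    30, 33, 36, 39, 42, 45, 48, 51, 54, 57),
    event = c(rep(1, 10), rep(0, 10)),
    x = c(10, 11, 12, 10.5, 11.5, 10.2, 11.8, 10.8, 11.2, 12.0,
          2, 1, 3, 2.5, 1.5, 2.2, 1.8, 2.8, 1.2, 2.9))
  cr <- maxstat_cutoff(rec, "x", n_perm = 400, seed = 1)
  expect_gt(cr$cutoff, 3)
  expect_lt(cr$cutoff, 10)
  expect_equal(cr$direction, "+")
  expect_lt(cr$p_value, 0.05)

  set.seed(53)
  for (i in 1:25) {
    co <- simulate_cohort(cohort_spec(n = 40, beta = c(nhoc_max = 1),
                                      seed = 1000 + i))
    got <- maxstat_cutoff(co, "nhoc_max", n_perm = 0)
    exp <- oracle_maxstat(co$time_months, co$event, co$nhoc_max)
    expect_equal(got$statistic, exp$statistic, tolerance = 1e-10)
    expect_equal(got$cutoff, exp$cutoff, tolerance = 1e-10)
  }
  expect_error(maxstat_cutoff(data.frame(time_months = c(1, 2),
                                         event = c(1, 1), x = c(1, 1)),
                              "x"), "equal")
})

test_that("Harrell C-index handles perfect orderings and matches pair counts", {
  rec <- data.frame(time_months = c(3, 1, 4, 2), event = 1)
  expect_equal(concordance_index(rec, -rec$time_months)$c_index, 1)
  expect_equal(concordance_index(rec, rec$time_months)$c_index, 0)
  # decreasing direction flips the score
  expect_equal(concordance_index(rec, rec$time_months,
                                 direction = "decreasing")$c_index, 1)

  set.seed(54)
  for (i in 1:25) {
    n <- 8
    rec2 <- data.frame(time_months = rexp(n) + 0.1,
                       event = rbinom(n, 1, 0.7))
    if (sum(rec2$event) == 0) rec2$event[1] <- 1
    x <- sample(c(1, 2, 2, 3, 4, 4, 5, 6))  # ties in the risk score
    got <- concordance_index(rec2, x)$c_index
    expect_equal(got, oracle_cindex(rec2$time_months, rec2$event, x),
                 tolerance = 1e-12)
  }
  # independent cross-check against survival::concordance on tie-free data
  rec3 <- data.frame(time_months = c(5, 2, 8, 1, 9, 4), event = c(1, 1, 0, 1, 1, 0))
  x3 <- c(0.3, 0.9, 0.1, 0.8, 0.2, 0.5)
  cc <- survival::concordance(survival::Surv(time_months, event) ~ x3,
                              data = rec3, reverse = TRUE)
  expect_equal(concordance_index(rec3, x3)$c_index, unname(cc$concordance))
})

test_that("risk categories stratify and adjust pairwise tests", {
  set.seed(55)
  n <- 240
  xa <- rnorm(n); xb <- rnorm(n)
  haz <- 0.05 * exp(0.9 * (xa > 0) + 0.9 * (xb > 0))
  rec <- data.frame(time_months = rexp(n, haz), event = 1,
                    a = xa, b = xb)
  rc <- risk_categories(rec, "a", 0, "+", "b", 0, "+")
  expect_setequal(unique(rc$category), 0:2)
  km0 <- km_estimate(rec[rc$category == 0, ])
  km2 <- km_estimate(rec[rc$category == 2, ])
  expect_lt(km2$median, km0$median)
  expect_true(all(rc$tests$p_adjusted >= rc$tests$p_raw - 1e-15))
  expect_true(all(diff(rc$tests$p_adjusted[order(rc$tests$p_raw)]) >= -1e-15))
  # all-favorable cohort: every subject in category 0, other tests skipped
  rc0 <- risk_categories(rec, "a", max(xa) + 1, "+", "b", max(xb) + 1, "+")
  expect_true(all(rc0$category == 0))
  expect_true(all(rc0$tests$skipped))
})

test_that("Wilcoxon rank-sum matches exact enumeration and has power", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)  # 2/20 partitions as extreme, two-sided
  expect_true(w$exact)
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(wilcoxon_ranksum(x, x)$p_value, 1)
  set.seed(56)
  hits <- 0
  for (i in 1:40) {
    if (wilcoxon_ranksum(rnorm(100), rnorm(100, 1))$p_value < 0.01)
      hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("survival_table has the screening-table shape", {
  co <- simulate_cohort(cohort_spec(n = 60, beta = c(nhoc_max = 1.5),
                                    seed = 57))
  tab <- survival_table(co, c("nhoc_max", "suv_max"), n_perm = 100, seed = 5)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("feature", "cutoff", "statistic", "p_value",
                      "direction", "c_index", "n_low", "n_high"))
  expect_true(all(tab$direction %in% c("+", "-")))
  expect_true(all(tab$n_low + tab$n_high == 60))
})
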