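test_that("product-limit estimates match hand-computed values", {
  # times (1,2,3), events (1,1,0): S = 2/3, 1/3, then a censored tail
  fit <- km_fit(c(1, 2, 3), c(1, 1, 0))
  expect_equal(fit$table$survival, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(fit$table$n_risk, c(3, 2, 1))

  # all censored: S stays 1
  flat <- km_fit(c(5, 8, 13), c(0, 0, 0))
  expect_true(all(flat$table$survival == 1))
  expect_true(is.na(km_median(flat)))

  # single event at t = 5 among n = 2
  half <- km_fit(c(5, 9), c(1, 0))
  expect_equal(km_survival_at(half, 5), 0.5)
  expect_equal(km_survival_at(half, 4), 1)

  # ties: events processed before censorings at the same time
  tie <- km_fit(c(4, 4, 4), c(1, 1, 0))
  expect_equal(tie$table$survival, 1 / 3)

  expect_error(km_fit(numeric(), numeric()), "at least one")
  expect_error(km_fit(c(0, 3), c(1, 1)), ">= 1")
})

test_that("with no censoring S(t) is the empirical survival function", {
  set.seed(3)
  for (i in 1:20) {
    t <- sample.int(50, sample(3:40, 1), replace = TRUE)
    fit <- km_fit(t, rep(1, length(t)))
    grid <- sort(unique(t))
    expect_equal(km_survival_at(fit, grid), vapply(grid, function(g) {
      mean(t > g)
    }, numeric(1)))
  }
})

test_that("km_fit matches the reference survival implementation to 1e-10", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    t <- sample.int(80, n, replace = TRUE)
    e <- rbinom(n, 1, runif(1, 0.2, 0.9))
    ref <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
    mine <- km_fit(t, e)$table
    expect_equal(mine$time, ref$time)
    expect_equal(mine$survival, ref$surv, tolerance = 1e-10)
    keep <- mine$survival > 0 & mine$survival < 1
    expect_equal(sqrt(mine$greenwood_var[keep]), ref$std.err[keep],
                 tolerance = 1e-10)
    expect_equal(mine$ci_low[keep], ref$lower[keep], tolerance = 1e-10)
    expect_equal(mine$ci_high[keep], ref$upper[keep], tolerance = 1e-10)
  }
})

test_that("confidence bounds bracket the estimate inside [0, 1]", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    fit <- km_fit(sample.int(40, n, replace = TRUE), rbinom(n, 1, 0.6))
    tab <- fit$table[!is.na(fit$table$ci_low), ]
    expect_true(all(tab$ci_low <= tab$survival + 1e-12))
    expect_true(all(tab$ci_high >= tab$survival - 1e-12))
    expect_true(all(tab$ci_low >= 0 & tab$ci_high <= 1))
    expect_true(all(diff(fit$table$survival) <= 1e-12))
  }
})

test_that("median uses the first event time at or below one half", {
  # S drops to exactly 0.5 at t = 10
  fit <- km_fit(c(10, 10, 20, 20), c(1, 1, 0, 0))
  expect_equal(fit$table$survival[1], 0.5)
  expect_equal(km_median(fit), 10)
  # S stays above 0.5: undefined
  fit2 <- km_fit(c(10, 20, 30), c(1, 0, 0))
  expect_true(is.na(km_median(fit2)))
})

test_that("cumulative discontinuation is the survival complement", {
  # one event among n at day 300 so S(365) = 1 - 1/n
  fit <- km_fit(c(300, rep(400, 4)), c(1, 0, 0, 0, 0))
  cd <- cumulative_discontinuation(fit, 1)
  expect_equal(cd$rate, 100 * (1 - km_survival_at(fit, 365)))
  expect_equal(cd$rate / 100 + km_survival_at(fit, 365), 1)
  expect_true(cd$ci_low <= cd$rate && cd$ci_high >= cd$rate)
  # horizon before the first event: zero with a degenerate interval
  early <- cumulative_discontinuation(km_fit(c(500, 600), c(1, 0)), 1)
  expect_equal(unlist(early[c("rate", "ci_low", "ci_high")]),
               c(rate = 0, ci_low = 0, ci_high = 0))
  # a curve with S(365) ~ 0.828 reports a 17.2% one-year rate
  n <- 1000
  t <- c(rep(200, 172), rep(2000, 828))
  e <- c(rep(1, 172), rep(0, 828))
  cd2 <- cumulative_discontinuation(km_fit(t, e), 1)
  expect_equal(cd2$rate, 17.2)
})

test_that("restart timing feeds the product-limit estimator", {
  counts <- tibble::tibble(index_drug = "etanercept",
                           pattern = c("restart", "discontinuation"),
                           n = c(6, 3))
  courses <- courses_from_counts(counts, seed0 = 7000)
  curve <- time_to_restart(courses)
  expect_s3_class(curve, "km_curve")
  expect_equal(sum(curve$table$n_event), 6)
  expect_equal(curve$n, 9)
  # all restart gaps exceed the 60-day grace by construction
  expect_true(all(curve$table$time[curve$table$n_event > 0] > 60))
  # continuation-only input has no interruptions
  cont <- courses_from_counts(tibble::tibble(index_drug = "etanercept",
                                             pattern = "continuation", n = 2),
                              seed0 = 8000)
  expect_null(time_to_restart(cont))
})

test_that("km curves tidy, glance and plot", {
  fit <- km_fit(c(3, 5, 5, 9, 12), c(1, 1, 0, 1, 0))
  td <- tidy(fit)
  expect_true(all(c("time", "estimate", "ci_low", "ci_high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 5)
  expect_equal(gl$events, 3)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
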