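test_that("log-rank statistic equals the hand-computed risk-set oracle", {
  # 6 subjects, hand-tabulated risk sets
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c("A", "B", "A", "B", "A", "B")
  got <- logrank_test(group, time, event)
  expect_equal(got$statistic, oracle_logrank(group, time, event),
               tolerance = 1e-9)
  set.seed(14)
  for (i in 1:10) {
    tm <- rexp(12)
    ev <- rbinom(12, 1, 0.8)
    gr <- rep(c("A", "B"), 6)
    expect_equal(logrank_test(gr, tm, ev)$statistic,
                 oracle_logrank(gr, tm, ev), tolerance = 1e-9)
  }
})

test_that("identical duplicated groups give statistic 0 and p 1", {
  time <- rep(c(3, 6, 8, 10), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("A", "B"), each = 4)
  got <- logrank_test(group, time, event)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p, 1)
  expect_error(logrank_test(rep("A", 4), time[1:4], event[1:4]),
               class = "dmrlink_validation_error")
})

test_that("log-rank is invariant under time rescaling", {
  set.seed(31)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.7); gr <- rep(c("A", "B"), 15)
  expect_equal(logrank_test(gr, tm, ev)$statistic,
               logrank_test(gr, 365 * tm, ev)$statistic)
})

test_that("Cox recovers a planted hazard and stays null on noise", {
  set.seed(9)
  n <- 200
  x <- rnorm(n)
  tm <- rexp(n, rate = 0.2 * exp(0.9 * x))
  cens <- runif(n, 0, 15)
  got <- cox_univariate(x, pmin(tm, cens), as.integer(tm <= cens))
  expect_gt(got$hr, 1.5)
  expect_lt(got$p, 1e-6)
  # independent covariate: CI covers 1 in >= 90% of a seed batch
  cover <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    z <- rnorm(n)
    fit <- cox_univariate(z, pmin(tm, cens), as.integer(tm <= cens))
    fit$ci_lower <= 1 && fit$ci_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("Cox degenerate inputs error; negation inverts the hazard ratio", {
  expect_error(cox_univariate(rep(1, 30), rexp(30), rbinom(30, 1, 0.5)),
               class = "dmrlink_degenerate_fit_error")
  expect_error(cox_univariate(rnorm(30), rexp(30),
                              c(1, rep(0, 29))),
               class = "dmrlink_insufficient_data")
  set.seed(2)
  x <- rnorm(80); tm <- rexp(80, 0.2 * exp(0.5 * x))
  ev <- rep(1, 80)
  a <- cox_univariate(x, tm, ev)
  b <- cox_univariate(-x, tm, ev)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-6)
})

test_that("optimal cutoff separates planted survival clusters", {
  set.seed(18)
  n <- 60
  risk <- rep(c(0, 1), each = n / 2)
  values <- ifelse(risk == 1, rnorm(n, 10, 0.5), rnorm(n, 2, 0.5))
  tm <- ifelse(risk == 1, rexp(n, 1), 5 + rexp(n, 0.05))
  got <- optimal_cutoff(values, tm, rep(1, n))
  expect_gt(got$cutoff, 4)
  expect_lt(got$cutoff, 9)
  expect_lt(got$p_min, 1e-6)
  # p_min never exceeds the median-split p on the same data
  med_p <- logrank_test(values > median(values), tm, rep(1, n))$p
  expect_lte(got$p_min, med_p)
  expect_error(optimal_cutoff(rep(3, n), tm, rep(1, n)),
               class = "dmrlink_degenerate_fit_error")
  expect_error(optimal_cutoff(values[1:10], tm[1:10], rep(1, 10)),
               class = "dmrlink_insufficient_data")
})

test_that("cutoff search is optimistic under the null, as documented", {
  set.seed(44)
  n <- 60
  p_min <- vapply(1:15, function(i) {
    v <- rnorm(n)
    tm <- rexp(n)
    optimal_cutoff(v, tm, rep(1, n))$p_min
  }, numeric(1))
  # minimised p-values sit well below uniform on average
  expect_lt(mean(p_min), 0.35)
})

test_that("combined stratification beats or matches single markers on joint signal", {
  set.seed(27)
  n <- 120
  better <- vapply(1:10, function(s) {
    set.seed(500 + s)
    meth <- rnorm(n)
    expr <- rnorm(n)
    lp <- 1.1 * (meth < 0) * (expr > 0)   # hazard needs both conditions
    tm <- rexp(n, 0.2 * exp(lp))
    cens <- runif(n, 0, 12)
    time <- pmin(tm, cens); ev <- as.integer(tm <= cens)
    comb <- combined_stratification(meth, expr, time, ev,
                                    meth_high_risk = "low",
                                    expr_high_risk = "high")
    comb$p <= min(comb$p_meth_only, comb$p_expr_only) + 1e-12
  }, logical(1))
  expect_gte(mean(better), 0.8)
})

test_that("redundant combined stratification reduces to the single marker", {
  set.seed(5)
  n <- 80
  v <- rnorm(n)
  tm <- rexp(n, 0.2 * exp(0.8 * v))
  ev <- rep(1, n)
  comb <- combined_stratification(v, v, tm, ev,
                                  meth_high_risk = "high",
                                  expr_high_risk = "high")
  single <- optimal_cutoff(v, tm, ev)
  expect_lte(comb$p, single$p_min * 1.5 + 1e-12)
})

test_that("stage ANOVA: identity, planted trend, and t-test equivalence", {
  vals <- rep(c(1, 2, 3, 4), 3)
  stages <- rep(c("I", "II", "III"), each = 4)
  got <- stage_association(vals, stages)
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 1)
  set.seed(6)
  v2 <- c(rnorm(50, 0), rnorm(50, 1), rnorm(50, 2))
  s2 <- rep(c("I", "II", "III"), each = 50)
  expect_lt(stage_association(v2, s2)$p, 0.01)
  # two groups: F equals the squared two-sample t statistic
  v3 <- rnorm(30); s3 <- rep(c("I", "II"), 15)
  f <- stage_association(v3, s3)$statistic
  t2 <- t.test(v3 ~ s3, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-9)
  expect_warning(stage_association(c(v3, 5), c(s3, "IV")), "IV")
  expect_error(suppressWarnings(stage_association(c(1, 2), c("I", "II"))),
               class = "dmrlink_validation_error")
})
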