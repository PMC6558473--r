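test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$at_risk, 4:1)
  # larger uncensored sample: S(t) = fraction of times > t at every step
  set.seed(5)
  t <- round(rexp(40, 0.1), 1)
  km <- km_estimate(t, rep(1, 40))
  emp <- vapply(km$event_times, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("product-limit with censoring matches the hand oracle", {
  # all censored: survival stays at 1, no event times
  km <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_equal(length(km$event_times), 0)
  # 6-subject toy with one censor between events, hand-computed:
  # S = 5/6, 2/3 then (skip censored) 4/9, 2/9, 0
  t <- 1:6; e <- c(1, 1, 0, 1, 1, 1)
  km <- km_estimate(t, e)
  expect_equal(km$event_times, c(1, 2, 4, 5, 6))
  expect_equal(km$survival, c(5/6, 2/3, 4/9, 2/9, 0))
  orc <- km_oracle(t, e)
  expect_equal(km$survival, orc$survival)
  expect_equal(km$greenwood_var, orc$greenwood_var)
  expect_equal(km$at_risk, orc$at_risk)
  # censored-after-event convention at tied times
  t <- c(2, 2, 2, 4); e <- c(1, 0, 1, 1)
  km <- km_estimate(t, e)
  expect_equal(km$survival, km_oracle(t, e)$survival)
  expect_equal(km$survival[1], 1 - 2 / 4)
  expect_error(km_estimate(numeric(0), numeric(0)), "no records")
})

test_that("horizon rates are right-continuous with log-log intervals", {
  t <- c(10, 20, 30, 40, 50, 60, 70, 80)
  e <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km <- km_estimate(t, e)
  expect_equal(survival_rate_at(km, 0), list(rate = 1, ci = c(1, 1),
                                             extrapolated = FALSE))
  # between two event times: value of the earlier step
  r25 <- survival_rate_at(km, 25)
  expect_equal(r25$rate, km$survival[km$event_times == 20])
  # exactly at an event time: the post-event value
  expect_equal(survival_rate_at(km, 40)$rate, km$survival[km$event_times == 40])
  # CI equals the independently coded complementary log-log formula
  i <- which(km$event_times == 40)
  s <- km$survival[i]; v <- km$greenwood_var[i]
  se_cll <- sqrt(v) / (s * abs(log(s)))
  z <- qnorm(0.975)
  r40 <- survival_rate_at(km, 40)
  expect_equal(r40$ci, c(s^exp(z * se_cll), s^exp(-z * se_cll)))
  expect_true(r40$ci[1] < s && s < r40$ci[2])
  # plain Greenwood interval by flag
  rp <- survival_rate_at(km, 40, conf_type = "plain")
  expect_equal(rp$ci, pmin(1, pmax(0, s + c(-1, 1) * z * sqrt(v))))
  # beyond last follow-up: last step, flagged
  expect_warning(rx <- survival_rate_at(km, 200), "beyond last follow-up")
  expect_true(rx$extrapolated)
  expect_equal(rx$rate, km$survival[length(km$survival)])
})

test_that("log-rank matches the hand O-E oracle and its df rule", {
  # two identical groups: chi2 = 0, p = 1
  t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  # 8-subject two-group toy against the hand O-E computation
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  group <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, group)
  orc <- logrank_oracle_2g(time, event, group)
  expect_equal(lr$chi2, orc$chi2, tolerance = 1e-10)
  expect_equal(lr$p_value, orc$p, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # k = 2 equals the squared standardized O-E statistic by construction
  expect_equal(lr$chi2, orc$oe^2 / orc$var, tolerance = 1e-10)
  # 3 groups -> df = 2
  lr3 <- logrank_test(c(time, 1.5, 2.5, 9), c(event, 1, 0, 1),
                      c(group, "C", "C", "C"))
  expect_equal(lr3$df, 2L)
  expect_error(logrank_test(c(1, 1), c(0, 0), c("a", "b")), "no events")
  expect_error(logrank_test(t, e, rep("a", 4)), "2 groups")
})

test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  # exchangeable groups: coefficient ~ 0, HR ~ 1
  d <- data.frame(time = rep(c(1, 2, 3, 4, 5), 2), event = 1,
                  x = rep(c(0, 1), each = 5))
  fit <- cox_fit(d, "time", "event", "x")
  expect_equal(fit$table$coef, 0, tolerance = 1e-6)
  expect_equal(fit$table$hr, 1, tolerance = 1e-6)
  # 10-subject toy without ties: grid search at step 1e-4
  d <- data.frame(time = c(5, 1, 8, 2, 11, 3, 14, 4, 17, 6),
                  event = rep(1, 10),
                  x = rep(c(0, 1), 5))
  fit <- cox_fit(d, "time", "event", "x")
  beta_grid <- cox_grid_oracle(d$time, d$event, d$x)
  expect_equal(fit$table$coef, beta_grid, tolerance = 2e-4)
  # the reported log-likelihood is the oracle's at the optimum
  expect_equal(fit$loglik, -cox_nll_oracle(fit$table$coef, d$time, d$event, d$x),
               tolerance = 1e-8)
  # Wald machinery is self-consistent
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(fit$table$ci_low < fit$table$hr & fit$table$hr < fit$table$ci_high)
  # argument validation
  expect_error(cox_fit(transform(d, x = 1), "time", "event", "x"), "constant")
  expect_error(cox_fit(transform(d, event = 0), "time", "event", "x"),
               "no events")
  sep <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                    event = 1, x = rep(c(1, 0), each = 4))
  expect_error(cox_fit(sep, "time", "event", "x"), "converge")
})

test_that("Cox recovers a known hazard ratio from a simulated cohort", {
  set.seed(314)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_true <- rexp(n, rate = 0.03 * exp(log(2) * x))
  cens <- runif(n, 0, 60)
  d <- data.frame(time = pmin(t_true, cens), event = as.integer(t_true <= cens),
                  x = x)
  fit <- cox_fit(d, "time", "event", "x")
  expect_lt(abs(fit$table$coef - log(2)), 0.1)
  # Efron and Breslow agree on tie-free data
  d$time <- d$time + seq_len(n) * 1e-9
  fb <- cox_fit(d, "time", "event", "x", ties = "breslow")
  fe <- cox_fit(d, "time", "event", "x", ties = "efron")
  expect_equal(fb$table$coef, fe$table$coef, tolerance = 1e-6)
})

test_that("rank-sum test approximates exact enumeration and detects shifts", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  # completely separated small samples vs exact enumeration
  x <- 1:5; y <- 6:10
  p_impl <- rank_sum_test(x, y)
  p_exact <- wilcoxon_exact_oracle(x, y)
  expect_lt(abs(p_impl - p_exact), 0.01)
  # interleaved case (looser: the normal approximation is crude near the
  # center of the null distribution at these sample sizes)
  x <- c(1, 4, 6, 7, 10, 12); y <- c(2, 3, 5, 8, 9, 11, 13, 14)
  expect_lt(abs(rank_sum_test(x, y) - wilcoxon_exact_oracle(x, y)), 0.06)
  # shift alternative: rejection rate at alpha = 0.05 well above 0.5
  set.seed(99)
  rej <- mean(replicate(200, {
    rank_sum_test(rnorm(20), rnorm(20, mean = 1.5)) < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("chi-square test uses the Pearson statistic without correction", {
  tab <- matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE)
  res <- chi_square_test(tab)
  # hand arithmetic: all expected counts 15, chi2 = 4 * 25/15
  expect_equal(res$chi2, 100 / 15)
  expect_equal(res$df, 1)
  same <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 2, byrow = TRUE)
  res <- chi_square_test(same)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "marginal")
  expect_error(chi_square_test(matrix(1:3, 1)), "2x2")
})

test_that("BH adjustment reproduces the hand step-up example and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  for (i in 1:5) {
    p <- runif(20)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
    expect_equal(order(p), order(q, p))            # input order preserved
  }
  # a fully adjusted (flat) vector is a fixed point of the step-up rule
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 0.5, 0.5)), c(0.5, 0.5, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})
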