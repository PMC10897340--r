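test_that("Kaplan-Meier estimate matches the product-limit computation", {
  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$times, 0)
  expect_equal(km_survival_at(km0, c(0.5, 2, 10)), c(1, 1, 1))

  # no censoring: equals the empirical survivor function
  km1 <- km_estimate(1:4, rep(1, 4))
  expect_equal(km1$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km1$median, 2)

  # hand product-limit with censoring: 4/5, then 4/5 * 2/3, then 0
  km2 <- km_estimate(1:5, c(1, 0, 1, 0, 1))
  expect_equal(km_survival_at(km2, 1:5),
               c(4 / 5, 4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3, 0),
               tolerance = 1e-12)

  # ties grouped; curve non-increasing; steps only at event times
  set.seed(42)
  tm <- sample(1:6, 30, TRUE)
  ev <- rbinom(30, 1, 0.6)
  km3 <- km_estimate(tm, ev)
  expect_true(all(diff(km3$survival) <= 0))
  expect_true(all(km3$times %in% tm[ev == 1]))

  # agrees with survival::survfit on random data
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(km_survival_at(km3, sort(unique(tm))),
               summary(sf, times = sort(unique(tm)))$surv,
               tolerance = 1e-12)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches brute-force hypergeometric computation", {
  # identical groups: perfect symmetry gives statistic 0, p 1
  d <- survival_data(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                     rep(c("a", "b"), each = 3))
  r <- logrank_test(d)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  # A events at 1,2; B events at 3,4; no censoring
  d2 <- survival_data(1:4, rep(1, 4), c("A", "A", "B", "B"))
  r2 <- logrank_test(d2)
  o2 <- oracle_logrank(1:4, rep(1, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r2$statistic, o2$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, o2$p_value, tolerance = 1e-12)

  # exhaustive small instances: all event patterns x group assignments
  for (n in 4:8) {
    tm <- c(1, 1, 2, 3, 4, 4, 5, 6)[1:n]  # includes ties
    evs <- 1:(2^n - 1)
    grs <- 1:(2^n - 2)
    if (n >= 7) {  # sample the larger spaces
      set.seed(n)
      evs <- sample(evs, 40)
      grs <- sample(grs, 40)
    }
    for (ei in evs) {
      ev <- as.integer(intToBits(ei))[1:n]
      for (gi in grs) {
        g <- as.logical(as.integer(intToBits(gi))[1:n])
        if (all(g) || !any(g)) next
        o <- oracle_logrank(tm, ev, g)
        r <- logrank_test(survival_data(tm, ev, ifelse(g, "hi", "lo")))
        expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
      }
    }
  }

  # independent route: survival::survdiff on a random configuration
  set.seed(9)
  tm <- round(runif(40, 1, 10), 2)
  ev <- rbinom(40, 1, 0.6)
  g <- rbinom(40, 1, 0.5) == 1
  sdf <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  r <- logrank_test(survival_data(tm, ev, ifelse(g, "hi", "lo")))
  expect_equal(r$statistic, unname(sdf$chisq), tolerance = 1e-8)

  # label swap invariance
  r_sw <- logrank_test(survival_data(tm, ev, ifelse(g, "lo", "hi")))
  expect_equal(r$statistic, r_sw$statistic, tolerance = 1e-12)

  # degenerate: zero events
  r0 <- logrank_test(survival_data(c(1, 2), c(0, 0), c("a", "b")))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)

  expect_error(logrank_test(survival_data(1:3, c(1, 1, 1), rep("a", 3))),
               "two")
})

test_that("log-rank has power against a planted hazard ratio", {
  set.seed(101)
  rejections <- 0
  for (rep in 1:500) {
    t1 <- rexp(200, 0.1); t2 <- rexp(200, 0.4)  # HR = 4
    cens <- runif(400, 2, 12)
    tm <- pmin(c(t1, t2), cens)
    ev <- as.integer(c(t1, t2) <= cens)
    g <- rep(c("lo", "hi"), each = 200)
    if (logrank_test(survival_data(tm, ev, g))$p_value < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gt(rejections / 500, 0.9)
})

test_that("Welch t statistic follows the textbook formula", {
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  se2 <- var(x) / 3 + var(y) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 6)^2 / 5)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  r <- welch_t(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p_value, p_hand, tolerance = 1e-12)

  # symmetry in group order
  r_sw <- welch_t(y, x)
  expect_equal(r_sw$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r_sw$p_value, r$p_value, tolerance = 1e-12)

  # separated populations detected
  set.seed(3)
  expect_lt(welch_t(rnorm(500, 0), rnorm(500, 1))$p_value, 1e-3)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Fisher exact p-values match full hypergeometric enumeration", {
  # ((3,1),(1,3)): P(X<=obs prob) = (1+16+16+1)/70
  r1 <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r1$p_value, 34 / 70, tolerance = 1e-12)

  # ((5,0),(0,5)): only the two extreme tables
  r2 <- fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r2$p_value, 2 / 252, tolerance = 1e-12)

  # symmetry in row order
  r1b <- fisher_exact(matrix(c(1, 3, 3, 1), 2, byrow = TRUE))
  expect_equal(r1b$p_value, r1$p_value, tolerance = 1e-12)

  # r x c table handled
  r3 <- fisher_exact(matrix(c(8, 2, 3, 4, 5, 9), 3, 2))
  expect_true(r3$p_value >= 0 && r3$p_value <= 1)

  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "negative")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("logit-method combination is calibrated and well-behaved", {
  # all 0.5: logits vanish, symmetric t reference gives exactly 0.5
  expect_equal(logit_combine(rep(0.5, 7)), 0.5, tolerance = 1e-12)

  # single p near-identity
  expect_lt(abs(logit_combine(0.05) - 0.05), 0.015)

  # permutation invariance
  p <- c(0.01, 0.2, 0.6, 0.93)
  expect_equal(logit_combine(p), logit_combine(rev(p)), tolerance = 1e-15)

  # monotone: decreasing any p never increases the combined p
  set.seed(5)
  for (i in 1:20) {
    ps <- runif(5)
    j <- sample(5, 1)
    ps2 <- ps
    ps2[j] <- ps[j] * runif(1)
    expect_lte(logit_combine(ps2), logit_combine(ps))
  }

  # null calibration: combined p of independent uniforms is uniform
  set.seed(11)
  comb <- replicate(2000, logit_combine(runif(20)))
  expect_gt(ks.test(comb, "punif")$p.value, 0.01)

  expect_error(logit_combine(numeric(0)), "no p-values")
})

test_that("Cox fit maximizes the partial likelihood and flags separation", {
  # identical survival in both levels: HR ~ 1, CI covers 1
  tm <- rep(c(1, 2, 3, 4), 2)
  ev <- rep(c(1, 1, 0, 1), 2)
  x <- rep(c(0, 1), each = 4)
  r <- cox_fit(tm, ev, data.frame(x = x))
  expect_equal(r$coefficients$hazard_ratio, 1, tolerance = 1e-6)
  expect_lte(r$coefficients$ci_low, 1)
  expect_gte(r$coefficients$ci_high, 1)

  # hand-maximized partial likelihood on a 4-subject toy (untied events)
  tm4 <- c(1, 2, 3, 4); ev4 <- rep(1, 4); x4 <- c(1, 0, 1, 0)
  opt <- optimize(function(b) -oracle_cox_logpl(b, tm4, ev4, x4),
                  c(-5, 5), tol = 1e-10)
  r4 <- cox_fit(tm4, ev4, data.frame(x = x4))
  expect_equal(r4$coefficients$coef, opt$minimum, tolerance = 1e-5)

  # score (numerical gradient of the partial likelihood) ~ 0 at the fit
  b_hat <- r4$coefficients$coef
  h <- 1e-5
  score <- (oracle_cox_logpl(b_hat + h, tm4, ev4, x4) -
              oracle_cox_logpl(b_hat - h, tm4, ev4, x4)) / (2 * h)
  expect_lt(abs(score), 1e-4)

  # parameter recovery: true log-HR = ln 2 at n = 2000
  set.seed(77)
  xr <- rbinom(2000, 1, 0.5)
  te <- rexp(2000, 0.1 * 2^xr)
  cn <- runif(2000, 2, 12)
  rr <- cox_fit(pmin(te, cn), as.integer(te <= cn), data.frame(x = xr))
  expect_lt(abs(rr$coefficients$coef - log(2)) / rr$coefficients$se, 3)

  # monotone likelihood flagged, not reported as a finite HR
  rs <- cox_fit(c(1, 2, 3, 4), c(1, 1, 1, 1),
                data.frame(x = c(1, 1, 0, 0)))
  expect_true(any(rs$coefficients$non_estimable))
  expect_false(rs$converged)

  expect_error(cox_fit(1:3, c(0, 0, 0), data.frame(x = 1:3)), "no events")
})
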