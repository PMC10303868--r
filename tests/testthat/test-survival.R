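# Kaplan-Meier, log-rank, dichotomization, cutpoints, Cox and PH diagnostics

test_that("KM with no censoring equals the empirical survival function", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))[[1]]
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  # all censored: S stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))[[1]]
  expect_true(all(km2$surv == 1))
})

test_that("KM matches the hand-computed product-limit table with censoring", {
  # 6 samples: times 1+,2,3+,4,5,6 (events at 2,4,5,6)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(0, 1, 0, 1, 1, 1)
  km <- km_estimate(time, event)[[1]]
  # hand computation: S(2)=1*(1-1/5)=0.8; S(4)=0.8*(1-1/3); S(5)=...*(1-1/2); S(6)=0
  expect_equal(km$surv[km$time == 2], 4 / 5)
  expect_equal(km$surv[km$time == 4], 4 / 5 * 2 / 3)
  expect_equal(km$surv[km$time == 5], 4 / 5 * 2 / 3 * 1 / 2)
  expect_equal(km$surv[km$time == 6], 0)
  # Greenwood variance at t=2: S^2 * sum d/(n(n-d)) = 0.8^2 * 1/(5*4)
  expect_equal(km$greenwood_se[km$time == 2], sqrt(0.8^2 * 1 / 20))
})

test_that("log-rank is zero for identical groups and rejects clear separation", {
  time <- c(1, 2, 3, 4, 5)
  lr <- logrank_test(rep(time, 2), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # perfectly separated at n = 20: all early events in one group
  time2 <- c(1:10, 101:110)
  lr2 <- logrank_test(time2, rep(1, 20), rep(c("early", "late"), each = 10))
  expect_lt(lr2$p, 0.01)

  expect_error(logrank_test(time, rep(1, 5), rep("a", 5)), ">= 2 groups")
})

test_that("log-rank equals the Cox score test on tie-free two-group data", {
  set.seed(5)
  n <- 40
  x <- rep(c(0, 1), each = n / 2)
  d <- draw_exp_surv(n, beta = 0.5, x = x)
  while (anyDuplicated(d$time)) d <- draw_exp_surv(n, beta = 0.5, x = x)
  lr <- logrank_test(d$time, d$event, x)
  fit <- cox_fit(d$time, d$event, data.frame(x = factor(x)))
  sc <- summary(fit$fit)$sctest[["test"]]
  expect_equal(lr$statistic, sc, tolerance = 1e-8)
})

test_that("dichotomization follows the documented tie and quartile conventions", {
  g <- dichotomize(c(a = 1, b = 2, c = 3, d = 4), "median")
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "thresholds"), 2.5)

  g2 <- dichotomize(c(1, 2, 2, 3), "median")  # median 2, ties go low
  expect_equal(as.character(g2), c("low", "low", "low", "high"))

  g3 <- dichotomize(1:8, "quartile")
  expect_equal(as.integer(table(g3)), rep(2L, 4))
  expect_equal(levels(g3), c("Q1", "Q2", "Q3", "Q4"))

  g4 <- dichotomize(c(0.1, 0.4, 0.9), "value", threshold = 0.5)
  expect_equal(as.character(g4), c("low", "low", "high"))

  expect_error(dichotomize(rep(3, 5), "median"), "constant")

  # median/quartile rules are invariant to strictly monotone transforms
  set.seed(2)
  x <- rnorm(40)
  expect_equal(as.character(dichotomize(x, "median")),
               as.character(dichotomize(exp(x) + 10, "median")))
  expect_equal(as.character(dichotomize(x, "quartile")),
               as.character(dichotomize(atan(x), "quartile")))
})

test_that("optimal cutpoint maximizes the log-rank statistic over admissible gap midpoints", {
  scores <- c(1, 2, 3, 10, 11, 12)
  time <- c(1, 2, 3, 50, 60, 70)
  event <- c(1, 1, 1, 0, 0, 0)
  oc <- optimal_cutpoint(scores, time, event, minprop = 0.15)
  # brute force: every candidate is a midpoint between consecutive distinct
  # scores; the returned threshold carries the maximal statistic
  sv <- sort(unique(scores))
  mids <- (sv[-length(sv)] + sv[-1]) / 2
  stats <- vapply(mids, function(ct) {
    survival::survdiff(survival::Surv(time, event) ~ (scores <= ct))$chisq
  }, numeric(1))
  expect_equal(oc$threshold, mids[which.max(stats)])
  expect_equal(oc$statistic, max(stats))
  expect_true(oc$threshold %in% mids)
  expect_true(oc$selection_biased)
  expect_equal(oc$p_naive,
               pchisq(max(stats), df = 1, lower.tail = FALSE))
  expect_error(optimal_cutpoint(scores, time, event, minprop = 0.5), "minprop")
  # minprop excludes extreme candidates: with minprop .34 only the central
  # gap (3, 10) remains admissible, so its midpoint 6.5 must be returned
  oc2 <- optimal_cutpoint(scores, time, event, minprop = 0.34)
  expect_equal(oc2$threshold, 6.5)
})

test_that("naive minimum-p cutpoint selection is anti-conservative under the null", {
  set.seed(31)
  n <- 60
  n_sim <- 120
  rej <- 0
  for (i in seq_len(n_sim)) {
    scores <- rnorm(n)
    d <- draw_exp_surv(n, beta = 0, x = rep(0, n))
    oc <- optimal_cutpoint(scores, d$time, d$event)
    if (oc$p_naive < 0.05) rej <- rej + 1
  }
  # the documented selection bias: far more than the nominal 5%
  expect_gt(rej / n_sim, 0.10)
})

test_that("Cox fit recovers the null under mirrored event times and matches ties conventions", {
  # two groups with identical survival experience
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  fit <- cox_fit(time, event, data.frame(g = factor(g)))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hazard_ratios), 1, tolerance = 1e-8)
  expect_equal(fit$lr_statistic, 0, tolerance = 1e-10)

  # tie-free data: Efron and Breslow coincide
  set.seed(7)
  x <- rep(c(0, 1), 15)
  d <- draw_exp_surv(30, beta = 0.7, x = x)
  fe <- cox_fit(d$time, d$event, data.frame(x = x), ties = "efron")
  fb <- cox_fit(d$time, d$event, data.frame(x = x), ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-10)
})

test_that("Cox fit maximizes the Efron partial likelihood (grid-search oracle)", {
  set.seed(20)
  x <- rep(c(0, 1), each = 10)
  d <- draw_exp_surv(20, beta = 0.8, x = x)
  fit <- cox_fit(d$time, d$event, data.frame(x = x))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- oracle_efron_loglik(grid, d$time, d$event, x)
  beta_grid <- grid[which.max(ll)]
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-3)
  # fitted log-likelihood is a true maximum against random probes
  expect_equal(fit$loglik_full,
               oracle_efron_loglik(unname(fit$coefficients), d$time, d$event, x))
  for (b in unname(fit$coefficients) + c(-0.2, -0.01, 0.01, 0.2)) {
    expect_gte(fit$loglik_full, oracle_efron_loglik(b, d$time, d$event, x))
  }
})

test_that("Cox fit rejects degenerate designs and perfect separation", {
  time <- 1:10
  event <- rep(1, 10)
  expect_error(cox_fit(time, event, data.frame(x = rep(1, 10))), "constant")
  x <- rnorm(10)
  expect_error(cox_fit(time, event, data.frame(a = x, b = 2 * x)), "collinear")
  # monotone likelihood: covariate perfectly ordered with survival
  expect_error(cox_fit(1:20, rep(1, 20),
                       data.frame(x = factor(rep(c("hi", "lo"), each = 10)))),
               "estimable|diverging")
  expect_error(cox_fit(time, rep(0, 10), data.frame(x = rnorm(10))),
               "no events")
})

test_that("LR statistic is non-negative and additive/multiplicative designs fit", {
  set.seed(13)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  d <- draw_exp_surv(n, beta = 0.6, x = x)
  grp <- factor(ifelse(z > median(z), "high", "low"), c("low", "high"))
  add <- cox_fit(d$time, d$event, data.frame(group = grp, x = x))
  expect_gte(add$lr_statistic, 0)
  expect_equal(add$lr_statistic,
               2 * (add$loglik_full - add$loglik_null))
  mult <- cox_fit(d$time, d$event, data.frame(group = grp, x = x),
                  interactions = "group:x")
  expect_true("grouphigh:x" %in% names(mult$coefficients))
  expect_gte(mult$loglik_full, add$loglik_full - 1e-10)
})

test_that("martingale residuals sum to zero and PH diagnostics need 3 events", {
  set.seed(17)
  n <- 60
  x <- rnorm(n)
  d <- draw_exp_surv(n, beta = 0.5, x = x)
  fit <- cox_fit(d$time, d$event, data.frame(x = x))
  expect_lt(abs(sum(residuals(fit$fit, type = "martingale"))), 1e-8)
  ph <- ph_diagnostics(fit)
  expect_true(all(ph$schoenfeld$p >= 0 & ph$schoenfeld$p <= 1))
  expect_named(ph$linearity, "x")
  expect_length(ph$linearity$x, 2)

  few <- cox_fit(c(1, 2, 3, 4), c(1, 1, 0, 0), data.frame(x = c(1, 0, 1, 0)))
  expect_error(ph_diagnostics(few), ">= 3 events")
})
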