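test_that("events after the 60-month cutoff are recoded as censored at 60", {
  frame <- data.frame(followup_months = c(72, 24, 40, 60),
                      event = c(1, 1, 0, 1))
  out <- build_ttr(frame)
  expect_equal(out$ttr_months, c(60, 24, 40, 60))
  expect_equal(out$ttr_event, c(0, 1, 0, 1))
  expect_error(build_ttr(data.frame(followup_months = -1, event = 0)),
               "negative")
})

test_that("score transform is log1p with a floor at zero, IEL untouched", {
  frame <- data.frame(EosF = c(0, exp(1) - 1, -0.2), LymF = c(1, 2, 3),
                      IEL = c(0.5, 0.6, 0.7))
  out <- transform_scores(frame)
  expect_equal(out$EosF, c(0, 1, 0))
  expect_equal(out$LymF, log1p(c(1, 2, 3)))
  expect_equal(out$IEL, frame$IEL)
  # monotone: patient ordering preserved
  set.seed(41)
  x <- rlnorm(50)
  expect_equal(order(transform_scores(data.frame(EosF = x))$EosF), order(x))
})

test_that("rank correlations behave on monotone, anti-monotone and independent data", {
  x <- 1:30
  frame <- data.frame(A = x, B = x^3, C = -x + 0.5 * x %% 1)
  cm <- correlation_matrix(frame, c("A", "B", "C"))
  expect_equal(unname(diag(cm$rho)), c(1, 1, 1))
  expect_equal(cm$rho["A", "B"], 1)
  expect_equal(cm$rho["A", "C"], -1)
  expect_equal(cm$rho, t(cm$rho))
  set.seed(43)
  ind <- data.frame(A = rnorm(1000), B = rnorm(1000))
  expect_lt(abs(correlation_matrix(ind, c("A", "B"))$rho["A", "B"]), 0.1)
})

test_that("Kendall tau-B hits the endpoints and stays small under independence", {
  stair <- rep(1:5, each = 4)
  # tau-B reaches +/-1 when the tie structures coincide
  expect_equal(ordinal_association(stair, stair)$tau, 1)
  expect_equal(ordinal_association(-stair, stair)$tau, -1)
  # strictly increasing score against a tied ordinal stays below 1 (tau-B
  # tie correction) but remains strongly positive
  expect_gt(ordinal_association(seq_along(stair), stair)$tau, 0.85)
  set.seed(47)
  r <- ordinal_association(rnorm(500), sample(1:4, 500, TRUE))
  expect_lt(abs(r$tau), 0.08)
})

test_that("Mann-Whitney group comparisons detect separation and demand data", {
  set.seed(53)
  g <- rep(c("a", "b"), each = 50)
  same <- c(rnorm(50), rnorm(50))
  expect_gt(group_compare(same, g)$p, 0.01)
  apart <- c(rnorm(50), rnorm(50) + 100)
  expect_lt(group_compare(apart, g)$p, 1e-4)
  expect_error(group_compare(rnorm(50), rep("a", 50)), "two non-empty")
})

test_that("KM quartile splits use full-cohort cuts and order protective effects", {
  set.seed(59)
  n <- 800
  score <- rlnorm(n)
  # strong protective effect: higher score, lower hazard
  rate <- 0.05 * exp(-1.2 * scale(log(score))[, 1])
  t <- rexp(n, rate); cens <- runif(n, 10, 80)
  time <- pmin(t, cens, 60); event <- as.integer(t <= pmin(cens, 60))
  km <- km_quartiles(score, time, event)
  expect_s3_class(km, "km_quartiles")
  expect_true(all(km$wald_p[c("Q3", "Q4")] < 0.01, na.rm = TRUE))
  # survival at end of follow-up increases across quartiles
  sf <- summary(km$survfit, times = 59, extend = TRUE)
  expect_true(all(diff(sf$surv) > 0))

  # subgroup analyses reuse the full-cohort cuts
  sub <- km_quartiles(score, time, event, subset = seq_len(n) <= 400)
  expect_equal(sub$cuts, km$cuts)

  # constant scores cannot be split
  expect_error(km_quartiles(rep(1, n), time, event, score_name = "EosF"),
               "EosF")
})

test_that("KM estimator matches a hand-computed product-limit table", {
  time <- c(1, 2, 2, 3, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  oracle <- bf_km(time, event)
  got <- summary(fit, times = oracle$time)$surv
  expect_equal(got, oracle$surv, tolerance = 1e-12)
})

test_that("Cox fits report HR, CI, p, AIC and obey likelihood monotonicity", {
  set.seed(61)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05); cens <- runif(n, 5, 40)
  d <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
                  g = g, noise = rnorm(n))
  f0 <- cox_fit(Surv(time, event) ~ g, d)
  expect_s3_class(f0, "cox_fit")
  # identical groups: HR near 1, p large
  expect_equal(f0$table$hr, 1, tolerance = 0.35)
  expect_gt(f0$table$p, 0.01)
  expect_true(f0$table$ci_low <= f0$table$hr &&
                f0$table$hr <= f0$table$ci_high)
  expect_equal(f0$aic, 2 * 1 - 2 * f0$loglik)

  # nested model has at least the smaller model's log-likelihood
  f1 <- cox_fit(Surv(time, event) ~ g + noise, d)
  expect_gte(f1$loglik, f0$loglik - 1e-9)
  cmp <- model_compare(list(base = f0, bigger = f1))
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(nrow(cmp), 2L)

  # complete-case handling is reported
  d2 <- d; d2$g[1:7] <- NA
  f2 <- cox_fit(Surv(time, event) ~ g, d2)
  expect_equal(f2$n_dropped, 7L)

  # models on different subsets are not AIC-comparable
  expect_error(model_compare(list(a = f0, b = f2)), "different subsets")
})

test_that("too few events raises a warning, not an error", {
  d <- data.frame(time = c(rexp(40, 0.01), 1, 2, 3),
                  event = c(rep(0, 40), 1, 1, 1),
                  x = rnorm(43))
  expect_warning(cox_fit(Surv(time, event) ~ x, d), "events")
})
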