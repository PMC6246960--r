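test_that("Kaplan-Meier product-limit matches hand computation", {
  # three subjects, events at 1, 2, 3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  # n = 2: event at 5, censored at 10
  km <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(km$survival, 0.5)
  expect_equal(km$median, 5)

  # all censored: flat S = 1, median undefined
  km <- km_estimate(c(3, 8, 11), c(0, 0, 0))
  expect_equal(length(km$time), 0)
  expect_true(is.na(km$median))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(17)
  t <- round(rexp(60, 1 / 100), 1)
  km <- km_estimate(t, rep(1, 60))
  for (i in seq_along(km$time))
    expect_equal(km$survival[i], mean(t > km$time[i]))
})

test_that("KM agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(23)
  t <- rexp(80, 1 / 200)
  e <- rbinom(80, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  et <- sf$time[sf$n.event > 0]
  expect_equal(km$time, et)
  expect_equal(km$survival, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  med <- summary(sf)$table["median"]
  expect_equal(km$median, unname(med))
})

test_that("log-rank statistic matches hand computation on a small case", {
  # groups A: events at 1, 3, censored 5; B: events at 2, 4, censored 6
  t <- c(1, 3, 5, 2, 4, 6)
  e <- c(1, 1, 0, 1, 1, 0)
  g <- c("A", "A", "A", "B", "B", "B")
  # hand-computed observed-minus-expected for group A:
  # t=1: n=6, nA=3, d=1, e=0.5; t=2: n=5, nA=2, e=0.4; t=3: n=4, nA=2,
  # e=0.5; t=4: n=3, nA=1, e=1/3. O_A=2, E_A=0.5+0.4+0.5+1/3
  EA <- 0.5 + 0.4 + 0.5 + 1 / 3
  res <- logrank_test(t, e, g)
  expect_equal(res$table$expected[res$table$group == "A"], EA,
               tolerance = 1e-12)
  # variance terms: d(n-d)/(n-1) * nA/n * (1 - nA/n), d=1 each time
  VA <- 0.5 * 0.5 + 0.4 * 0.6 + 0.5 * 0.5 + (1 / 3) * (2 / 3)
  expect_equal(res$chisq, (2 - EA)^2 / VA, tolerance = 1e-12)
  expect_equal(res$z, (2 - EA) / sqrt(VA), tolerance = 1e-12)
})

test_that("log-rank is zero for duplicated groups and matches survdiff", {
  t <- c(2, 5, 9, 12)
  e <- c(1, 1, 0, 1)
  dup <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(dup$chisq, 0)
  expect_equal(dup$p_value, 1)

  skip_if_not_installed("survival")
  set.seed(41)
  for (k in 2:3) {
    t <- rexp(90, 1 / 150)
    e <- rbinom(90, 1, 0.8)
    g <- sample(LETTERS[1:k], 90, TRUE)
    mine <- logrank_test(t, e, g)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
    expect_equal(mine$df, k - 1)
  }
  expect_error(logrank_test(t, e, rep("A", 90)), "2 groups")
})

test_that("maxstat scan equals exhaustive candidate evaluation", {
  skip_if_not_installed("survival")
  set.seed(57)
  n <- 50
  values <- round(rlnorm(n, 4, 1), 2)
  t <- rexp(n, 1 / (100 + values))
  e <- rbinom(n, 1, 0.8)
  res <- maxstat_cutpoint(values, t, e, min_group_fraction = 0.1)
  # independent scan: survdiff chi-square at every admissible midpoint
  uv <- sort(unique(values))
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  mids <- mids[vapply(mids, function(m)
    sum(values <= m) >= 5 && sum(values > m) >= 5, TRUE)]
  zs <- vapply(mids, function(m) {
    g <- factor(values > m)
    sqrt(survival::survdiff(survival::Surv(t, e) ~ g)$chisq)
  }, 0)
  expect_equal(res$candidates_evaluated, length(mids))
  expect_equal(res$cutpoint, mids[which.max(zs)])
  expect_equal(res$max_standardized_statistic, max(zs), tolerance = 1e-8)
})

test_that("maxstat respects the minimum group fraction and degenerate input", {
  values <- c(rep(1, 30), 2)
  t <- rexp(31, 1 / 100); e <- rep(1, 31)
  # the only midpoint leaves 1/31 on one side: inadmissible at 10%
  expect_error(maxstat_cutpoint(values, t, e), "min_group_fraction")
  expect_error(maxstat_cutpoint(rep(5, 31), t, e), "identical")
  expect_error(maxstat_cutpoint(1:5, rexp(5), rep(1, 5)), "at least 10")

  # identical survival in all subjects: statistic ~ 0, flagged unreliable
  res <- maxstat_cutpoint(1:20, rep(10, 20), rep(1, 20))
  expect_equal(res$max_standardized_statistic, 0)
  expect_false(res$reliable)
})

test_that("stratification: not_detected, then high/low by the cut point", {
  quants <- data.frame(sample_id = c("a", "b", "c", "d"),
                       detected = c(FALSE, TRUE, TRUE, TRUE),
                       ctdna_copies_per_ml = c(0, 6947.82, 210.53, 12))
  g <- stratify_ctdna(quants, 210.53)
  expect_identical(unname(g), c("not_detected", "high", "low", "low"))
  expect_error(stratify_ctdna(quants, 0), "positive")
})

test_that("Cox fit: symmetry, oracle likelihood, and coxph agreement", {
  # identical groups: HR exactly 1
  t <- c(2, 5, 9, 12); e <- c(1, 1, 0, 1)
  fit <- cox_univariate(c(t, t), c(e, e), rep(c("high", "low"), each = 4))
  expect_equal(unname(fit$hazard_ratios["low"]), 1, tolerance = 1e-8)

  # Breslow partial likelihood at the optimum equals a brute-force
  # evaluation over explicitly enumerated risk sets (n <= 8)
  set.seed(3)
  t <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- rep(c("high", "low"), 4)
  fit <- cox_univariate(t, e, g)
  beta <- unname(fit$coef["low"])
  x <- as.numeric(g == "low")
  ll <- 0
  for (i in which(e == 1)) {
    risk <- which(t >= t[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  expect_equal(fit$log_partial_likelihood, ll, tolerance = 1e-10)

  skip_if_not_installed("survival")
  set.seed(71)
  t <- rexp(120, 1 / 100)
  e <- rbinom(120, 1, 0.75)
  g <- sample(c("high", "low", "not_detected"), 120, TRUE)
  fit <- cox_univariate(t, e, g, reference = "high")
  ref <- survival::coxph(
    survival::Surv(t, e) ~ relevel(factor(g), "high"),
    ties = "breslow")
  expect_equal(sort(unname(fit$coef)), sort(unname(coef(ref))),
               tolerance = 1e-6)
  expect_equal(fit$log_partial_likelihood, ref$loglik[2], tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$ci95[, "lower"] < fit$hazard_ratios) &&
                all(fit$hazard_ratios < fit$ci95[, "upper"]))
})

test_that("Cox flags monotone likelihood when a group has no events", {
  t <- c(rexp(20, 1 / 50), rexp(20, 1 / 500))
  e <- c(rep(1, 20), rep(0, 20))
  g <- rep(c("high", "low"), each = 20)
  fit <- suppressWarnings(cox_univariate(t, e, g))
  expect_true(fit$monotone_likelihood)
  expect_error(cox_univariate(t, rep(0, 40), g), "no events")
})

test_that("survival report assembles curves, tests and median differences", {
  # construct groups with exact KM medians: high 120, low 318, nd 400
  mk_grp <- function(g, med, n = 11) {
    data.frame(sample_id = sprintf("%s%02d", g, 1:n), group = g,
               time_days = med + seq(-50, 50, length.out = n),
               event = 1)
  }
  rec <- rbind(mk_grp("high", 120), mk_grp("low", 318),
               mk_grp("not_detected", 400))
  rep3 <- survival_report(rec, cutpoint = 210.53)
  expect_equal(unname(rep3$medians["high"]), 120)
  expect_equal(unname(rep3$median_diff_vs_high[["low"]]), 198)
  expect_equal(unname(rep3$median_diff_vs_high[["not_detected"]]), 280)
  expect_equal(nrow(rep3$pairwise_logrank), 3)
  out <- capture.output(print(rep3))
  expect_true(any(grepl("280", out)))
  expect_true(any(grepl("210.53", out)))

  # single group: one curve, no tests
  rep1 <- survival_report(mk_grp("high", 120))
  expect_null(rep1$global_logrank)
  expect_null(rep1$pairwise_logrank)

  # permuting group labels leaves the numeric content unchanged
  rec2 <- rec[sample(nrow(rec)), ]
  rep3b <- survival_report(rec2, cutpoint = 210.53)
  expect_equal(rep3b$medians, rep3$medians)
  expect_equal(rep3b$global_logrank$chisq, rep3$global_logrank$chisq)
})

test_that("simulated survival honors hazards, censoring and determinism", {
  groups <- stats::setNames(rep(c("high", "low", "not_detected"), each = 50),
                            sprintf("S%03d", 1:150))
  p <- survival_sim_params(seed = 5)
  a <- simulate_survival(groups, p)
  b <- simulate_survival(groups, p)
  expect_identical(a, b)
  expect_true(all(a$time_days <= p$study_days))
  expect_true(all(a$event[a$time_days == p$study_days] == 0))

  z <- simulate_survival(groups, survival_sim_params(study_days = 0))
  expect_true(all(z$time_days == 0) && all(z$event == 0))

  expect_error(simulate_survival(c(S1 = "mystery")), "no hazard")
})

test_that("Nelson-Aalen cumulative hazard of simulated data is linear", {
  # single group, no censoring horizon issues: fit slope over early times
  groups <- stats::setNames(rep("high", 10000), sprintf("S%05d", 1:10000))
  haz <- 1 / 300
  p <- survival_sim_params(group_hazards = c(high = haz),
                           study_days = 1e6, seed = 8)
  s <- simulate_survival(groups, p)
  km <- km_estimate(s$time_days, s$event)
  na_cumhaz <- cumsum(km$n_event / km$n_risk)
  # compare the slope at a fixed time point (t = 300: H(t) should be 1)
  i <- findInterval(300, km$time)
  expect_lt(abs(na_cumhaz[i] / 300 - haz) / haz, 0.05)
})
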