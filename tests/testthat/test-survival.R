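test_that("median split assigns ties high and flags degenerate input", {
  expect_identical(unname(median_split(c(a = 1, b = 2, c = 3, d = 4))),
                   c("low", "low", "high", "high"))
  expect_warning(g <- median_split(c(5, 5, 5)), "degenerate")
  expect_true(all(g == "high"))
  expect_identical(unname(median_split(c(1, 2, 2, 9))),
                   c("low", "high", "high", "high"))
  expect_warning(median_split(c(1, NA, 3, 4)), "missing")
})

test_that("Kaplan-Meier matches the hand-worked product limit", {
  # times 5+, 6, 8, 10+, 12 (+ censored)
  km <- km_curve(c(5, 6, 8, 10, 12), c(0, 1, 1, 0, 1))
  expect_equal(km$surv[km$time == 6], 3 / 4)
  expect_equal(km$surv[km$time == 8], 3 / 4 * 2 / 3)
  expect_equal(km$surv[km$time == 12], 0)
  expect_true(all(diff(km$surv) <= 0))

  # all censored: S stays 1
  expect_true(all(km_curve(1:5, rep(0, 5))$surv == 1))

  # no censoring: S equals the empirical survival fraction
  tt <- c(2, 4, 6, 8)
  km2 <- km_curve(tt, rep(1, 4))
  expect_equal(km2$surv, 1 - ecdf(tt)(tt))
})

test_that("log-rank statistic matches direct O-E summation", {
  # identical groups by symmetric duplication: no signal
  lr0 <- logrank_test(c(1, 2, 3, 4, 1, 2, 3, 4),
                      c(1, 1, 0, 1, 1, 1, 0, 1),
                      rep(c("A", "B"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 8-subject toy table against the direct-summation oracle
  time <- c(3, 5, 7, 9, 2, 4, 6, 10)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, grp)
  dr <- direct_logrank(time, event, grp)
  expect_equal(lr$chi2, dr$chi2, tolerance = 1e-10)
  expect_equal(lr$p, dr$p, tolerance = 1e-10)

  # invariant under swapping group labels
  lr_sw <- logrank_test(time, event, ifelse(grp == "A", "B", "A"))
  expect_equal(lr_sw$chi2, lr$chi2, tolerance = 1e-12)
})

test_that("log-rank detects a strong group effect", {
  set.seed(15)
  rejections <- mean(replicate(500, {
    time <- c(rexp(200, 1), rexp(200, 2))
    grp <- rep(c("low", "high"), each = 200)
    logrank_test(time, rep(1, 400), grp)$p < 0.05
  }))
  expect_gt(rejections, 0.9)
})

test_that("Cox fit matches the Breslow grid-search oracle", {
  # exchangeable groups: beta = 0
  fit0 <- cox_fit(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                  rep(c("high", "low"), each = 3))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
  expect_equal(fit0$hr, 1, tolerance = 1e-8)

  # 6-subject toy dataset
  time <- c(4, 6, 8, 10, 12, 14)
  event <- c(1, 1, 1, 1, 0, 1)
  grp <- c("high", "low", "high", "low", "high", "low")
  fit <- cox_fit(time, event, grp)
  beta_ref <- grid_search_cox_beta(time, event, as.numeric(grp == "high"))
  expect_equal(fit$beta, beta_ref, tolerance = 1e-6)
  expect_equal(fit$ci_low, exp(fit$beta - qnorm(0.975) * fit$se))
  expect_equal(fit$percent_risk, 100 * (fit$hr - 1))
  expect_gte(fit$hr, fit$ci_low)
  expect_lte(fit$hr, fit$ci_high)

  # hazard-ratio-to-percent reporting convention
  expect_equal(hr_to_percent(1.181), 18.1, tolerance = 1e-9)

  # complete separation is flagged
  sep <- cox_fit(c(1, 2, 3, 11, 12, 13), rep(1, 6),
                 rep(c("high", "low"), each = 3))
  expect_true(sep$flagged)
})

test_that("log-rank equals the Cox score test at beta = 0 (untied data)", {
  set.seed(22)
  for (r in 1:5) {
    n <- 30
    time <- round(rexp(n, 0.1), 6) + seq_len(n) * 1e-4  # untied
    event <- rbinom(n, 1, 0.8)
    grp <- rep(c("high", "low"), length.out = n)
    if (sum(event) == 0) next
    lr <- logrank_test(time, event, grp)
    cf <- cox_fit(time, event, grp)
    expect_equal(lr$chi2, cf$score_chi2, tolerance = 1e-6)
  }
})

test_that("candidate validation runs the full split-test-fit chain", {
  cfg <- sim_config(target_log_hr = log(2), seed = 27L)
  sim <- simulate_study(cfg)
  tg <- sim$truth$target_gene
  rk <- data.frame(rank = 1L, gene_id = tg, module = 1L,
                   module_score = 10, abs_log2fc = 3)
  out <- validate_candidates(rk, sim$cohort$expr, sim$survival)
  expect_equal(nrow(out), 1)
  expect_gt(out$hr, 1)  # strong planted effect
  expect_lt(out$logrank_p, 0.05)

  # empty ranking gives an empty report
  expect_equal(nrow(validate_candidates(rk[0, ], sim$cohort$expr,
                                        sim$survival)), 0)
  # absent candidate is skipped with a warning
  rk2 <- rbind(rk, data.frame(rank = 2L, gene_id = "absent", module = 1L,
                              module_score = 1, abs_log2fc = 1))
  expect_warning(out2 <- validate_candidates(rk2, sim$cohort$expr,
                                             sim$survival), "absent")
  expect_equal(nrow(out2), 1)
})
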