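test_that("treatment classification keyword rules", {
  res <- classify_treatment(c("Oxaliplatin", "letrozole", "paclitaxel",
                              "", "Doxorubicin", "AC", "5-FU",
                              "tamoxifen"))
  expect_equal(res$class,
               c("chemo", "non_chemo", "non_chemo", "non_chemo",
                 "chemo", "chemo", "chemo", "non_chemo"))
  expect_true(res$untreated[4])
  expect_false(any(res$untreated[-4]))
  expect_equal(res$matched[1], "platin")

  # substring mode replicates the unsafe verbatim behaviour
  res_sub <- classify_treatment("paclitaxel", match = "substring")
  expect_equal(res_sub$class, "chemo")  # "ac" substring hit

  # multiple drugs in one record; list input per patient
  res_list <- classify_treatment(list(c("letrozole", "gemzar"), "herceptin"))
  expect_equal(res_list$class, c("chemo", "non_chemo"))
})

test_that("Kaplan-Meier matches the hand product-limit table", {
  # times {1 event, 2 censor, 3 event}: S(1) = 2/3, then 1 at risk, S(3) = 0
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km_at(km, 0.5), 1)
  expect_equal(km_at(km, 1), 2 / 3)
  expect_equal(km_at(km, 2.5), 2 / 3)
  expect_equal(km_at(km, 3), 0)

  # no events: S identically 1 with warning
  expect_warning(km0 <- km_curve(c(1, 2), c(0, 0)), "identically 1")
  expect_equal(km_at(km0, 5), 1)

  # without censoring KM equals the empirical survival function
  set.seed(1)
  t <- rexp(40, 0.3)
  km2 <- km_curve(t, rep(1, 40))
  for (q in c(0.5, 1, 2, 5)) {
    expect_equal(km_at(km2, q), mean(t > q))
  }
})

test_that("KM estimates agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(2)
  t <- rexp(100, 0.2)
  e <- rbinom(100, 1, 0.7)
  km <- km_curve(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  expect_equal(sqrt(km$var), (sf$std.err * sf$surv)[sf$n.event > 0],
               tolerance = 1e-8)
})

test_that("Cox fit maximises the Efron partial likelihood", {
  # 10-subject instance with ties; compare with a grid search
  t <- c(1, 1, 2, 3, 3, 4, 5, 6, 7, 8)
  e <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  fit <- cox_hr(t, e, x)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- efron_loglik(grid, t, e, x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 1.1e-4)

  # identical groups give HR ~ 1
  t2 <- rep(c(1, 2, 3, 4), 2)
  e2 <- rep(c(1, 1, 0, 1), 2)
  x2 <- rep(c(0, 1), each = 4)
  expect_equal(cox_hr(t2, e2, x2)$hr, 1, tolerance = 1e-6)

  # swapping group labels inverts the hazard ratio exactly
  f1 <- cox_hr(t, e, ifelse(x == 1, "b", "a"))
  f2 <- cox_hr(t, e, ifelse(x == 1, "a", "b"))
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-9)

  # monotone likelihood reported as divergence, not a number
  expect_warning(fd <- cox_hr(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
                 "monotone")
  expect_true(fd$diverged)
  expect_true(is.na(fd$hr))
})

test_that("Cox fit agrees with survival::coxph (Efron ties)", {
  skip_if_not_installed("survival")
  set.seed(3)
  for (i in 1:3) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    t <- round(rexp(n, 0.2 * exp(0.7 * x)), 1) + 0.1  # induce ties
    e <- rbinom(n, 1, 0.8)
    fit <- cox_hr(t, e, x)
    ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "efron")
    expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(unname(ref$var[1, 1])), tolerance = 1e-6)
  }
})

test_that("fitted log-hazard ratio is nearly unbiased at n = 2000", {
  coefs <- vapply(1:20, function(s) {
    sim <- simulate_survival_cohort(2000, true_hr = 2,
                                    baseline_5yr_survival = 0.7, seed = s)
    cox_hr(sim$cohort$time, sim$cohort$event, sim$cohort$group)$coef
  }, numeric(1))
  expect_lt(abs(mean(coefs) - log(2)), 0.05)
})

test_that("stratified analysis recovers planted per-stratum effects", {
  chemo <- simulate_survival_cohort(1500, true_hr = 2.67,
                                    baseline_5yr_survival = 0.8, seed = 21)$cohort
  nonchemo <- simulate_survival_cohort(1500, true_hr = 1,
                                       baseline_5yr_survival = 0.8, seed = 22)$cohort
  chemo$treatment_class <- "chemo"
  nonchemo$treatment_class <- "non_chemo"
  cohort <- rbind(chemo, nonchemo)
  names(cohort)[names(cohort) == "group"] <- "burden_class"
  res <- stratified_survival_analysis(cohort, horizon = 5)
  expect_equal(nrow(res$km), 4)
  hr_chemo <- res$cox$hr[res$cox$treatment_class == "chemo"]
  hr_non <- res$cox$hr[res$cox$treatment_class == "non_chemo"]
  expect_gt(hr_chemo, 1.8)
  expect_lt(abs(log(hr_non)), 0.35)

  # relabeling burden classes inverts both hazard ratios
  flipped <- cohort
  flipped$burden_class <- ifelse(cohort$burden_class == "net_gain",
                                 "net_loss", "net_gain")
  res_f <- stratified_survival_analysis(flipped, horizon = 5)
  expect_equal(res_f$cox$hr, 1 / res$cox$hr, tolerance = 1e-6)

  # single treatment stratum: partial table with warning
  expect_warning(res_p <- stratified_survival_analysis(chemo_only <- {
    x <- cohort[cohort$treatment_class == "chemo", ]
    x
  }), "empty stratum")
  expect_true(all(res_p$km$treatment_class == "chemo"))

  # a single burden class is rejected outright
  one_class <- cohort[cohort$burden_class == "net_gain", ]
  expect_error(stratified_survival_analysis(one_class), "both")
})
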