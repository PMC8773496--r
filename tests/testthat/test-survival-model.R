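test_that("Kaplan-Meier estimates match hand-computed product limits", {
  one <- km_estimate(2, 1)
  expect_equal(one$surv[one$time == 2], 0)

  two <- km_estimate(c(1, 2), c(0, 1))
  expect_equal(two$surv[two$time == 1], 1)   # censoring does not drop S
  expect_equal(two$surv[two$time == 2], 0)   # risk set of 1 at t = 2

  allc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(allc$surv == 1))

  three <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(three$surv, c(2 / 3, 2 / 3, 0))
})

test_that("Cox fit recovers a known hazard ratio and flags degeneracies", {
  set.seed(51)
  n <- 2000
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(log(3) * g))
  cc <- runif(n, 5, 60)
  d <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc), g = g)
  fit <- cox_fit(survival::Surv(time, event) ~ g, d)
  i <- fit$table$term == "g"
  expect_lt(abs(fit$table$loghr[i] - log(3)), 3 * fit$table$se[i])

  d$flat <- 1
  expect_error(cox_fit(survival::Surv(time, event) ~ g + flat, d), "flat")

  d$ginv <- 1 - d$g
  fit2 <- cox_fit(survival::Surv(time, event) ~ ginv, d)
  expect_equal(fit2$table$loghr, -fit$table$loghr[i], tolerance = 1e-8)
})

test_that("hazard ratios are invariant to time-unit scaling", {
  set.seed(52)
  n <- 400
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.08 * exp(0.7 * g))
  d <- data.frame(time = pmin(tt, 30), event = as.integer(tt <= 30), g = g)
  f1 <- cox_fit(survival::Surv(time, event) ~ g, d)
  d2 <- transform(d, time = time * 12)
  f2 <- cox_fit(survival::Surv(time, event) ~ g, d2)
  expect_equal(f1$table$loghr, f2$table$loghr, tolerance = 1e-8)
})

test_that("PH score test flags time-varying effects but not nulls", {
  set.seed(53)
  # proportional data: violation rate stays near the nominal 5%
  flags <- vapply(1:120, function(i) {
    n <- 150
    g <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.1 * exp(0.5 * g))
    d <- data.frame(time = pmin(tt, 25), event = as.integer(tt <= 25), g = g)
    fit <- cox_fit(survival::Surv(time, event) ~ g, d)
    ph_check(fit)$violates[1]
  }, NA)
  rate <- mean(flags)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))

  # crossing hazards: protective early, harmful late -> flagged
  flags2 <- vapply(1:20, function(i) {
    n <- 600
    g <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, 0.07 * exp(-1 * g))
    tt <- ifelse(t1 < 10, t1, 10 + rexp(n, 0.07 * exp(1 * g)))
    d <- data.frame(time = pmin(tt, 60), event = as.integer(tt <= 60), g = g)
    fit <- cox_fit(survival::Surv(time, event) ~ g, d)
    ph_check(fit)$violates[1]
  }, NA)
  expect_gt(mean(flags2), 0.8)
})

test_that("stratified refits drop the stratified coefficient row", {
  set.seed(54)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, 0.4)
  tt <- rexp(n, 0.1 * exp(0.5 * g + 0.3 * z))
  d <- data.frame(time = pmin(tt, 30), event = as.integer(tt <= 30),
                  g = g, z = factor(z))
  fit <- cox_fit(survival::Surv(time, event) ~ g + z, d)
  expect_setequal(fit$table$term, c("g", "z1"))
  refit <- refit_with_strata(fit, "z")
  expect_equal(refit$table$term, "g")
  expect_identical(refit$strata_vars, "z")

  # direct stratified construction agrees
  direct <- cox_fit(survival::Surv(time, event) ~ g, d, strata_vars = "z")
  expect_equal(refit$table$loghr, direct$table$loghr, tolerance = 1e-8)
})

test_that("the fast design-matrix fit agrees with coxph", {
  set.seed(55)
  coh <- generate_cohort(small_cohort_spec(150, missing_rates = numeric(0)),
                         seed = 55, keep_cores = FALSE)
  d <- coh$clinical
  X <- model.matrix(~ grade + node, d)[, -1]
  f1 <- tamspatial:::fast_cox(X, d$pfs_months, d$progressed)
  f2 <- survival::coxph(survival::Surv(pfs_months, progressed) ~ grade + node,
                        d, ties = "efron")
  expect_equal(unname(f1$coef), unname(coef(f2)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(f1$var))),
               unname(sqrt(diag(vcov(f2)))), tolerance = 1e-7)

  st <- as.integer(d$node)
  f3 <- tamspatial:::fast_cox(X[, 1:2], d$pfs_months, d$progressed, strata = st)
  f4 <- survival::coxph(survival::Surv(pfs_months, progressed) ~ grade + strata(node),
                        d, ties = "efron")
  expect_equal(unname(f3$coef), unname(coef(f4)), tolerance = 1e-7)
})
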