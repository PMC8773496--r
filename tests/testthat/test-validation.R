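test_that("Rubin pooling reproduces hand-computed examples", {
  res <- rubin_pool(c(1, 3), c(0.5, 0.5))
  expect_equal(res$estimate, 2)
  expect_equal(res$between, 2)
  expect_equal(res$variance, 0.5 + 1.5 * 2)   # within + (1 + 1/m) * between

  single <- rubin_pool(5, 0.25)
  expect_equal(single$estimate, 5)
  expect_equal(single$variance, 0.25)

  flat <- rubin_pool(rep(1.2, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(flat$variance, 0.25)           # between = 0 -> mean within
  expect_equal(flat$df, Inf)
  expect_error(rubin_pool(numeric(0), numeric(0)), "at least one")
})

test_that("pooled total variance never drops below the mean within-variance", {
  set.seed(71)
  for (i in 1:30) {
    m <- sample(2:10, 1)
    est <- rnorm(m)
    v <- runif(m, 0.1, 2)
    expect_gte(rubin_pool(est, v)$variance, mean(v))
  }
})

test_that("complete data passes through imputation untouched", {
  coh <- generate_cohort(small_cohort_spec(60, missing_rates = numeric(0)),
                         seed = 72, keep_cores = FALSE)
  imp <- mice_impute(coh$clinical, covariates = c("grade", "node", "age"),
                     m = 3, seed = 1)
  expect_equal(imp$m, 3)
  expect_identical(imp$datasets[[1]], imp$datasets[[3]])
  expect_identical(imp$datasets[[2]], coh$clinical)
})

test_that("imputed cells stay in range and observed cells are untouched", {
  coh <- generate_cohort(small_cohort_spec(120), seed = 73, keep_cores = FALSE)
  d <- coh$clinical
  imp <- mice_impute(d, covariates = c("grade", "node", "size_cat", "hrht",
                                       "age"), m = 4, seed = 2)
  for (k in 1:4) {
    dk <- imp$datasets[[k]]
    expect_false(anyNA(dk[c("grade", "node", "size_cat", "hrht")]))
    for (v in c("grade", "node", "size_cat", "hrht")) {
      obs <- !is.na(d[[v]])
      expect_identical(dk[[v]][obs], d[[v]][obs])
      expect_true(all(dk[[v]] %in% levels(d[[v]])))
    }
  }
  # different imputations actually differ somewhere
  expect_false(identical(imp$datasets[[1]], imp$datasets[[2]]))
  # reproducible from the seed
  imp2 <- mice_impute(d, covariates = c("grade", "node", "size_cat", "hrht",
                                        "age"), m = 4, seed = 2)
  expect_identical(imp$datasets, imp2$datasets)
})

test_that("MAR-missing covariate means are recovered within 3 SE", {
  set.seed(74)
  n <- 600
  x1 <- rnorm(n)
  p2 <- plogis(-0.3 + 0.8 * x1)
  x2 <- rbinom(n, 1, p2)
  tt <- rexp(n, 0.1)
  d <- data.frame(pfs_months = pmin(tt, 15),
                  progressed = as.integer(tt <= 15),
                  x1 = x1, x2 = factor(x2))
  truth <- mean(x2)
  miss <- runif(n) < plogis(-2.2 + 1.2 * x1)   # MAR via observed x1
  d$x2[miss] <- NA
  # complete-case mean is biased; imputation should undo it
  imp <- mice_impute(d, covariates = c("x1", "x2"), m = 15, seed = 3)
  means <- vapply(imp$datasets, function(dk) mean(dk$x2 == "1"), 0)
  pool <- rubin_pool(means, rep(truth * (1 - truth) / n, 15))
  expect_lt(abs(pool$estimate - truth), 3 * sqrt(pool$variance))
})

test_that("forcing identity resamples makes optimism exactly zero", {
  coh <- generate_cohort(small_cohort_spec(150, missing_rates = numeric(0)),
                         seed = 75, keep_cores = FALSE)
  res <- optimism_correct(coh$clinical, "comm_mean",
                          survival::Surv(pfs_months, progressed) ~ grade,
                          B = 10, seed = 1,
                          .resample = function(n) seq_len(n))
  expect_equal(unname(res$optimism_mean), rep(0, length(res$optimism_mean)),
               tolerance = 1e-10)
  expect_equal(res$corrected, res$apparent, tolerance = 1e-10)
  expect_equal(res$n_skipped, 0L)
})

test_that("optimism correction is reproducible and stable in B", {
  coh <- generate_cohort(small_cohort_spec(200, missing_rates = numeric(0)),
                         seed = 76, keep_cores = FALSE)
  d <- coh$clinical
  f <- survival::Surv(pfs_months, progressed) ~ 1
  r1 <- optimism_correct(d, "comm_mean", f, B = 150, seed = 11)
  r2 <- optimism_correct(d, "comm_mean", f, B = 150, seed = 11)
  expect_identical(r1$optimism_mean, r2$optimism_mean)
  r4 <- optimism_correct(d, "comm_mean", f, B = 300, seed = 11)
  # doubling B moves the mean optimism by at most Monte-Carlo noise
  sd_b <- sd(r4$boot_cutpoints[, 1]) # scale proxy
  expect_lt(abs(r1$optimism_mean["marker_high"] -
                r4$optimism_mean["marker_high"]), 0.25)
})

test_that("the full otcox fit recovers a known threshold effect", {
  coh <- generate_cohort(cohort_gen_spec(n_patients = 300,
                                         core = small_core_spec()),
                         seed = 77, keep_cores = FALSE)
  d <- coh$clinical
  fit <- otcox(survival::Surv(pfs_months, progressed) ~ grade + node +
                 size_cat + hrht,
               d, marker = "comm_mean", B_cutpoint = 150, B_optimism = 150,
               m = 3, seed = 12)
  i <- grepl("comm_mean", fit$table$term)
  expect_equal(sum(i), 1)
  # corrected log HR within pooled 3 SE of the generating log(3)
  expect_lt(abs(fit$table$loghr[i] - log(3)), 3 * fit$table$se[i])
  # cutpoint interval sits inside the observed metric range
  expect_true(fit$cutoff >= min(d$comm_mean) && fit$cutoff <= max(d$comm_mean))
  # methods
  expect_named(coef(fit), fit$table$term)
  ci <- confint(fit)
  expect_equal(nrow(ci), nrow(fit$table))
  grp <- predict(fit, d)
  expect_s3_class(grp, "factor")
  expect_equal(length(grp), nrow(d))
})
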