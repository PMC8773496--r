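test_that("core generation honors counts, window, zero-TAM and seeding", {
  spec <- small_core_spec(tam_fraction = 0)
  core <- generate_core(spec, seed = 81)
  expect_equal(sum(attr(core, "truth_tam")), 0)
  expect_equal(nrow(core$cells), 180)
  r <- sqrt(core$cells$x^2 + core$cells$y^2)
  expect_true(all(r <= 300 + 1e-9))

  c1 <- generate_core(small_core_spec(), seed = 82)
  c2 <- generate_core(small_core_spec(), seed = 82)
  expect_identical(c1$cells, c2$cells)
  expect_identical(attr(c1, "truth_tam"), attr(c2, "truth_tam"))
})

test_that("attracted TAMs sit closer to cancer cells than random TAMs", {
  set.seed(83)
  med_nnd <- function(mode) {
    vapply(1:60, function(i) {
      core <- generate_core(small_core_spec(proximity_mode = mode,
                                            tam_fraction = 0.15))
      core$cells$tam <- attr(core, "truth_tam")
      median(nnd_set(core))
    }, 0)
  }
  att <- med_nnd("attracted")
  rnd <- med_nnd("random")
  rep_ <- med_nnd("repulsed")
  expect_lt(median(att), median(rnd))
  expect_lt(median(rnd), median(rep_))
})

test_that("phenotyping recovers hidden TAM labels at 3-log-sd separation", {
  set.seed(84)
  acc <- numeric(200)
  for (i in seq_along(acc)) {
    core <- generate_core(core_gen_spec(tam_shift = 1.5))
    truth <- attr(core, "truth_tam")
    lab <- classify_tams(core, background_utl(core))
    st <- core$cells$compartment == "stromal"
    acc[i] <- mean(lab$cells$tam[st] == truth[st])
  }
  expect_gte(mean(acc), 0.95)
})

test_that("metrics from phenotyped labels track metrics from true labels", {
  set.seed(85)
  true_m <- phen_m <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    core <- generate_core(core_gen_spec(
      tam_fraction = runif(1, 0.02, 0.35), tam_shift = 1.5))
    truth <- attr(core, "truth_tam")
    tcore <- core; tcore$cells$tam <- truth
    pcore <- classify_tams(core, background_utl(core))
    mt <- compute_metric_suite(tcore)
    mp <- compute_metric_suite(pcore)
    true_m[i, ] <- c(mt$tam_count, mt$comm_mean)
    phen_m[i, ] <- c(mp$tam_count, mp$comm_mean)
  }
  expect_gt(cor(true_m[, 1], phen_m[, 1], method = "spearman"), 0.9)
  expect_gt(cor(true_m[, 2], phen_m[, 2], method = "spearman"), 0.9)
})

test_that("cohort generation hits the target event fraction and is seeded", {
  coh <- generate_cohort(small_cohort_spec(300), seed = 86, keep_cores = FALSE)
  expect_lt(abs(coh$truth$event_fraction - 0.6), 0.09)
  expect_equal(nrow(coh$clinical), 300)
  expect_true(all(coh$clinical$pfs_months > 0))
  # metric threshold defines the generating groups
  expect_identical(coh$truth$high,
                   coh$clinical$comm_mean > coh$truth$cutpoint)

  coh2 <- generate_cohort(small_cohort_spec(300), seed = 86, keep_cores = FALSE)
  expect_identical(coh$clinical, coh2$clinical)
})

test_that("a null cohort shows no marker-survival association", {
  set.seed(87)
  reps <- 60
  pvals <- vapply(seq_len(reps), function(i) {
    coh <- generate_cohort(small_cohort_spec(60, beta = 0,
                                             missing_rates = numeric(0)),
                           keep_cores = FALSE)
    d <- coh$clinical
    sd <- survival::survdiff(survival::Surv(d$pfs_months, d$progressed) ~
                               coh$truth$high)
    1 - pchisq(sd$chisq, 1)
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("written cohort files leak no ground truth", {
  coh <- generate_cohort(small_cohort_spec(20), seed = 88)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_cohort(coh, dir)
  cells <- read.csv(paths["cells"])
  expect_setequal(names(cells), c("core_id", "patient_id", "cell_id", "x_um",
                                  "y_um", "compartment", "cd163_intensity"))
  clin <- read.csv(paths["clinical"])
  expect_false(any(grepl("tam|truth|high|beta|cutpoint",
                         names(clin), ignore.case = TRUE)))
  expect_false(any(grepl("comm_mean|nnd_", names(clin))))
  # the truth file exists but is separate from the pipeline inputs
  expect_true(file.exists(paths["truth"]))
})

test_that("rejection sampling failure is reported helpfully", {
  spec <- small_core_spec(attraction_sd = 1e6)
  expect_error(generate_core(spec, seed = 89), "attraction_sd")
})
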