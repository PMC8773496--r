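test_that("the toy separation example splits at the midpoint 52", {
  x <- c(1, 2, 3, 101, 102, 103)
  tt <- c(10, 11, 12, 1, 2, 3)
  ev <- c(0, 0, 0, 1, 1, 1)
  res <- tree_cutpoint(x, tt, ev, min_leaf = 1, min_split = 2, cv = FALSE)
  expect_equal(res$cutpoint, 52)
  expect_identical(res$direction, "gt")

  # independent cross-check: rpart's survival tree first split
  skip_if_not_installed("rpart")
  rp <- rpart::rpart(survival::Surv(tt, ev) ~ x,
                     control = rpart::rpart.control(minsplit = 2,
                                                    minbucket = 1, cp = 0))
  expect_equal(unname(rp$splits[1, "index"]), 52)
})

test_that("the selected split maximizes the log-rank scan of the oracle", {
  set.seed(61)
  for (i in 1:25) {
    n <- 60
    x <- round(runif(n, 0, 10), 1)          # ties on purpose
    tt <- rexp(n, 0.1 * exp(0.4 * (x > 5)))
    ev <- as.integer(tt < quantile(tt, 0.8))
    res <- tree_cutpoint(x, tt, ev, min_leaf = 7, min_split = 20, cv = FALSE)
    o <- oracle_split_scan(x, tt, ev, min_leaf = 7)
    if (all(is.na(o$stat))) {
      expect_true(is.na(res$cutpoint))
    } else {
      j <- which.max(o$stat)
      expect_equal(res$cutpoint, o$cand[j])
      expect_equal(res$statistic, o$stat[j], tolerance = 1e-9)
    }
  }
})

test_that("the log-rank score numerator agrees with survdiff", {
  set.seed(62)
  n <- 80
  x <- sample(rep(1:8, 10))
  tt <- rexp(n, 0.1)
  tt[1:10] <- tt[2:11]                     # tied times
  ev <- rbinom(n, 1, 0.75)
  a <- tamspatial:::logrank_scores(tt, ev)
  expect_equal(sum(a), 0, tolerance = 1e-10)
  low <- x <= 4
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ low)
  expect_equal(sum(a[low]), sd$obs[2] - sd$exp[2], tolerance = 1e-8)
})

test_that("degenerate inputs yield no split", {
  expect_false(tree_cutpoint(rep(3, 30), rexp(30), rbinom(30, 1, 0.5))$retained)
  expect_false(tree_cutpoint(runif(10), rexp(10), rep(1, 10))$retained)  # n < min_split
  expect_false(tree_cutpoint(runif(30), rexp(30), rep(0, 30))$retained)  # no events
  # duplicate metric values collapse the candidate set to unique midpoints
  x <- rep(c(1, 2), each = 15)
  res <- tree_cutpoint(x, rexp(30, 0.2), rbinom(30, 1, 0.8), cv = FALSE)
  expect_equal(res$cutpoint, 1.5)
  expect_equal(res$n_candidates, 1L)
})

test_that("cross-validated pruning rejects most null splits", {
  set.seed(63)
  n_split <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    d <- gen_null_surv(100)
    if (tree_cutpoint(d$x, d$time, d$event)$retained) n_split <- n_split + 1
  }
  expect_lt(n_split / reps, 0.5)
})

test_that("bootstrap cutpoints recover a strong threshold and are seeded", {
  set.seed(64)
  n <- 250
  x <- runif(n, 0, 100)
  tt <- rexp(n, 0.05 * exp(log(3) * (x > 40)))
  cc <- runif(n, 5, 80)
  d <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
  res <- bootstrap_cutpoint(x, d$time, d$event, B = 200, seed = 9)
  expect_true(res$ci90[1] <= res$cutpoint && res$cutpoint <= res$ci90[2])
  expect_true(res$cutpoint >= min(x) && res$cutpoint <= max(x))
  expect_true(res$ci90[1] <= 40 && 40 <= res$ci90[2])
  expect_identical(res$direction, "gt")

  rerun <- bootstrap_cutpoint(x, d$time, d$event, B = 200, seed = 9)
  expect_identical(res$bootstrap_cutoffs, rerun$bootstrap_cutoffs)

  # B = 1 degenerates to the tree cutpoint of a single resample
  one <- bootstrap_cutpoint(x, d$time, d$event, B = 1, seed = 5)
  set.seed(5)
  idx <- sample.int(n, n, replace = TRUE)
  ref <- tree_cutpoint(x[idx], d$time[idx], d$event[idx])
  expect_equal(one$cutpoint, ref$cutpoint)
})

test_that("splits are invariant under monotone metric transforms", {
  set.seed(65)
  n <- 120
  x <- runif(n, 1, 9)
  tt <- rexp(n, 0.1 * exp(0.9 * (x > 5)))
  ev <- rbinom(n, 1, 0.8)
  r1 <- tree_cutpoint(x, tt, ev, cv = FALSE)
  r2 <- tree_cutpoint(exp(x), tt, ev, cv = FALSE)
  # same induced partition: the threshold maps through the transform
  expect_equal(sum(x <= r1$cutpoint), sum(exp(x) <= r2$cutpoint))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
})

test_that("dichotomization and the combined marker follow the contracts", {
  expect_identical(as.character(dichotomize(c(60, 80), 70)), c("low", "high"))
  expect_identical(as.character(dichotomize(70, 70)), "low")
  expect_identical(as.character(dichotomize(c(60, 80), 70, direction = "lt")),
                   c("high", "low"))

  expect_identical(as.character(combined_marker(FALSE, FALSE)), "1")
  expect_identical(as.character(combined_marker(FALSE, TRUE)), "2")
  expect_identical(as.character(combined_marker(TRUE, FALSE)), "3")
  expect_identical(as.character(combined_marker(TRUE, TRUE)), "3")
  expect_true(is.na(combined_marker(NA, TRUE)))
  expect_identical(as.character(combined_marker(factor("high", c("low", "high")),
                                                factor("low", c("low", "high")))),
                   "3")
})
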