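test_that("marked point pattern preserves counts and requires labels", {
  core <- make_labelled_core(cx = c(0, 1, 2, 3, 4), cy = rep(0, 5),
                             tx = c(10, 11, 12), ty = rep(0, 3),
                             nx = c(20, 21), ny = c(0, 0))
  pat <- build_mmpp(core)
  expect_equal(as.vector(table(pat$marks)), c(5, 3, 2))

  core$cells$tam[6] <- NA
  expect_error(build_mmpp(core), "unlabelled")

  zero <- make_labelled_core(cx = c(0, 1), cy = c(0, 0),
                             tx = numeric(0), ty = numeric(0),
                             nx = 5, ny = 5)
  expect_equal(sum(build_mmpp(zero)$marks == "tam"), 0)
})

test_that("nearest-neighbor distances follow plane geometry", {
  core <- make_labelled_core(cx = c(0, 10), cy = c(0, 0), tx = 3, ty = 4)
  expect_equal(sort(nnd_set(core)), sort(c(5, sqrt(65))))

  coincident <- make_labelled_core(cx = 0, cy = 0, tx = c(0, 9), ty = c(0, 0))
  expect_equal(min(nnd_set(coincident)), 0)
})

test_that("NND and disc counts match brute-force oracles on random patterns", {
  set.seed(99)
  for (i in 1:60) {
    n_c <- sample(1:120, 1)
    n_t <- sample(0:80, 1)
    pts <- runif_disc_pts(n_c + n_t, 290)
    core <- make_labelled_core(cx = pts$x[seq_len(n_c)], cy = pts$y[seq_len(n_c)],
                               tx = pts$x[-seq_len(n_c)], ty = pts$y[-seq_len(n_c)])
    expect_equal(nnd_set(core),
                 oracle_nnd(pts$x[seq_len(n_c)], pts$y[seq_len(n_c)],
                            pts$x[-seq_len(n_c)], pts$y[-seq_len(n_c)]),
                 tolerance = 1e-12)
    for (r in c(12, 250)) {
      expect_equal(mean_count_within(core, r),
                   mean(oracle_count_within(pts$x[seq_len(n_c)], pts$y[seq_len(n_c)],
                                            pts$x[-seq_len(n_c)], pts$y[-seq_len(n_c)],
                                            r)),
                   tolerance = 1e-12)
    }
  }
})

test_that("NND percentiles use linear interpolation and truncate at 600", {
  d <- c(0, 10, 20, 30)
  q <- summarize_nnd(d)
  expect_equal(unname(q["nnd_p50"]), 15)
  expect_equal(unname(q["nnd_p25"]), 7.5)  # h = (n-1)q + 1 convention
  expect_equal(unname(q["nnd_p10"]), 3)

  # zero-TAM sentinel distances collapse to the truncation value
  expect_equal(unname(summarize_nnd(rep(Inf, 7))), c(600, 600, 600))
  expect_equal(unname(summarize_nnd(c(20, 700, Inf), truncation = 600)[3]), 600)
  expect_error(summarize_nnd(numeric(0)), "empty")
})

test_that("disc-count means respect the strict radius", {
  core <- make_labelled_core(cx = 0, cy = 0, tx = c(5, 20), ty = c(0, 0))
  expect_equal(mean_count_within(core, 12), 1)
  expect_equal(mean_count_within(core, 250), 2)
  expect_equal(mean_count_within(core, 5), 0)   # strict: d = 5 not < 5
  expect_error(mean_count_within(core, 0), "positive")

  shared <- make_labelled_core(cx = c(-1, 1), cy = c(0, 0),
                               tx = c(0, 2, -2), ty = c(1, 0, 0))
  expect_equal(mean_count_within(shared, 12), 3)
})

test_that("the metric suite applies zero-TAM conventions and invariants", {
  set.seed(31)
  pts <- runif_disc_pts(60, 280)
  core <- make_labelled_core(cx = pts$x[1:10], cy = pts$y[1:10],
                             tx = pts$x[11:15], ty = pts$y[11:15],
                             nx = pts$x[16:60], ny = pts$y[16:60])
  m <- compute_metric_suite(core)
  expect_equal(m$tam_count, 5)
  expect_equal(m$tam_proportion, 5 / 50)
  expect_true(m$nnd_p10 <= m$nnd_p25 && m$nnd_p25 <= m$nnd_p50)
  expect_true(m$adj_mean <= m$comm_mean && m$comm_mean <= m$tam_count)

  zero <- make_labelled_core(cx = pts$x[1:10], cy = pts$y[1:10],
                             tx = numeric(0), ty = numeric(0),
                             nx = pts$x[11:20], ny = pts$y[11:20])
  mz <- compute_metric_suite(zero)
  expect_equal(mz$tam_count, 0)
  expect_equal(mz$tam_proportion, 0)
  expect_equal(c(mz$nnd_p10, mz$nnd_p25, mz$nnd_p50), c(600, 600, 600))
  expect_equal(c(mz$adj_mean, mz$comm_mean), c(0, 0))
})

test_that("metrics are invariant under rigid motions", {
  set.seed(32)
  core <- generate_core(small_core_spec(), seed = 32)
  utl <- background_utl(core)
  core <- classify_tams(core, utl)
  m0 <- compute_metric_suite(core)[, -(1:2)]

  th <- 0.83
  rot <- core
  x <- core$cells$x; y <- core$cells$y
  rot$cells$x <- cos(th) * x - sin(th) * y + 40
  rot$cells$y <- sin(th) * x + cos(th) * y - 15
  rot$window <- list(cx = 40, cy = -15, diameter = core$window$diameter)
  expect_equal(compute_metric_suite(rot)[, -(1:2)], m0, tolerance = 1e-9)

  refl <- core
  refl$cells$x <- -core$cells$x
  expect_equal(compute_metric_suite(refl)[, -(1:2)], m0, tolerance = 1e-9)
})

test_that("adding a TAM never increases any cancer cell's NND", {
  set.seed(33)
  for (i in 1:20) {
    pts <- runif_disc_pts(40, 280)
    core <- make_labelled_core(cx = pts$x[1:20], cy = pts$y[1:20],
                               tx = pts$x[21:30], ty = pts$y[21:30])
    d0 <- nnd_set(core)
    plus <- make_labelled_core(cx = pts$x[1:20], cy = pts$y[1:20],
                               tx = pts$x[21:31], ty = pts$y[21:31])
    expect_true(all(nnd_set(plus) <= d0 + 1e-12))
  }
})
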