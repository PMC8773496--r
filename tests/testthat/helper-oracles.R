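## Independent brute-force oracles and small fixture builders.
## These deliberately use naive loop-based code paths, distinct from the
## package internals they check.

runif_disc_pts <- function(n, R = 300) {
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(x = r * cos(th), y = r * sin(th))
}

## Exhaustive scan for the smallest UTL rank by direct binomial summation.
oracle_utl_rank <- function(n, p = 0.95, gamma = 0.99) {
  for (r in 1:n) {
    cover <- sum(choose(n, 0:(r - 1)) * p^(0:(r - 1)) * (1 - p)^(n - (0:(r - 1))))
    if (cover >= gamma) return(list(rank = r, degenerate = FALSE))
  }
  list(rank = n, degenerate = TRUE)
}

## Per-cancer-cell nearest-TAM distance by an explicit loop.
oracle_nnd <- function(cx, cy, tx, ty) {
  if (length(tx) == 0) return(rep(Inf, length(cx)))
  out <- numeric(length(cx))
  for (i in seq_along(cx))
    out[i] <- min(sqrt((cx[i] - tx)^2 + (cy[i] - ty)^2))
  out
}

## Per-cancer-cell count of TAMs strictly within r, explicit loop.
oracle_count_within <- function(cx, cy, tx, ty, r) {
  out <- integer(length(cx))
  if (length(tx) == 0) return(out)
  for (i in seq_along(cx))
    out[i] <- sum(sqrt((cx[i] - tx)^2 + (cy[i] - ty)^2) < r)
  out
}

## Standardized log-rank split statistic for every candidate threshold,
## computed from first principles (explicit Nelson-Aalen loop over event
## times, permutation variance).
oracle_split_scan <- function(x, time, event, min_leaf = 7) {
  n <- length(x)
  a <- numeric(n)
  for (i in seq_len(n)) {
    lam <- 0
    for (ut in sort(unique(time[event == 1]))) {
      if (ut > time[i]) break
      lam <- lam + sum(time == ut & event == 1) / sum(time >= ut)
    }
    a[i] <- event[i] - lam
  }
  u <- sort(unique(x))
  cand <- (u[-length(u)] + u[-1]) / 2
  stat <- rep(NA_real_, length(cand))
  for (j in seq_along(cand)) {
    low <- x <= cand[j]
    n1 <- sum(low)
    if (n1 < min_leaf || n - n1 < min_leaf) next
    S <- sum(a[low])
    V <- n1 * (n - n1) / (n * (n - 1)) * sum(a^2)
    stat[j] <- S^2 / V
  }
  list(cand = cand, stat = stat)
}

## Two-sided Fisher p by exhaustive enumeration of all tables with the
## observed margins (sum of probabilities <= the observed one).
oracle_fisher_2x3 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  logp <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(m))
  }
  p_obs <- logp(tab)
  tot <- 0
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
    cc <- rs[1] - a - b
    if (cc < 0 || cc > cs[3]) next
    m <- rbind(c(a, b, cc), c(cs[1] - a, cs[2] - b, cs[3] - cc))
    if (any(m < 0)) next
    lp <- logp(m)
    if (lp <= p_obs + 1e-7) tot <- tot + exp(lp)
  }
  tot
}

## Small deterministic core: explicit coordinates and intensities.
make_toy_core <- function(cancer_xy, stromal_xy, cancer_int, stromal_int,
                          core_id = "c1", patient_id = "p1",
                          diameter = 600) {
  cells <- data.frame(
    x = c(cancer_xy[, 1], stromal_xy[, 1]),
    y = c(cancer_xy[, 2], stromal_xy[, 2]),
    compartment = c(rep("cancer", nrow(cancer_xy)),
                    rep("stromal", nrow(stromal_xy))),
    cd163 = c(cancer_int, stromal_int))
  core_table(core_id, patient_id, cells,
             window = list(cx = 0, cy = 0, diameter = diameter))
}

## Labelled toy core straight from mark vectors (skips phenotyping).
make_labelled_core <- function(cx, cy, tx, ty, nx = numeric(0),
                               ny = numeric(0), diameter = 1300) {
  cells <- data.frame(
    x = c(cx, tx, nx), y = c(cy, ty, ny),
    compartment = c(rep("cancer", length(cx)), rep("stromal", length(tx) + length(nx))),
    cd163 = 1)
  core <- core_table("c1", "p1", cells,
                     window = list(cx = 0, cy = 0, diameter = diameter))
  core$cells$tam <- c(rep(FALSE, length(cx)), rep(TRUE, length(tx)),
                      rep(FALSE, length(nx)))
  core
}

## Small-core generator spec for property tests (cheap but structurally
## identical to the defaults).
small_core_spec <- function(...) {
  core_gen_spec(n_cancer = 60, n_stromal = 120, ...)
}

small_cohort_spec <- function(n_patients = 60, ...) {
  cohort_gen_spec(n_patients = n_patients, core = small_core_spec(), ...)
}

## Simple null survival data (metric independent of outcome).
gen_null_surv <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(x = runif(n),
             time = rexp(n, 0.1),
             event = rbinom(n, 1, 0.7))
}
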