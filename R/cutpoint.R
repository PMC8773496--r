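## Log-rank scores a_i = delta_i - NelsonAalen(t_i). The two-sample
## log-rank numerator for any split equals the sum of scores on one side,
## and the scores sum to zero overall.
logrank_scores <- function(time, event) {
  as.numeric(event) - nelson_aalen_at(time, event)
}

## Nelson-Aalen cumulative hazard at each observation, input pre-sorted by
## time (ties allowed).
.nelson_aalen_sorted <- function(t_s, d_s) {
  n <- length(t_s)
  uniq <- !duplicated(t_s)
  n_risk <- n - (which(uniq) - 1L)
  grp <- cumsum(uniq)
  d_u <- as.vector(rowsum(d_s, grp))
  cumsum(d_u / n_risk)[grp]
}

## Maximally-selected standardized log-rank statistic over all candidate
## midpoints. xs ascending; a_s the log-rank scores in the same order.
.split_scan <- function(xs, a_s, min_leaf) {
  n <- length(xs)
  if (n < 2) return(NULL)
  last <- c(which(xs[-1] != xs[-n]), n)
  if (length(last) < 2) return(NULL)
  u <- xs[last]
  nl <- last[-length(last)]
  mid <- (u[-length(u)] + u[-1]) / 2
  keep <- nl >= min_leaf & (n - nl) >= min_leaf
  if (!any(keep)) return(NULL)
  sig2 <- sum(a_s^2)
  if (sig2 <= 0) return(NULL)
  S <- cumsum(a_s)[nl]
  varS <- nl * (n - nl) / (n * (n - 1)) * sig2
  z2 <- S^2 / varS
  z2[!keep] <- -Inf
  j <- which.max(z2)
  list(cut = mid[j], stat = z2[j], S = S[j], n_candidates = sum(keep))
}

#' Survival-tree first split for one metric
#'
#' Finds the single best dichotomizing threshold for a continuous metric
#' against right-censored survival: candidate thresholds are the midpoints
#' between consecutive unique metric values whose resulting groups both
#' contain at least `min_leaf` observations, and the candidate maximizing
#' the standardized two-sample log-rank statistic (score form, permutation
#' variance — the maximally-selected log-rank statistic) is chosen. With
#' `cv = TRUE` the split is retained only if the 10-fold cross-validated
#' predictive deviance of the one-split exponential survival model does
#' not exceed that of the no-split model, mirroring the pruning of a
#' cross-validated survival tree; otherwise the result is "no split".
#'
#' @param x Metric values.
#' @param time,event Survival outcome.
#' @param min_leaf Minimum observations on each side of a split, default 7
#'   (the conventional survival-tree leaf size).
#' @param min_split Minimum sample size to attempt a split, default 20.
#' @param folds Cross-validation folds, default 10.
#' @param cv Apply the cross-validated retention check?
#' @param seed Optional seed for the fold assignment; when `NULL` the
#'   current RNG stream is used (so enclosing bootstrap loops stay
#'   reproducible from a single seed).
#' @return List with `cutpoint` (`NA` if no split), `statistic` (the
#'   maximal standardized log-rank chi-square), `retained`, `direction`
#'   (`"gt"` if values above the cutpoint carry the higher risk, else
#'   `"lt"`), `n_candidates`, `reason`.
#' @export
tree_cutpoint <- function(x, time, event, min_leaf = 7, min_split = 20,
                          folds = 10, cv = TRUE, seed = NULL) {
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  no_split <- function(reason)
    list(cutpoint = NA_real_, statistic = NA_real_, retained = FALSE,
         direction = NA_character_, n_candidates = 0L, reason = reason)
  if (n < max(min_split, 2 * min_leaf)) return(no_split("too_few"))
  ev <- as.numeric(event)
  if (sum(ev) < 1) return(no_split("no_events"))
  ord_t <- order(time)
  t_s <- time[ord_t]; e_s <- ev[ord_t]
  a <- numeric(n)
  a[ord_t] <- e_s - .nelson_aalen_sorted(t_s, e_s)
  ord_x <- order(x)
  xs <- x[ord_x]
  if (xs[1] == xs[n]) return(no_split("constant_metric"))
  best <- .split_scan(xs, a[ord_x], min_leaf)
  if (is.null(best)) return(no_split("no_candidates"))
  cutoff <- best$cut
  direction <- if (best$S > 0) "lt" else "gt" # positive score sum = excess
                                              # events in the low group
  retained <- TRUE
  if (cv && folds > 1) {
    ## honest cross-validation of the one-split model class: the split is
    ## re-derived on each training fold and its held-out exponential
    ## deviance compared with the no-split model
    set_seed_if(seed)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    f_t <- fold_id[ord_t]; f_x <- fold_id[ord_x]
    t_x <- time[ord_x]; e_x <- ev[ord_x]
    a_tmp <- numeric(n)
    dev_null <- dev_split <- 0
    rate <- function(d, tt, fb) if (tt > 0) (d + 0.5) / tt else fb
    for (f in seq_len(folds)) {
      tr_t <- f_t != f
      if (!any(tr_t) || all(tr_t)) next
      a_tmp[ord_t[tr_t]] <- e_s[tr_t] - .nelson_aalen_sorted(t_s[tr_t],
                                                             e_s[tr_t])
      tr_x <- f_x != f
      te_x <- !tr_x
      l0 <- rate(sum(e_x[tr_x]), sum(t_x[tr_x]), NA)
      dev_null <- dev_null + 2 * (l0 * sum(t_x[te_x]) -
                                    log(l0) * sum(e_x[te_x]))
      bs <- .split_scan(xs[tr_x], a_tmp[ord_x][tr_x], min_leaf)
      if (is.null(bs)) {                   # fold with no split: null model
        dev_split <- dev_split + 2 * (l0 * sum(t_x[te_x]) -
                                        log(l0) * sum(e_x[te_x]))
        next
      }
      hi_tr <- xs > bs$cut & tr_x
      lo_tr <- xs <= bs$cut & tr_x
      lh <- rate(sum(e_x[hi_tr]), sum(t_x[hi_tr]), l0)
      ll <- rate(sum(e_x[lo_tr]), sum(t_x[lo_tr]), l0)
      hi_te <- xs > bs$cut & te_x
      lo_te <- te_x & !hi_te
      dev_split <- dev_split +
        2 * (lh * sum(t_x[hi_te]) - log(lh) * sum(e_x[hi_te])) +
        2 * (ll * sum(t_x[lo_te]) - log(ll) * sum(e_x[lo_te]))
    }
    retained <- dev_split <= dev_null
  }
  list(cutpoint = cutoff, statistic = best$stat, retained = retained,
       direction = direction, n_candidates = best$n_candidates,
       reason = if (retained) NA_character_ else "cv_pruned")
}

#' Bootstrap distribution of survival-tree cutpoints
#'
#' Draws `B` bootstrap samples with replacement, derives the
#' cross-validated survival-tree cutpoint in each, and summarizes the
#' retained cutpoints: the median is the reported dichotomization
#' threshold and the 5th/95th percentiles form its non-parametric 90%
#' confidence interval. Bootstrap samples in which no split is retained
#' are excluded from the quantiles and counted in `n_failed`.
#'
#' @inheritParams tree_cutpoint
#' @param B Number of bootstrap samples, default 1000.
#' @param seed Seed for the full resampling + fold stream.
#' @return Object of class `cutpoint_result`: `cutpoint`, `ci90`,
#'   `direction`, `bootstrap_cutoffs`, `n_failed`, `B`.
#' @export
bootstrap_cutpoint <- function(x, time, event, B = 1000, seed = NULL,
                               min_leaf = 7, min_split = 20, folds = 10,
                               cv = TRUE) {
  set_seed_if(seed)
  n <- length(x)
  cuts <- rep(NA_real_, B)
  dirs <- character(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tree_cutpoint(x[idx], time[idx], event[idx], min_leaf = min_leaf,
                         min_split = min_split, folds = folds, cv = cv,
                         seed = NULL)
    if (res$retained) {
      cuts[b] <- res$cutpoint
      dirs[b] <- res$direction
    }
  }
  ok <- !is.na(cuts)
  if (!any(ok))
    stop("no bootstrap sample yielded a retained split; the metric effect ",
         "or the sample size is too small for data-driven dichotomization")
  direction <- names(sort(table(dirs[ok]), decreasing = TRUE))[1]
  structure(list(
    cutpoint = stats::median(cuts[ok]),
    ci90 = stats::quantile(cuts[ok], c(0.05, 0.95), names = FALSE, type = 7),
    direction = direction,
    bootstrap_cutoffs = cuts[ok],
    n_failed = sum(!ok), B = B), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Bootstrap survival-tree cutpoint: %.4g (90%% CI %.4g-%.4g)\n",
              x$cutpoint, x$ci90[1], x$ci90[2]))
  cat(sprintf("  high-risk side: %s cutpoint; %d/%d bootstrap samples",
              if (identical(x$direction, "gt")) "above" else "below",
              x$B - x$n_failed, x$B),
      "retained a split\n")
  invisible(x)
}

#' Dichotomize a metric at a cutoff
#'
#' `"high"` iff the value is strictly above the cutoff (a value exactly at
#' the cutoff is `"low"`; cutpoints are placed at midpoints between
#' observed values, so no observed value sits on the boundary). For
#' metrics whose risk direction is inverted — such as the NND percentiles,
#' where short distances carry the risk — `direction = "lt"` swaps the
#' labels so that `"high"` always denotes the high-metric side being
#' reported against, never silently reassigning risk.
#'
#' @param x Metric values.
#' @param cutoff Finite threshold.
#' @param direction `"gt"` (default): high iff `x > cutoff`; `"lt"`:
#'   labels swapped.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(x, cutoff, direction = c("gt", "lt")) {
  direction <- match.arg(direction)
  stopifnot(is.finite(cutoff))
  g <- x > cutoff
  if (direction == "lt") g <- !g
  factor(ifelse(g, "high", "low"), levels = c("low", "high"))
}

#' Combined 3-category CD163+ TAM marker
#'
#' Combines the dichotomized communicating-TAM count with the dichotomized
#' median cancer-to-TAM NND into three risk categories:
#' 1 = low communicating count and high median NND (reference, lowest
#' risk); 2 = low communicating count and low median NND; 3 = high
#' communicating count regardless of median NND. Missing inputs propagate
#' as missing categories.
#'
#' @param comm_high Logical (or `low`/`high` factor): high communicating
#'   TAM count.
#' @param nnd_median_low Logical (or factor): low median cancer-to-TAM NND.
#' @return Factor with levels `"1"`, `"2"`, `"3"` (reference `"1"`).
#' @export
combined_marker <- function(comm_high, nnd_median_low) {
  as_l <- function(v) if (is.logical(v)) v else v == "high" | v == TRUE
  ch <- as_l(comm_high)
  nl <- if (is.logical(nnd_median_low)) nnd_median_low else
    nnd_median_low == "high" | nnd_median_low == TRUE
  out <- ifelse(is.na(ch) | (!ch & is.na(nl)), NA_character_,
         ifelse(ch, "3", ifelse(nl, "2", "1")))
  factor(out, levels = c("1", "2", "3"))
}
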