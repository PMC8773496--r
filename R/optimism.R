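#' Bootstrap optimism correction for a data-driven dichotomized marker
#'
#' Quantifies and removes the optimistic bias incurred by deriving a
#' dichotomization cutpoint and estimating its hazard ratio on the same
#' data. For each of `B` bootstrap samples (drawn with replacement from a
#' complete dataset): the survival-tree cutpoint is derived in the
#' resample; the Cox model with the marker dichotomized at that cutpoint
#' is fitted in the resample ("bootstrap performance") and in the original
#' dataset ("test performance"); the per-replicate optimism is the
#' difference of the two coefficient vectors. The mean optimism over
#' replicates is subtracted from the "apparent" coefficients (the fit at
#' the cutpoint derived on the original dataset itself).
#'
#' By default the cutpoint rule inside this procedure is the maximally
#' selected log-rank split without the cross-validated retention step
#' (`cv = FALSE`), so the dichotomized marker is defined in every dataset
#' and replicate; replicates where no candidate split exists or a fit is
#' degenerate are skipped and counted (a warning is raised above 20%).
#'
#' @param data Complete `data.frame` (post-imputation).
#' @param marker Name of the metric column to dichotomize, or a length-2
#'   vector `c(communicating_metric, nnd_metric)` for the combined
#'   3-category marker.
#' @param formula `Surv(time, event) ~ covariates` (use `~ 1` for the
#'   univariate model). The marker term is added internally.
#' @param B Bootstrap replicates, default 500.
#' @param seed Seed for the resampling stream.
#' @param min_leaf,min_split,folds,cv Passed to [tree_cutpoint()].
#' @param strata_vars Covariates to stratify on (see [cox_fit()]).
#' @param .resample Testing hook: function of `n` returning resample
#'   indices (default sampling with replacement).
#' @return Object of class `optimism_result` with per-term `apparent`,
#'   `optimism_mean`, `corrected`, `se_apparent`, plus `cutpoint`,
#'   `boot_cutpoints`, `n_skipped`, `B`.
#' @export
optimism_correct <- function(data, marker, formula, B = 500, seed = NULL,
                             min_leaf = 7, min_split = 20, folds = 10,
                             cv = FALSE, strata_vars = NULL,
                             .resample = NULL) {
  set_seed_if(seed)
  env <- .optimism_env(data, marker, formula, strata_vars)
  tc <- function(xcol, idx) tree_cutpoint(
    xcol[idx], env$time[idx], env$event[idx], min_leaf = min_leaf,
    min_split = min_split, folds = folds, cv = cv, seed = NULL)
  n <- length(env$time)
  all_idx <- seq_len(n)
  # apparent cutpoint(s) and fit on the original data
  ct0 <- lapply(env$xcols, tc, idx = all_idx)
  if (any(vapply(ct0, function(r) is.na(r$cutpoint), NA)))
    stop("no candidate split on the original dataset for marker '",
         paste(marker, collapse = "', '"), "'")
  cut0 <- vapply(ct0, `[[`, 0, "cutpoint")
  fit0 <- env$fit_at(cut0, all_idx, all_idx)
  if (is.null(fit0))
    stop("apparent Cox fit failed for marker '",
         paste(marker, collapse = "', '"), "'")
  p <- length(fit0$coef)
  resample <- .resample %||% function(n) sample.int(n, n, replace = TRUE)
  opt <- matrix(NA_real_, B, p)
  boot_cuts <- matrix(NA_real_, B, length(env$xcols))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- resample(n)
    ctb <- lapply(env$xcols, tc, idx = idx)
    if (any(vapply(ctb, function(r) is.na(r$cutpoint), NA))) {
      skipped <- skipped + 1L
      next
    }
    cutb <- vapply(ctb, `[[`, 0, "cutpoint")
    fit_boot <- env$fit_at(cutb, idx, idx)
    fit_test <- env$fit_at(cutb, all_idx, all_idx)
    if (is.null(fit_boot) || is.null(fit_test)) {
      skipped <- skipped + 1L
      next
    }
    opt[b, ] <- fit_boot$coef - fit_test$coef
    boot_cuts[b, ] <- cutb
  }
  if (skipped > 0.2 * B)
    warning(sprintf("%d of %d bootstrap replicates skipped", skipped, B))
  ok <- !is.na(opt[, 1])
  if (!any(ok))
    stop("all bootstrap replicates failed; increase the sample size or ",
         "the effect")
  optimism_mean <- colMeans(opt[ok, , drop = FALSE])
  se <- sqrt(diag(fit0$var))
  structure(list(
    terms = names(fit0$coef),
    apparent = fit0$coef,
    optimism_mean = stats::setNames(optimism_mean, names(fit0$coef)),
    corrected = fit0$coef - optimism_mean,
    se_apparent = stats::setNames(se, names(fit0$coef)),
    var_apparent = fit0$var,
    cutpoint = cut0,
    boot_cutpoints = boot_cuts[ok, , drop = FALSE],
    n_skipped = skipped, B = B, marker = marker),
    class = "optimism_result")
}

## Precompute the covariate design once; return closures that append the
## dichotomized marker column(s) for a given cutpoint and fit by
## survival::coxph.fit.
.optimism_env <- function(data, marker, formula, strata_vars) {
  stopifnot(length(marker) %in% c(1L, 2L), all(marker %in% names(data)))
  lhs <- eval(formula[[2]], data, environment(formula))
  if (!survival::is.Surv(lhs)) stop("formula must have a Surv() response")
  time <- lhs[, 1]
  event <- lhs[, 2]
  rhs_vars <- setdiff(all.vars(formula[[3]]), c("1", strata_vars))
  model_cols <- unique(c(rhs_vars, strata_vars, marker))
  if (anyNA(data[model_cols]))
    stop("optimism_correct requires complete data; impute first")
  X0 <- if (length(rhs_vars) == 0) {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  } else {
    stats::model.matrix(stats::reformulate(rhs_vars), data = data)[, -1, drop = FALSE]
  }
  strata <- if (is.null(strata_vars) || length(strata_vars) == 0) NULL else {
    binned <- lapply(strata_vars, function(v) .strata_bin(data[[v]], v))
    as.integer(interaction(binned, drop = TRUE))
  }
  xcols <- lapply(marker, function(mcol) data[[mcol]])
  names(xcols) <- marker
  combined <- length(marker) == 2L
  y0 <- survival::Surv(time, event)
  ctrl <- survival::coxph.control()
  fit_at <- function(cut, fit_idx, dich_idx) {
    # dich_idx indexes the rows whose marker values are dichotomized;
    # for both uses here it equals fit_idx's source rows.
    if (combined) {
      ch <- xcols[[1]][fit_idx] > cut[1]
      nl <- !(xcols[[2]][fit_idx] > cut[2])
      cat2 <- !ch & nl
      cat3 <- ch
      if (!any(cat2) || !any(cat3) || all(cat2 | cat3)) return(NULL)
      M <- cbind(marker_cat2 = as.numeric(cat2),
                 marker_cat3 = as.numeric(cat3))
    } else {
      hi <- xcols[[1]][fit_idx] > cut[1]
      if (!any(hi) || all(hi)) return(NULL)
      M <- cbind(marker_high = as.numeric(hi))
    }
    X <- cbind(X0[fit_idx, , drop = FALSE], M)
    out <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        X, y0[fit_idx], strata = if (is.null(strata)) NULL else strata[fit_idx],
        offset = NULL, init = NULL, control = ctrl, weights = NULL,
        method = "efron", rownames = NULL)),
      error = function(e) NULL)
    if (is.null(out) || is.null(out$coefficients) ||
        anyNA(out$coefficients) || any(!is.finite(out$coefficients)) ||
        any(abs(out$coefficients) > 15))
      return(NULL)
    list(coef = out$coefficients, var = out$var)
  }
  list(time = time, event = event, xcols = xcols, fit_at = fit_at,
       combined = combined)
}

#' @export
print.optimism_result <- function(x, ...) {
  cat("Bootstrap optimism correction (B =", x$B, ",",
      x$n_skipped, "skipped)\n")
  cat("  marker:", paste(x$marker, collapse = " + "),
      "; cutpoint(s):", paste(signif(x$cutpoint, 4), collapse = ", "), "\n")
  tab <- data.frame(term = x$terms, apparent = x$apparent,
                    optimism = x$optimism_mean, corrected = x$corrected,
                    se = x$se_apparent, row.names = NULL)
  print(tab, digits = 3)
  invisible(x)
}
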