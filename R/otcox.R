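#' Optimism-corrected Cox model with data-driven dichotomization
#'
#' The central model fit of the package: for a continuous spatial metric
#' (or a pair of metrics forming the combined 3-category marker), `otcox`
#' (i) derives the dichotomization threshold and its non-parametric 90%
#' confidence interval from `B_cutpoint` bootstrap survival trees,
#' (ii) multiply imputes missing covariates by chained equations when
#' needed, (iii) checks the proportional-hazards assumption and moves
#' violating covariates into strata, (iv) runs the bootstrap optimism
#' correction of the full coefficient vector within each completed
#' dataset, and (v) pools the corrected log hazard ratios across
#' imputations by Rubin's rule.
#'
#' @param formula `Surv(time, event) ~ covariates`; use `~ 1` for a
#'   univariate marker model. The marker term is added internally.
#' @param data `data.frame` holding outcome, covariates and metric
#'   columns. Outcome and metric must be complete; covariates may have
#'   missing values.
#' @param marker Metric column to dichotomize, or length-2
#'   `c(communicating_metric, nnd_metric)` for the combined marker.
#' @param direction `"auto"` (risk direction learned from the data),
#'   `"gt"` (values above the cutoff are high-risk) or `"lt"`. Only used
#'   for a single marker.
#' @param B_cutpoint Bootstrap samples for the threshold distribution
#'   (default 1000).
#' @param B_optimism Bootstrap samples for the optimism correction
#'   (default 500).
#' @param m Imputations when covariates are incomplete (default 40).
#' @param maxit Chained-equation sweeps (default 10).
#' @param min_leaf,min_split,folds Survival-tree controls.
#' @param ph_alpha Level of the proportional-hazards score test used to
#'   flag covariates for stratification.
#' @param strata_vars Covariates to stratify on a priori.
#' @param seed Seed controlling every random element of the fit.
#' @return Object of class `otcox`; see [summary.otcox()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_gen_spec(n_patients = 120), seed = 7)
#' fit <- otcox(survival::Surv(pfs_months, progressed) ~ grade + node,
#'              data = cohort$clinical, marker = "comm_mean",
#'              B_cutpoint = 50, B_optimism = 50, m = 2, seed = 1)
#' print(fit)
#' }
#' @export
otcox <- function(formula, data, marker, direction = "auto",
                  B_cutpoint = 1000, B_optimism = 500, m = 40, maxit = 10,
                  min_leaf = 7, min_split = 20, folds = 10,
                  ph_alpha = 0.05, strata_vars = NULL, seed = NULL) {
  cl <- match.call()
  stopifnot(length(marker) %in% c(1L, 2L), all(marker %in% names(data)))
  seeds <- derive_seeds(seed, 4)
  lhs <- eval(formula[[2]], data, environment(formula))
  if (!survival::is.Surv(lhs)) stop("formula must have a Surv() response")
  time <- lhs[, 1]; event <- lhs[, 2]
  if (anyNA(time) || anyNA(event) || anyNA(data[marker]))
    stop("outcome and marker column(s) must be complete")

  ## (i) threshold + 90% CI per metric
  cutres <- lapply(seq_along(marker), function(i)
    bootstrap_cutpoint(data[[marker[i]]], time, event, B = B_cutpoint,
                       seed = if (is.null(seed)) NULL else seeds[[i]],
                       min_leaf = min_leaf, min_split = min_split,
                       folds = folds, cv = TRUE))
  names(cutres) <- marker
  cutoff <- vapply(cutres, `[[`, 0, "cutpoint")
  if (length(marker) == 1L && direction == "auto")
    direction <- cutres[[1]]$direction

  ## (ii) imputation of incomplete covariates
  rhs_vars <- setdiff(all.vars(formula[[3]]), "1")
  needs_mi <- length(rhs_vars) > 0 && anyNA(data[rhs_vars])
  tecols <- .find_outcome_cols(formula, data)
  imp <- if (needs_mi) {
    mice_impute(data, covariates = rhs_vars, time_col = tecols["time"],
                event_col = tecols["event"], m = m, maxit = maxit,
                seed = seeds[[3]])
  } else {
    structure(list(datasets = list(data), m = 1L, methods = character(),
                   seed = NULL), class = "imputation_set")
  }

  ## (iii) PH diagnostics on the first completed dataset
  d1 <- imp$datasets[[1]]
  d1$.marker_grp <- .marker_group(d1, marker, cutoff, direction)
  ph_formula <- stats::reformulate(c(if (length(rhs_vars)) rhs_vars else NULL,
                                     ".marker_grp"),
                                   response = formula[[2]])
  environment(ph_formula) <- environment(formula)
  ph_tab <- NULL
  violators <- character()
  fit_ph <- tryCatch(cox_fit(ph_formula, d1, strata_vars = strata_vars),
                     error = function(e) NULL)
  if (!is.null(fit_ph)) {
    ph_tab <- tryCatch(ph_check(fit_ph, alpha = ph_alpha),
                       error = function(e) NULL)
    if (!is.null(ph_tab))
      violators <- intersect(ph_tab$term[ph_tab$violates], rhs_vars)
  }
  strata_all <- union(strata_vars %||% character(), violators)

  ## (iv) optimism correction per completed dataset
  opt_seeds <- derive_seeds(seeds[[4]] %||% NULL, imp$m)
  opts <- lapply(seq_len(imp$m), function(k)
    optimism_correct(imp$datasets[[k]], marker, formula, B = B_optimism,
                     seed = opt_seeds[[k]], min_leaf = min_leaf,
                     min_split = min_split, folds = folds,
                     strata_vars = if (length(strata_all)) strata_all else NULL))

  ## (v) Rubin pooling of corrected (and apparent) coefficients
  terms <- opts[[1]]$terms
  corr <- do.call(rbind, lapply(opts, `[[`, "corrected"))
  appa <- do.call(rbind, lapply(opts, `[[`, "apparent"))
  vars <- do.call(rbind, lapply(opts, function(o) o$se_apparent^2))
  pool <- lapply(seq_along(terms), function(j)
    rubin_pool(corr[, j], vars[, j]))
  pool_app <- vapply(seq_along(terms), function(j)
    mean(appa[, j]), 0)
  tab <- data.frame(
    term = terms,
    loghr_apparent = pool_app,
    loghr = vapply(pool, `[[`, 0, "estimate"),
    se = vapply(pool, `[[`, 0, "se"),
    hr = exp(vapply(pool, `[[`, 0, "estimate")),
    ci_lower = exp(vapply(pool, function(p) p$ci[1], 0)),
    ci_upper = exp(vapply(pool, function(p) p$ci[2], 0)),
    p = vapply(pool, `[[`, 0, "p"),
    stringsAsFactors = FALSE)

  ## reporting contrast for an inverted-direction marker (e.g. NND:
  ## short distances are the risky side -> report "low vs high")
  if (length(marker) == 1L) {
    i <- tab$term == "marker_high"
    if (direction == "lt") {
      tab$loghr[i] <- -tab$loghr[i]
      tab$loghr_apparent[i] <- -tab$loghr_apparent[i]
      ci <- cbind(1 / tab$ci_upper[i], 1 / tab$ci_lower[i])
      tab$hr[i] <- exp(tab$loghr[i])
      tab$ci_lower[i] <- ci[, 1]; tab$ci_upper[i] <- ci[, 2]
      tab$term[i] <- paste0("Low vs high ", marker)
    } else tab$term[i] <- paste0("High vs low ", marker)
  } else {
    tab$term[tab$term == "marker_cat2"] <-
      paste0("Low ", marker[1], " & low ", marker[2], " (2 vs 1)")
    tab$term[tab$term == "marker_cat3"] <-
      paste0("High ", marker[1], " (3 vs 1)")
  }

  structure(list(
    call = cl, formula = formula, marker = marker, direction = direction,
    cutpoints = cutres, cutoff = cutoff, table = tab, ph = ph_tab,
    strata_vars = strata_all, m = imp$m, B_cutpoint = B_cutpoint,
    B_optimism = B_optimism,
    n = length(time), nevent = sum(event),
    n_skipped = vapply(opts, `[[`, 0L, "n_skipped"),
    data1 = d1, time = time, event = event, seed = seed),
    class = "otcox")
}

.find_outcome_cols <- function(formula, data) {
  sv <- formula[[2]]
  vars <- all.vars(sv)
  if (length(vars) < 2) stop("cannot identify time/event columns")
  c(time = vars[1], event = vars[2])
}

.marker_group <- function(data, marker, cutoff, direction) {
  if (length(marker) == 1L) {
    dichotomize(data[[marker]], cutoff[1],
                if (direction %in% c("gt", "lt")) direction else "gt")
  } else {
    ch <- data[[marker[1]]] > cutoff[1]
    nl <- !(data[[marker[2]]] > cutoff[2])
    combined_marker(ch, nl)
  }
}

#' @export
print.otcox <- function(x, digits = 3, ...) {
  cat("Optimism-corrected Cox model with data-driven dichotomization\n")
  cat("  n =", x$n, ", events =", x$nevent,
      "; imputations m =", x$m, "\n")
  for (mk in x$marker) {
    cr <- x$cutpoints[[mk]]
    cat(sprintf("  %s: cutpoint %.4g (90%% CI %.4g-%.4g)\n",
                mk, cr$cutpoint, cr$ci90[1], cr$ci90[2]))
  }
  if (length(x$strata_vars))
    cat("  strata:", paste(x$strata_vars, collapse = ", "), "\n")
  i <- grepl("^(High vs low|Low vs high|Low |High )", x$table$term)
  cat("  bias-adjusted marker effect(s):\n")
  print(x$table[i, c("term", "hr", "ci_lower", "ci_upper", "p")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summary of an optimism-corrected Cox fit
#'
#' @param object An [otcox()] fit.
#' @param ... Unused.
#' @return The full coefficient table (apparent and corrected log hazard
#'   ratios, pooled CIs and p-values), cutpoint results, PH diagnostics.
#' @export
summary.otcox <- function(object, ...) {
  structure(list(call = object$call, table = object$table,
                 cutpoints = object$cutpoints, ph = object$ph,
                 strata_vars = object$strata_vars, n = object$n,
                 nevent = object$nevent, m = object$m,
                 B_cutpoint = object$B_cutpoint,
                 B_optimism = object$B_optimism,
                 n_skipped = object$n_skipped),
            class = "summary.otcox")
}

#' @export
print.summary.otcox <- function(x, digits = 3, ...) {
  cat("Call:\n"); print(x$call)
  cat("\nn =", x$n, ", events =", x$nevent, ", imputations m =", x$m,
      ", B(cutpoint) =", x$B_cutpoint, ", B(optimism) =", x$B_optimism, "\n")
  for (mk in names(x$cutpoints)) print(x$cutpoints[[mk]])
  if (length(x$strata_vars))
    cat("Stratified covariates:", paste(x$strata_vars, collapse = ", "), "\n")
  cat("\nPooled bias-adjusted coefficients:\n")
  print(x$table, digits = digits, row.names = FALSE)
  if (!is.null(x$ph)) {
    cat("\nProportional-hazards score tests:\n")
    print(x$ph, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.otcox <- function(object, ...) {
  stats::setNames(object$table$loghr, object$table$term)
}

#' @export
confint.otcox <- function(object, parm, level = 0.95, ...) {
  # intervals on the log hazard-ratio scale
  out <- cbind(log(object$table$ci_lower), log(object$table$ci_upper))
  rownames(out) <- object$table$term
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Risk-group assignment for new data
#'
#' @param object An [otcox()] fit.
#' @param newdata `data.frame` containing the marker column(s).
#' @param ... Unused.
#' @return Factor of marker groups: `low`/`high` (where `high` is the
#'   high-risk side) or the combined marker categories `1`/`2`/`3`.
#' @export
predict.otcox <- function(object, newdata, ...) {
  .marker_group(newdata, object$marker, object$cutoff, object$direction)
}

#' Kaplan-Meier curves by dichotomized marker group
#'
#' @param x An [otcox()] fit.
#' @param col,lty Per-group graphical parameters.
#' @param ... Passed to `plot.survfit`.
#' @export
plot.otcox <- function(x, col = NULL, lty = 1, ...) {
  grp <- x$data1$.marker_grp
  sf <- survival::survfit(survival::Surv(x$time, x$event) ~ grp)
  k <- nlevels(grp)
  if (is.null(col)) col <- seq_len(k)
  graphics::plot(sf, col = col, lty = lty, xlab = "Months",
                 ylab = "Progression-free survival", ...)
  graphics::legend("bottomleft", legend = levels(grp), col = col,
                   lty = lty, bty = "n",
                   title = paste(x$marker, collapse = " + "))
  invisible(x)
}
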