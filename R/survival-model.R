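#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator of progression-free survival, optionally by
#' group.
#'
#' @param time Follow-up time (months).
#' @param event Event indicator (1 = progression, 0 = censored).
#' @param group Optional grouping factor.
#' @return `data.frame` with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  s <- summary(fit, censored = TRUE)
  g <- if (is.null(s$strata)) rep(levels(group)[1], length(s$time))
       else sub("^group=", "", as.character(s$strata))
  data.frame(group = g, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Thin wrapper around `survival::coxph` with the Efron tie convention,
#' explicit checks for degenerate covariates, and a tidy coefficient table
#' (log hazard ratio, SE, Wald 95% CI, p).
#'
#' @param formula `Surv(time, event) ~ covariates`.
#' @param data Model data.
#' @param strata_vars Character vector of variables to use as strata
#'   (continuous variables are binned into quartiles).
#' @param ties Tie-handling method, default `"efron"`.
#' @return Object of class `cox_fit`: the underlying `coxph` fit plus
#'   `table`, `n`, `nevent`, `strata_vars`, `converged`.
#' @export
cox_fit <- function(formula, data, strata_vars = NULL, ties = "efron") {
  mf_vars <- all.vars(formula[[3]])
  for (v in setdiff(mf_vars, "1")) {
    vals <- data[[v]]
    if (!is.null(vals) && length(unique(stats::na.omit(vals))) < 2)
      stop("covariate '", v, "' is constant; drop it or supply varying data")
  }
  if (!is.null(strata_vars) && length(strata_vars) > 0) {
    for (v in strata_vars) data[[v]] <- .strata_bin(data[[v]], v)
    rhs <- paste(c(deparse(formula[[3]]),
                   sprintf("strata(%s)", strata_vars)), collapse = " + ")
    keep <- setdiff(all.vars(formula[[3]]), strata_vars)
    rhs <- paste(c(if (length(keep)) keep else "1",
                   sprintf("strata(%s)", strata_vars)), collapse = " + ")
    formula <- stats::reformulate(rhs, response = formula[[2]])
    environment(formula) <- environment()
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties, x = TRUE,
                    model = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), loghr = co[, "coef"],
                    se = co[, "se(coef)"],
                    hr = exp(co[, "coef"]),
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(fit = fit, table = tab, n = fit$n, nevent = fit$nevent,
                 strata_vars = strata_vars, converged = converged,
                 formula = formula),
            class = "cox_fit")
}

.strata_bin <- function(x, name) {
  if (is.numeric(x) && length(unique(stats::na.omit(x))) > 4) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, 0.25), na.rm = TRUE))
    cut(x, breaks = br, include.lowest = TRUE)
  } else factor(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$nevent, "\n")
  if (!is.null(x$strata_vars) && length(x$strata_vars))
    cat("  strata:", paste(x$strata_vars, collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: fit flagged as non-converged\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$table$loghr, object$table$term)
}

#' Proportional-hazards diagnostics
#'
#' Scaled-Schoenfeld-residual score test per term; a term with p below
#' `alpha` is flagged as violating the proportional-hazards assumption.
#'
#' @param fit A [cox_fit()] result.
#' @param alpha Flagging level, default 0.05.
#' @return `data.frame` with `term`, `chisq`, `df`, `p`, `violates`.
#' @export
ph_check <- function(fit, alpha = 0.05) {
  zph <- survival::cox.zph(fit$fit)
  tab <- as.data.frame(zph$table)
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, violates = tab$p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Refit a Cox model with PH-violating covariates as strata
#'
#' Violating covariates are moved from the linear predictor into strata
#' (continuous covariates are binned into quartiles first); the stratified
#' terms no longer appear as coefficient rows. Strata levels without any
#' event trigger a warning.
#'
#' @param fit A [cox_fit()] result.
#' @param violators Character vector of covariate names to stratify on.
#' @return A new `cox_fit`.
#' @export
refit_with_strata <- function(fit, violators) {
  if (length(violators) == 0) return(fit)
  data <- fit$fit$model
  names(data)[1] <- ".surv"
  ## reconstruct the plain variables from the model frame
  f0 <- fit$formula
  rhs_vars <- setdiff(all.vars(f0[[3]]), violators)
  rhs <- paste(c(if (length(rhs_vars)) rhs_vars else "1",
                 sprintf("strata(%s)", violators)), collapse = " + ")
  for (v in violators) data[[v]] <- .strata_bin(data[[v]], v)
  new_formula <- stats::as.formula(paste(".surv ~", rhs))
  environment(new_formula) <- environment()
  converged <- TRUE
  newfit <- withCallingHandlers(
    survival::coxph(new_formula, data = data, ties = "efron", x = TRUE,
                    model = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  st <- survival::strata(data[violators], shortlabel = TRUE)
  ev <- fit$fit$y[, ncol(fit$fit$y)]
  noev <- tapply(ev, st, sum) == 0
  if (any(noev, na.rm = TRUE))
    warning("strata level(s) without events: ",
            paste(names(noev)[noev %in% TRUE], collapse = ", "))
  co <- summary(newfit)$coefficients
  tab <- data.frame(term = rownames(co), loghr = co[, "coef"],
                    se = co[, "se(coef)"], hr = exp(co[, "coef"]),
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(fit = newfit, table = tab, n = newfit$n,
                 nevent = newfit$nevent, strata_vars = violators,
                 converged = converged, formula = new_formula),
            class = "cox_fit")
}

## Fast Cox fit on a prebuilt design matrix; used inside bootstrap loops.
## Returns NULL when the fit is degenerate or fails.
fast_cox <- function(X, time, event, strata = NULL) {
  y <- survival::Surv(time, event)
  out <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      X, y, strata = strata, offset = NULL, init = NULL,
      control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(out) || is.null(out$coefficients) ||
      anyNA(out$coefficients) || any(!is.finite(out$coefficients)))
    return(NULL)
  if (any(abs(out$coefficients) > 15)) return(NULL)  # separation guard
  list(coef = out$coefficients, var = out$var)
}
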