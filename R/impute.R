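#' Chained-equation multiple imputation for survival covariates
#'
#' Fully conditional specification: each incomplete covariate is imputed
#' from a univariate model matched to its type (binary -> logistic,
#' unordered categorical -> multinomial, ordered -> proportional odds,
#' continuous -> Bayesian linear regression), cycling over variables for a
#' fixed number of sweeps. Following standard survival-imputation
#' practice, every imputation model's predictors include all other
#' covariates plus the event indicator and the marginal Nelson-Aalen
#' cumulative hazard transform of the follow-up time. Only covariates may
#' be missing; the outcome must be complete.
#'
#' @param data `data.frame` with complete `time`/`event` columns and
#'   possibly-incomplete covariates.
#' @param covariates Character vector of covariate columns to impute/use
#'   as predictors.
#' @param time_col,event_col Names of the outcome columns.
#' @param m Number of completed datasets, default 40.
#' @param maxit Chained-equation sweeps per dataset, default 10.
#' @param seed Seed for the whole procedure.
#' @return Object of class `imputation_set`: `datasets` (list of m
#'   completed data frames), `m`, `methods` (per-variable model type),
#'   `seed`.
#' @export
mice_impute <- function(data, covariates,
                        time_col = "pfs_months", event_col = "progressed",
                        m = 40, maxit = 10, seed = NULL) {
  stopifnot(m >= 1)
  if (anyNA(data[[time_col]]) || anyNA(data[[event_col]]))
    stop("outcome columns must be complete; only covariates may be missing")
  covariates <- intersect(covariates, names(data))
  miss_frac <- vapply(data[covariates], function(v) mean(is.na(v)), 0)
  if (any(miss_frac == 1))
    stop("covariate(s) entirely missing: ",
         paste(covariates[miss_frac == 1], collapse = ", "))
  if (any(miss_frac > 0.5))
    warning("covariate(s) with >50% missingness: ",
            paste(covariates[miss_frac > 0.5], collapse = ", "))
  target <- covariates[miss_frac > 0]
  methods <- vapply(data[covariates], .impute_method, "")
  set_seed_if(seed)
  base <- data
  base$.event <- as.numeric(data[[event_col]])
  base$.cumhaz <- nelson_aalen_at(data[[time_col]], base$.event)
  if (length(target) == 0)
    return(structure(list(datasets = replicate(m, data, simplify = FALSE),
                          m = m, methods = methods, seed = seed),
                     class = "imputation_set"))
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    comp <- base
    for (v in target) {         # random-draw initialization
      na <- is.na(comp[[v]])
      comp[[v]][na] <- sample(comp[[v]][!na], sum(na), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in target) {
        na <- is.na(base[[v]])
        preds <- c(setdiff(covariates, v), ".event", ".cumhaz")
        comp[[v]][na] <- .impute_draw(comp, v, preds, na, methods[[v]])
      }
    }
    datasets[[k]] <- comp[names(data)]
  }
  structure(list(datasets = datasets, m = m, methods = methods, seed = seed),
            class = "imputation_set")
}

.impute_method <- function(v) {
  if (is.ordered(v)) return("polr")
  if (is.factor(v) || is.character(v) || is.logical(v)) {
    k <- length(unique(stats::na.omit(as.character(v))))
    if (k <= 2) "logistic" else "multinom"
  } else if (length(unique(stats::na.omit(v))) <= 2) "logistic" else "norm"
}

## One Gibbs-style draw for variable v given the current completed data.
## Any model failure falls back to drawing from the observed marginal.
.impute_draw <- function(comp, v, preds, na, method) {
  obs <- !na
  fallback <- function() sample(comp[[v]][obs], sum(na), replace = TRUE)
  X <- tryCatch(stats::model.matrix(
    stats::reformulate(preds), data = comp), error = function(e) NULL)
  if (is.null(X) || nrow(X) != nrow(comp)) return(fallback())
  keep <- which(apply(X[obs, , drop = FALSE], 2, function(cc) stats::var(cc) > 0))
  keep <- union(1L, keep)  # intercept
  X <- X[, keep, drop = FALSE]
  yobs <- comp[[v]][obs]
  out <- tryCatch(switch(
    method,
    norm = {
      fit <- stats::lm.fit(X[obs, , drop = FALSE], yobs)
      ok <- !is.na(fit$coefficients)
      res <- fit$residuals
      df <- max(length(yobs) - sum(ok), 1)
      sig <- sqrt(sum(res^2) / stats::rchisq(1, df))
      Xo <- X[obs, ok, drop = FALSE]
      V <- chol2inv(chol(crossprod(Xo))) * sig^2
      beta <- fit$coefficients[ok] +
        drop(t(chol(V)) %*% stats::rnorm(sum(ok)))
      drop(X[na, ok, drop = FALSE] %*% beta) + stats::rnorm(sum(na), 0, sig)
    },
    logistic = {
      yf <- factor(yobs)
      fit <- suppressWarnings(stats::glm.fit(
        X[obs, , drop = FALSE], as.numeric(yf) - 1,
        family = stats::binomial()))
      ok <- !is.na(fit$coefficients)
      # approximate posterior draw of the coefficients
      Xo <- X[obs, ok, drop = FALSE]
      W <- fit$weights
      V <- tryCatch(chol2inv(chol(crossprod(Xo * sqrt(W)))),
                    error = function(e) NULL)
      beta <- fit$coefficients[ok]
      if (!is.null(V))
        beta <- beta + drop(t(chol(V)) %*% stats::rnorm(sum(ok)))
      p <- stats::plogis(drop(X[na, ok, drop = FALSE] %*% beta))
      draw <- stats::rbinom(sum(na), 1, p)
      .cast_like(levels(yf)[draw + 1], comp[[v]])
    },
    multinom = {
      yf <- factor(yobs)
      dfit <- data.frame(.y = yf, X[obs, -1, drop = FALSE],
                         check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = dfit, trace = FALSE)
      nd <- data.frame(X[na, -1, drop = FALSE], check.names = FALSE)
      p <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(p))) p <- rbind(p)
      if (ncol(p) != nlevels(yf)) stop("prob matrix mismatch")
      picks <- apply(p, 1, function(pr) sample(levels(yf), 1, prob = pr))
      .cast_like(picks, comp[[v]])
    },
    polr = {
      yf <- droplevels(factor(yobs, ordered = TRUE))
      dfit <- data.frame(.y = yf, X[obs, -1, drop = FALSE],
                         check.names = FALSE)
      fit <- MASS::polr(.y ~ ., data = dfit)
      nd <- data.frame(X[na, -1, drop = FALSE], check.names = FALSE)
      p <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(p))) p <- rbind(p)
      picks <- apply(p, 1, function(pr) sample(colnames(p), 1, prob = pr))
      .cast_like(picks, comp[[v]])
    }), error = function(e) NULL)
  if (is.null(out) || length(out) != sum(na)) fallback() else out
}

.cast_like <- function(vals, template) {
  if (is.factor(template))
    factor(vals, levels = levels(template), ordered = is.ordered(template))
  else if (is.logical(template)) as.logical(vals)
  else if (is.numeric(template)) as.numeric(vals)
  else vals
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set>", x$m, "completed datasets\n")
  cat("  methods:", paste(names(x$methods), x$methods, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Rubin's rule for pooling across imputations
#'
#' Pooled estimate = mean of the per-dataset estimates; total variance =
#' mean within-imputation variance + (1 + 1/m) x between-imputation
#' variance, with the small-sample degrees-of-freedom adjustment
#' `df = (m - 1) (1 + ubar / ((1 + 1/m) b))^2`. With a single dataset
#' (or zero between-variance) the total variance reduces to the within
#' variance and the reference distribution is normal.
#'
#' @param estimates Per-imputation point estimates.
#' @param variances Per-imputation squared standard errors.
#' @param level Confidence level for the pooled interval.
#' @return List with `estimate`, `variance`, `se`, `df`, `ci`, `p`,
#'   `between`, `within`, `m`.
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 1) stop("rubin_pool requires at least one estimate")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- ubar + (1 + 1 / m) * b
  if (b > 0) {
    df <- (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
    tcrit <- stats::qt(1 - (1 - level) / 2, df)
    p <- 2 * stats::pt(-abs(qbar) / sqrt(total), df)
  } else {
    df <- Inf
    tcrit <- stats::qnorm(1 - (1 - level) / 2)
    p <- 2 * stats::pnorm(-abs(qbar) / sqrt(total))
  }
  list(estimate = qbar, variance = total, se = sqrt(total), df = df,
       ci = qbar + c(-1, 1) * tcrit * sqrt(total), p = p,
       between = b, within = ubar, m = m)
}
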