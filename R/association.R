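test_result <- function(method, statistic, p, estimate = NA_real_,
                        ci = c(NA_real_, NA_real_), note = NA_character_) {
  data.frame(method = method, statistic = statistic, estimate = estimate,
             ci_lower = ci[1], ci_upper = ci[2], p_raw = p,
             p_adjusted = NA_real_, note = note, stringsAsFactors = FALSE)
}

#' Spearman rank correlation with transform-based confidence interval
#'
#' The interval uses the normalizing inverse-hyperbolic-tangent (Fisher z)
#' transform with standard error `1/sqrt(n - 3)`; the p-value is the
#' asymptotic rank-correlation test.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param level Confidence level, default 0.95.
#' @return One-row `data.frame` (method, statistic, estimate, CI, p).
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_ci needs at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  z <- qnorm_2side(level)
  ci <- tanh(atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * z / sqrt(n - 3))
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  test_result("spearman", rho, p, estimate = rho, ci = ci)
}

qnorm_2side <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Kruskal-Wallis test of a metric across factor levels
#'
#' Tie-corrected H statistic against the chi-square reference with k-1
#' degrees of freedom. A sample in which all values are equal is treated as
#' perfectly null (H = 0, p = 1).
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length; at least two
#'   non-empty groups.
#' @return One-row `data.frame`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("kruskal_wallis needs at least 2 groups")
  if (length(unique(values)) == 1)
    return(test_result("kruskal-wallis", 0, 1))
  kt <- stats::kruskal.test(values, groups)
  test_result("kruskal-wallis", unname(kt$statistic), kt$p.value)
}

#' Fisher's exact test for r x c contingency tables
#'
#' 2x2 tables use the exact two-sided hypergeometric rule (sum of table
#' probabilities not exceeding the observed one). Larger tables use the
#' network/enumeration algorithm when feasible and fall back to a seeded
#' Monte-Carlo p-value (recorded in `note`) otherwise. A table with a zero
#' row or column margin is degenerate and returns p = 1.
#'
#' @param table Matrix of non-negative integer counts.
#' @param mc_B Monte-Carlo replicates for the fallback, default 1e5.
#' @param seed Seed used only if the Monte-Carlo fallback triggers.
#' @return One-row `data.frame`.
#' @export
fisher_exact_rxc <- function(table, mc_B = 1e5, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(test_result("fisher", NA_real_, 1, note = "zero margin"))
  res <- tryCatch(stats::fisher.test(table), error = function(e) NULL)
  if (is.null(res)) {
    set_seed_if(seed)
    res <- stats::fisher.test(table, simulate.p.value = TRUE, B = mc_B)
    return(test_result("fisher", NA_real_, res$p.value,
                       note = sprintf("monte-carlo B=%d", mc_B)))
  }
  test_result("fisher", NA_real_, res$p.value)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test: exact when the combined sample
#' is small and untied, otherwise the tie-corrected normal approximation.
#' This is the appropriate test for a continuous variable (such as age)
#' between two independent groups; a paired signed-rank variant is
#' available through `paired = TRUE`.
#'
#' @param a,b Numeric samples.
#' @param paired Use the paired signed-rank test instead.
#' @return One-row `data.frame`.
#' @export
wilcoxon_ranksum <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  exact <- !paired && (length(a) + length(b) <= 20) &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE))
  test_result(if (paired) "wilcoxon-signed-rank" else "wilcoxon-rank-sum",
              unname(wt$statistic), wt$p.value)
}

#' Holm step-down adjustment within one test family
#'
#' Family-wise error rate control by Holm's step-down method with the
#' cumulative-maximum monotonicity enforcement; input order is preserved.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Associations between CD163 metrics and clinicopathologic factors
#'
#' For each (metric, factor) pair: continuous metrics against categorical
#' factors use Kruskal-Wallis; dichotomized metrics against categorical
#' factors use Fisher's exact test (or its r x c extension); age against a
#' dichotomized metric uses the two-sample rank-sum test. Holm adjustment
#' is applied within one family per clinicopathologic factor (separately
#' for the continuous and the dichotomized metric sets); the family
#' partition is configurable via the returned `family` column.
#'
#' @param metrics Metric table from [compute_metrics()] (plus optional
#'   dichotomized columns named `<metric>_high`).
#' @param clinical Clinical table (merged on `patient_id`).
#' @param factors Character vector of clinical factor columns to test.
#' @param metric_cols Metric columns, default the seven standard metrics.
#' @return Tidy `data.frame` of test results with `p_adjusted` filled.
#' @export
associate_metrics <- function(metrics, clinical,
                              factors = intersect(c("hrht", "race", "grade",
                                                    "node", "size_cat", "her2",
                                                    "radiation"),
                                                  names(clinical)),
                              metric_cols = intersect(.metric_names, names(metrics))) {
  df <- merge(metrics, clinical, by = "patient_id")
  rows <- list()
  for (fac in factors) {
    fam <- paste0("continuous|", fac)
    for (mc in metric_cols) {
      tr <- tryCatch(kruskal_wallis(df[[mc]], df[[fac]]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      tr$metric <- mc; tr$factor <- fac; tr$family <- fam
      rows[[length(rows) + 1]] <- tr
    }
    dich <- paste0(metric_cols, "_high")
    dich <- dich[dich %in% names(df)]
    fam2 <- paste0("dichotomized|", fac)
    for (dc in dich) {
      tab <- table(df[[dc]], df[[fac]])
      tr <- tryCatch(fisher_exact_rxc(tab), error = function(e) NULL)
      if (is.null(tr)) next
      tr$metric <- dc; tr$factor <- fac; tr$family <- fam2
      rows[[length(rows) + 1]] <- tr
    }
  }
  if ("age" %in% names(df)) {
    dich <- paste0(metric_cols, "_high")
    dich <- dich[dich %in% names(df)]
    for (dc in dich) {
      g <- df[[dc]]
      if (length(unique(stats::na.omit(g))) < 2) next
      a <- df$age[g == levels(factor(g))[1]]
      b <- df$age[g == levels(factor(g))[2]]
      tr <- tryCatch(wilcoxon_ranksum(a, b), error = function(e) NULL)
      if (is.null(tr)) next
      tr$metric <- dc; tr$factor <- "age"; tr$family <- "dichotomized|age"
      rows[[length(rows) + 1]] <- tr
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  for (fam in unique(out$family)) {
    i <- out$family == fam
    out$p_adjusted[i] <- holm_adjust(out$p_raw[i])
  }
  rownames(out) <- NULL
  out[c("metric", "factor", "family", "method", "statistic", "estimate",
        "ci_lower", "ci_upper", "p_raw", "p_adjusted", "note")]
}
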