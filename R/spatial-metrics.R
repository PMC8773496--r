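#' Build the multitype marked point pattern of a core
#'
#' Each cell becomes one point marked `cancer`, `tam` (CD163+ TAM) or
#' `stromal-` (CD163- stromal cell); the marks partition the points.
#'
#' @param core A phenotyped [core_table] (every stromal cell labelled).
#' @return List with `x`, `y`, `marks` (factor), `window`.
#' @export
build_mmpp <- function(core) {
  cells <- core$cells
  if (anyNA(cells$tam[cells$compartment == "stromal"]))
    stop("core ", core$core_id,
         " has unlabelled stromal cells; run phenotyping first")
  marks <- ifelse(cells$compartment == "cancer", "cancer",
                  ifelse(cells$tam %in% TRUE, "tam", "stromal-"))
  list(x = cells$x, y = cells$y,
       marks = factor(marks, levels = c("cancer", "tam", "stromal-")),
       window = core$window)
}

## Squared cross-distances in row chunks to bound memory on large patterns.
.chunked_rows <- function(n, chunk = 512L) split(seq_len(n), ceiling(seq_len(n) / chunk))

## For each (ax, ay) point the distance to the nearest (bx, by) point.
cross_nn_dist <- function(ax, ay, bx, by) {
  n <- length(ax)
  if (length(bx) == 0) return(rep(Inf, n))
  out <- numeric(n)
  for (idx in .chunked_rows(n)) {
    d2 <- outer(ax[idx], bx, "-")^2 + outer(ay[idx], by, "-")^2
    out[idx] <- sqrt(d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))])
  }
  out
}

## For each (ax, ay) point the number of (bx, by) points strictly within r.
cross_count_within <- function(ax, ay, bx, by, r) {
  n <- length(ax)
  if (length(bx) == 0) return(rep(0L, n))
  out <- integer(n)
  r2 <- r^2
  for (idx in .chunked_rows(n)) {
    d2 <- outer(ax[idx], bx, "-")^2 + outer(ay[idx], by, "-")^2
    out[idx] <- as.integer(rowSums(d2 < r2))
  }
  out
}

#' Cancer-to-TAM nearest neighbor distances
#'
#' Euclidean distance from each cancer cell to its nearest CD163+ TAM.
#' No edge correction is applied: the cores are small fixed windows and the
#' metrics are defined on the observed pattern. When the core has no TAMs,
#' every cancer cell gets the sentinel `Inf` ("no neighbor"); the summary
#' step maps it to the truncation value.
#'
#' @param pattern A pattern from [build_mmpp()] (or a phenotyped
#'   [core_table], which is converted).
#' @return Numeric vector, one distance per cancer cell.
#' @export
nnd_set <- function(pattern) {
  if (inherits(pattern, "core_table")) pattern <- build_mmpp(pattern)
  ca <- pattern$marks == "cancer"
  tm <- pattern$marks == "tam"
  if (!any(ca)) stop("pattern has no cancer cells")
  cross_nn_dist(pattern$x[ca], pattern$y[ca], pattern$x[tm], pattern$y[tm])
}

#' Percentile summary of the NND distribution
#'
#' Returns the 10th, 25th and 50th percentiles of the per-cancer-cell NNDs,
#' computed by linear interpolation between order statistics. Distances are
#' first capped at `truncation` (600 um, the core diameter), so a zero-TAM
#' core — where every distance is the "no neighbor" sentinel — yields all
#' three percentiles exactly at the truncation value. Inside a valid window
#' the cap is a no-op for finite distances.
#'
#' @param distances Output of [nnd_set()].
#' @param truncation Cap in micrometres, default 600.
#' @return Named numeric vector `nnd_p10`, `nnd_p25`, `nnd_p50`.
#' @export
summarize_nnd <- function(distances, truncation = 600) {
  if (length(distances) == 0) stop("no cancer cells: empty NND set")
  d <- pmin(distances, truncation)
  q <- stats::quantile(d, probs = c(0.10, 0.25, 0.50), names = FALSE, type = 7)
  c(nnd_p10 = q[1], nnd_p25 = q[2], nnd_p50 = q[3])
}

#' Mean count of TAMs within a radius of each cancer cell
#'
#' Average over cancer cells of the number of CD163+ TAMs at distance
#' strictly less than `radius`. With the 12 um radius this is the mean
#' number of directly adjacent (juxtacrine-range) TAMs per cancer cell;
#' with 250 um, the mean number of communicating (paracrine-range) TAMs.
#'
#' @param pattern A pattern from [build_mmpp()] or a phenotyped core.
#' @param radius Radius in micrometres (> 0).
#' @return Scalar mean count (0 for a zero-TAM core).
#' @export
mean_count_within <- function(pattern, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a positive number")
  if (inherits(pattern, "core_table")) pattern <- build_mmpp(pattern)
  ca <- pattern$marks == "cancer"
  tm <- pattern$marks == "tam"
  if (!any(ca)) stop("pattern has no cancer cells")
  mean(cross_count_within(pattern$x[ca], pattern$y[ca],
                          pattern$x[tm], pattern$y[tm], radius))
}

#' The seven per-core CD163+ TAM metrics
#'
#' Computes, for one phenotyped core: the TAM count within the sampled core
#' area, the TAM proportion among stromal cells, the 10th/25th/50th NND
#' percentiles, and the mean adjacent (<12 um) and communicating (<250 um)
#' TAM counts per cancer cell.
#'
#' @param core A phenotyped [core_table].
#' @param adjacent_um,communicating_um Disc radii in micrometres.
#' @param truncation_um NND truncation, default the 600 um core diameter.
#' @return One-row `data.frame` with columns `core_id`, `patient_id`,
#'   `tam_count`, `tam_proportion`, `nnd_p10`, `nnd_p25`, `nnd_p50`,
#'   `adj_mean`, `comm_mean`.
#' @export
compute_metric_suite <- function(core, adjacent_um = 12, communicating_um = 250,
                                 truncation_um = 600) {
  cells <- core$cells
  if (anyNA(cells$tam[cells$compartment == "stromal"]))
    stop("core ", core$core_id,
         " has unlabelled stromal cells; run phenotyping first")
  ca <- cells$compartment == "cancer"
  tm <- !ca & cells$tam %in% TRUE
  if (!any(ca)) stop("core ", core$core_id, " has no cancer cells")
  if (sum(!ca) == 0)
    warning("core ", core$core_id, " has no stromal cells; tam_proportion = 0")
  m <- .metric_kernel(cells$x[ca], cells$y[ca], cells$x[tm], cells$y[tm],
                      n_stromal = sum(!ca), adjacent_um = adjacent_um,
                      communicating_um = communicating_um,
                      truncation_um = truncation_um)
  out <- data.frame(core_id = core$core_id, patient_id = core$patient_id,
                    stringsAsFactors = FALSE)
  out[names(m)] <- as.list(m)
  out
}

## Shared computation of the seven metrics from raw coordinate vectors.
.metric_kernel <- function(cx, cy, tx, ty, n_stromal, adjacent_um = 12,
                           communicating_um = 250, truncation_um = 600) {
  nt <- length(tx)
  nnd <- summarize_nnd(cross_nn_dist(cx, cy, tx, ty), truncation_um)
  c(tam_count = nt,
    tam_proportion = if (n_stromal == 0) 0 else nt / n_stromal,
    nnd,
    adj_mean = mean(cross_count_within(cx, cy, tx, ty, adjacent_um)),
    comm_mean = mean(cross_count_within(cx, cy, tx, ty, communicating_um)))
}

#' Metric table for a list of cores
#'
#' @param cores List of phenotyped [core_table] objects.
#' @param ... Passed to [compute_metric_suite()].
#' @return `data.frame` with one row per core.
#' @export
compute_metrics <- function(cores, ...) {
  out <- do.call(rbind, lapply(cores, compute_metric_suite, ...))
  rownames(out) <- NULL
  out
}

.metric_names <- c("tam_count", "tam_proportion", "nnd_p10", "nnd_p25",
                   "nnd_p50", "adj_mean", "comm_mean")
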