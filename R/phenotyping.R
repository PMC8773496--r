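#' Specification of a non-parametric upper tolerance limit
#'
#' A one-sided non-parametric upper tolerance limit (UTL) with content `p`
#' and confidence `gamma` is an order statistic of a background sample
#' chosen so that, with probability at least `gamma`, it exceeds the
#' population `p`-quantile of the background distribution. The defaults
#' (95% content, 99% confidence) give the cutoff used to call a stromal
#' cell CD163-positive relative to the cancer-cell background signal of
#' its own core.
#'
#' @param content Content proportion `p` in (0, 1); default 0.95.
#' @param confidence Confidence `gamma` in (0, 1); default 0.99.
#' @param mode `"exact"` uses the exact binomial order-statistic rule;
#'   `"table"` interpolates a user-supplied rank table on `n`.
#' @param rank_table For `mode = "table"`: `data.frame` with columns `n`
#'   and `rank` (1-based ascending order-statistic index).
#' @return An object of class `utl_spec`.
#' @export
utl_spec <- function(content = 0.95, confidence = 0.99,
                     mode = c("exact", "table"), rank_table = NULL) {
  stopifnot(content > 0, content < 1, confidence > 0, confidence < 1)
  mode <- match.arg(mode)
  if (mode == "table") {
    if (is.null(rank_table) || !all(c("n", "rank") %in% names(rank_table)))
      stop("mode = 'table' requires a rank_table with columns n and rank")
    rank_table <- rank_table[order(rank_table$n), ]
  }
  structure(list(content = content, confidence = confidence, mode = mode,
                 rank_table = rank_table), class = "utl_spec")
}

#' Order-statistic rank of the non-parametric UTL
#'
#' For a background sample of size `n`, returns the smallest 1-based
#' ascending rank `r` such that the r-th order statistic exceeds the
#' population `content`-quantile with probability at least `confidence`:
#' the number of observations below that quantile is Binomial(n, p), so the
#' requirement is `pbinom(r - 1, n, p) >= gamma`. When even the sample
#' maximum (`r = n`) cannot reach the nominal confidence, the maximum is
#' used and flagged `degenerate`, with achieved confidence `1 - p^n`; for
#' p = 0.95 and gamma = 0.99 the nominal level first becomes attainable at
#' n = 90.
#'
#' @param n Background sample size (`>= 1`).
#' @param spec A [utl_spec()].
#' @return List with `rank`, `achieved_confidence`, `degenerate`, `n`.
#' @examples
#' utl_rank(100)  # rank 100: only the sample maximum reaches 99% confidence
#' utl_rank(10)   # degenerate: achieved confidence 1 - 0.95^10 = 0.401
#' @export
utl_rank <- function(n, spec = utl_spec()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer sample size")
  n <- as.integer(n)
  p <- spec$content
  gamma <- spec$confidence
  if (spec$mode == "table") {
    tab <- spec$rank_table
    if (n < min(tab$n) || n > max(tab$n))
      stop("n = ", n, " outside the supplied rank table range")
    r <- round(stats::approx(tab$n, tab$rank, xout = n, ties = "ordered")$y)
    r <- max(1L, min(n, as.integer(r)))
    return(list(rank = r, achieved_confidence = stats::pbinom(r - 1, n, p),
                degenerate = FALSE, n = n))
  }
  # smallest r with P(Binom(n, p) <= r - 1) >= gamma
  r <- stats::qbinom(gamma, n, p) + 1L
  if (r > n) {
    list(rank = n, achieved_confidence = stats::pbinom(n - 1, n, p),
         degenerate = TRUE, n = n)
  } else {
    list(rank = as.integer(r), achieved_confidence = stats::pbinom(r - 1, n, p),
         degenerate = FALSE, n = n)
  }
}

#' Background UTL of a core's cancer-cell CD163 signal
#'
#' The CD163 signal measured in cancer cells is treated as background noise
#' (cancer cells do not express CD163); the UTL of that background sample
#' is the per-core positivity threshold for stromal cells.
#'
#' @param core A [core_table] with at least 10 cancer cells.
#' @param spec A [utl_spec()].
#' @return List with `utl_value` (intensity units), `rank`,
#'   `achieved_confidence`, `degenerate`, `n`.
#' @export
background_utl <- function(core, spec = utl_spec()) {
  bg <- core$cells$cd163[core$cells$compartment == "cancer"]
  if (length(bg) < 10)
    stop("core ", core$core_id, " has ", length(bg),
         " cancer cells; at least 10 are required for the background UTL")
  res <- utl_rank(length(bg), spec)
  res$utl_value <- sort(bg)[res$rank]
  res
}

#' Label CD163+ TAMs in a core
#'
#' A stromal cell is labelled a CD163+ TAM iff its CD163 intensity is
#' strictly above the core's background UTL. Cancer cells are never
#' labelled TAM. A core in which no stromal cell exceeds the UTL is a valid
#' zero-TAM core and is retained (downstream metrics apply the zero-TAM
#' conventions).
#'
#' @param core A [core_table].
#' @param utl Result of [background_utl()] for the same core.
#' @return The core with its `tam` column filled.
#' @export
classify_tams <- function(core, utl) {
  core$cells$tam <- core$cells$compartment == "stromal" &
    core$cells$cd163 > utl$utl_value
  core
}

#' Phenotype a list of cores
#'
#' Runs [background_utl()] and [classify_tams()] on each core.
#'
#' @param cores List of [core_table] objects (post-QC).
#' @param spec A [utl_spec()].
#' @return List with `cores` (labelled) and `summary` (one row per core:
#'   background size, UTL rank and value, degeneracy flag, TAM count).
#' @export
phenotype_cores <- function(cores, spec = utl_spec()) {
  out <- lapply(cores, function(core) {
    utl <- background_utl(core, spec)
    core <- classify_tams(core, utl)
    attr(core, "utl") <- utl
    core
  })
  summary <- do.call(rbind, lapply(out, function(core) {
    utl <- attr(core, "utl")
    data.frame(core_id = core$core_id, patient_id = core$patient_id,
               n_cancer = utl$n, utl_rank = utl$rank,
               utl_value = utl$utl_value,
               achieved_confidence = utl$achieved_confidence,
               degenerate = utl$degenerate, n_tam = n_tam(core),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(cores = out, summary = summary)
}
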