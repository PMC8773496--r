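`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sampled area of a circular tissue core
#'
#' Area of a circular tissue-microarray core in mm^2. The default 600 um
#' diameter corresponds to the standard 0.6 mm TMA punch and gives a sampled
#' area of 0.2827 mm^2 (0.28 mm^2 to the printed precision used when
#' reporting TAM counts "per core").
#'
#' @param diameter_um Core diameter in micrometres.
#' @return Area in mm^2.
#' @examples
#' core_area_mm2()        # 0.2827433
#' round(core_area_mm2(), 2)
#' @export
core_area_mm2 <- function(diameter_um = 600) {
  stopifnot(is.numeric(diameter_um), diameter_um > 0)
  pi * (diameter_um / 2000)^2
}

## Derive independent child seeds from one user seed. Values stay below
## 2^31 - 1 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

## Nelson-Aalen cumulative hazard evaluated at each subject's own time.
## Shared by the log-rank scores (cutpoint search) and the imputation models.
nelson_aalen_at <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- as.numeric(event[ord])
  # at-risk count just before each sorted time (ties share the risk set)
  uniq <- !duplicated(t_s)
  ut <- t_s[uniq]
  n_risk <- n - (which(uniq) - 1L)
  d_u <- as.vector(rowsum(d_s, group = match(t_s, ut)))
  haz <- d_u / n_risk
  cumhaz_u <- cumsum(haz)
  out <- numeric(n)
  out[ord] <- cumhaz_u[match(t_s, ut)]
  out
}
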