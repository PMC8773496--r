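#' Specification of a synthetic tissue core
#'
#' Defines the generative model for one simulated 600 um tissue core:
#' cancer cells from a parent-offspring cluster process (tumor nests),
#' CD163- stromal cells uniform in the window, true TAMs placed uniformly,
#' attracted to cancer cells (Gaussian displacement from a random cancer
#' cell) or repulsed from them, and lognormal CD163 intensities — a common
#' background for cancer and CD163- stromal cells, and a shifted
#' distribution for true TAMs.
#'
#' @param n_cancer,n_stromal Cell counts (stromal includes true TAMs).
#' @param tam_fraction Fraction of stromal cells that are true TAMs.
#' @param proximity_mode `"attracted"`, `"random"` or `"repulsed"`.
#' @param attraction_sd Gaussian displacement sd (um) for attracted TAMs.
#' @param bg_meanlog,bg_sdlog Background lognormal intensity parameters.
#' @param tam_shift Additive meanlog shift (> 0) of true-TAM intensities;
#'   the default 2.0 is four background log-sds, giving well-separated but
#'   overlapping intensity distributions.
#' @param diameter_um Window diameter (600 um core).
#' @param n_parents,offspring_sd Cluster-process parameters for the
#'   cancer-cell nests.
#' @return Object of class `core_gen_spec`.
#' @export
core_gen_spec <- function(n_cancer = 150, n_stromal = 300,
                          tam_fraction = 0.1,
                          proximity_mode = c("attracted", "random", "repulsed"),
                          attraction_sd = 30, bg_meanlog = 0, bg_sdlog = 0.5,
                          tam_shift = 2, diameter_um = 600, n_parents = 5,
                          offspring_sd = 40) {
  proximity_mode <- match.arg(proximity_mode)
  stopifnot(n_cancer >= 0, n_stromal >= 0,
            tam_fraction >= 0, tam_fraction <= 1,
            tam_shift > 0, diameter_um > 0, attraction_sd > 0)
  structure(as.list(environment()), class = "core_gen_spec")
}

runif_disc <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

## Gaussian displacement from anchor points, rejection-sampled into the
## disc of radius R. Errors out if acceptance is hopeless.
.displace_into_disc <- function(ax, ay, sd, R, max_tries = 1e5) {
  n <- length(ax)
  out <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0) {
    tries <- tries + length(todo)
    if (tries > max_tries)
      stop("rejection sampling into the window failed; ",
           "use a smaller attraction_sd / offspring_sd")
    px <- ax[todo] + stats::rnorm(length(todo), 0, sd)
    py <- ay[todo] + stats::rnorm(length(todo), 0, sd)
    ok <- px^2 + py^2 <= R^2
    out[todo[ok], ] <- cbind(px[ok], py[ok])
    todo <- todo[!ok]
  }
  out
}

#' Generate one synthetic core with hidden ground-truth TAM labels
#'
#' The returned [core_table] looks exactly like an upstream segmentation
#' export (coordinates, compartment, CD163 intensity); the true TAM labels
#' are carried only as the attribute `"truth_tam"` and are never written
#' to disk by [write_cell_table()].
#'
#' @param spec A [core_gen_spec()].
#' @param seed Optional seed (the core is deterministic given the seed).
#' @param core_id,patient_id Identifiers for the generated core.
#' @return A `core_table` with attribute `truth_tam` (logical per cell).
#' @export
generate_core <- function(spec = core_gen_spec(), seed = NULL,
                          core_id = "core1", patient_id = "pt1") {
  set_seed_if(seed)
  R <- spec$diameter_um / 2
  parents <- runif_disc(max(spec$n_parents, 1), R * 0.8)
  pid <- sample.int(nrow(parents), spec$n_cancer, replace = TRUE)
  canc <- .displace_into_disc(parents[pid, 1], parents[pid, 2],
                              spec$offspring_sd, R)
  n_tam <- round(spec$tam_fraction * spec$n_stromal)
  n_neg <- spec$n_stromal - n_tam
  neg <- runif_disc(n_neg, R)
  tam <- if (n_tam == 0) matrix(numeric(0), 0, 2) else switch(
    spec$proximity_mode,
    random = runif_disc(n_tam, R),
    attracted = {
      if (spec$n_cancer == 0) runif_disc(n_tam, R) else {
        anchor <- sample.int(spec$n_cancer, n_tam, replace = TRUE)
        .displace_into_disc(canc[anchor, 1], canc[anchor, 2],
                            spec$attraction_sd, R)
      }
    },
    repulsed = {
      if (spec$n_cancer == 0) runif_disc(n_tam, R) else {
        ref <- runif_disc(500, R)
        med <- stats::median(cross_nn_dist(ref[, 1], ref[, 2],
                                           canc[, 1], canc[, 2]))
        got <- matrix(NA_real_, n_tam, 2)
        filled <- 0L; tries <- 0L
        while (filled < n_tam) {
          tries <- tries + 1L
          if (tries > 1000)
            stop("rejection sampling for repulsed TAMs failed")
          cand <- runif_disc(4 * n_tam, R)
          d <- cross_nn_dist(cand[, 1], cand[, 2], canc[, 1], canc[, 2])
          ok <- which(d > med)
          take <- utils::head(ok, n_tam - filled)
          if (length(take)) {
            got[(filled + 1):(filled + length(take)), ] <- cand[take, ]
            filled <- filled + length(take)
          }
        }
        got
      }
    })
  x <- c(canc[, 1], tam[, 1], neg[, 1])
  y <- c(canc[, 2], tam[, 2], neg[, 2])
  compartment <- c(rep("cancer", spec$n_cancer), rep("stromal", spec$n_stromal))
  truth <- c(rep(FALSE, spec$n_cancer), rep(TRUE, n_tam), rep(FALSE, n_neg))
  cd163 <- stats::rlnorm(length(x),
                         meanlog = spec$bg_meanlog + spec$tam_shift * truth,
                         sdlog = spec$bg_sdlog)
  cells <- list(cell_id = as.character(seq_along(x)), x = x, y = y,
                compartment = compartment, cd163 = cd163,
                tam = rep(NA, length(x)))
  class(cells) <- "data.frame"
  attr(cells, "row.names") <- .set_row_names(length(x))
  core <- core_table(core_id, patient_id, cells,
                     window = list(cx = 0, cy = 0,
                                   diameter = spec$diameter_um))
  attr(core, "truth_tam") <- truth
  core
}

#' Specification of a synthetic patient cohort
#'
#' Ground-truth generative model for a cohort with a known threshold
#' effect: per patient a core is generated (TAM fraction drawn uniformly
#' from `tam_fraction_range` to create between-patient spread), the
#' designated metric is computed from the true TAM labels, and the
#' progression hazard is `h0 * exp(beta * 1[metric > cutpoint] + x'eta)`
#' with an exponential baseline; censoring is uniform and the baseline
#' rate is calibrated in closed form so the expected event fraction
#' matches `event_fraction`. Covariate distributions mimic a chemotherapy-
#' treated breast-cancer cohort; missingness is injected MAR through a
#' logistic model on the (always-observed) age.
#'
#' @param n_patients Cohort size.
#' @param core A [core_gen_spec()] template.
#' @param tam_fraction_range Per-patient uniform range of the true TAM
#'   fraction.
#' @param metric Designated metric (`"comm_mean"` by default).
#' @param cutpoint True threshold on the designated metric; `NULL` uses
#'   the realized cohort median (returned in the ground truth).
#' @param beta True log hazard ratio of the threshold effect.
#' @param covariate_effects Named log hazard ratios for the non-reference
#'   covariate levels.
#' @param event_fraction Target expected event fraction in (0, 1).
#' @param censor_range_months Uniform censoring support (months).
#' @param missing_rates Named marginal missingness rates per covariate.
#' @return Object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_patients = 400, core = core_gen_spec(),
                            tam_fraction_range = c(0.02, 0.35),
                            metric = "comm_mean", cutpoint = NULL,
                            beta = log(3),
                            covariate_effects = c("grade2" = 0.3,
                                                  "grade3" = 0.6,
                                                  "nodepositive" = 0.5,
                                                  "size_cat2-5cm" = 0.3,
                                                  "size_cat>5cm" = 0.6,
                                                  "hrhtHR+ non-compliant" = 0.5,
                                                  "hrhtHR-" = 0.4),
                            event_fraction = 0.6,
                            censor_range_months = c(6, 120),
                            missing_rates = c(grade = 0.03, node = 0.03,
                                              size_cat = 0.03, her2 = 0.03,
                                              race = 0.02, hrht = 0.15)) {
  stopifnot(n_patients >= 1, is.finite(beta),
            event_fraction > 0, event_fraction < 1,
            metric %in% .metric_names)
  structure(as.list(environment()), class = "cohort_gen_spec")
}

## P(T < C) for T ~ Exp(rate) and C ~ U(a, b), in closed form.
.event_prob <- function(rate, a, b) {
   1 - (exp(-rate * a) - exp(-rate * b)) / (rate * (b - a))
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [cohort_gen_spec()].
#' @param seed Seed; the cohort is fully reproducible from it.
#' @param keep_cores Keep the generated [core_table] objects (set `FALSE`
#'   to save memory in metric-level simulations).
#' @return List with `clinical` (per-patient covariates, outcome and the
#'   seven true-label metrics), `cores` (named by patient), and `truth`
#'   (designated metric name, true cutpoint, `beta`, baseline rate,
#'   per-patient true TAM counts and high/low group).
#' @export
generate_cohort <- function(spec = cohort_gen_spec(), seed = NULL,
                            keep_cores = TRUE) {
  set_seed_if(seed)
  n <- spec$n_patients
  pids <- sprintf("pt%03d", seq_len(n))

  cores <- vector("list", n)
  mvals <- matrix(NA_real_, n, length(.metric_names),
                  dimnames = list(NULL, .metric_names))
  truth_tam_count <- integer(n)
  for (i in seq_len(n)) {
    cs <- spec$core
    cs$tam_fraction <- stats::runif(1, spec$tam_fraction_range[1],
                                    spec$tam_fraction_range[2])
    core <- generate_core(cs, seed = NULL, core_id = paste0("core_", pids[i]),
                          patient_id = pids[i])
    truth <- attr(core, "truth_tam")
    truth_tam_count[i] <- sum(truth)
    cells <- core$cells
    ca <- cells$compartment == "cancer"
    tm <- truth & !ca
    mvals[i, ] <- .metric_kernel(cells$x[ca], cells$y[ca],
                                 cells$x[tm], cells$y[tm],
                                 n_stromal = sum(!ca))
    if (keep_cores) cores[[i]] <- core
  }
  met <- as.data.frame(mvals)

  ## covariates
  clin <- data.frame(
    patient_id = pids,
    age = round(stats::rnorm(n, 56, 11), 1),
    race = factor(sample(c("white", "non-white"), n, TRUE, c(0.77, 0.23)),
                  levels = c("white", "non-white")),
    grade = factor(sample(c("1", "2", "3"), n, TRUE, c(0.27, 0.40, 0.33)),
                   levels = c("1", "2", "3")),
    node = factor(sample(c("negative", "positive"), n, TRUE, c(0.51, 0.49)),
                  levels = c("negative", "positive")),
    size_cat = factor(sample(c("<2cm", "2-5cm", ">5cm"), n, TRUE,
                             c(0.48, 0.39, 0.13)),
                      levels = c("<2cm", "2-5cm", ">5cm")),
    her2 = factor(sample(c("negative", "positive"), n, TRUE, c(0.87, 0.13)),
                  levels = c("negative", "positive")),
    radiation = stats::rbinom(n, 1, 0.58),
    hrht = factor(sample(c("HR+ compliant", "HR+ non-compliant", "HR-"),
                         n, TRUE, c(0.55, 0.24, 0.21)),
                  levels = c("HR+ compliant", "HR+ non-compliant", "HR-")),
    stringsAsFactors = FALSE)

  ## linear predictor: threshold effect + covariate effects
  x <- met[[spec$metric]]
  cut_true <- spec$cutpoint %||% stats::median(x)
  high <- x > cut_true
  eff <- spec$covariate_effects
  X <- stats::model.matrix(~ grade + node + size_cat + hrht, clin)[, -1]
  eta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  eta[intersect(names(eff), names(eta))] <-
    eff[intersect(names(eff), names(eta))]
  lp <- spec$beta * high + drop(X %*% eta)

  a <- spec$censor_range_months[1]; b <- spec$censor_range_months[2]
  h0 <- stats::uniroot(function(h)
    mean(.event_prob(h * exp(lp), a, b)) - spec$event_fraction,
    interval = c(1e-6, 10), tol = 1e-8)$root
  lat <- stats::rexp(n, rate = h0 * exp(lp))
  cen <- stats::runif(n, a, b)
  clin$pfs_months <- round(pmin(lat, cen), 3)
  clin$progressed <- as.integer(lat <= cen)
  ev_frac <- mean(clin$progressed)
  if (ev_frac < 0.05 || ev_frac > 0.95)
    warning("realized event fraction ", round(ev_frac, 3),
            " is outside (0.05, 0.95)")

  ## MAR missingness driven by (observed) age
  zage <- as.numeric(scale(clin$age))
  for (v in names(spec$missing_rates)) {
    rho <- spec$missing_rates[[v]]
    if (rho <= 0 || is.null(clin[[v]])) next
    p <- stats::plogis(stats::qlogis(rho) + 0.5 * zage)
    clin[[v]][stats::runif(n) < p] <- NA
  }

  clinical <- cbind(clin, met[.metric_names])
  names(cores) <- pids
  list(clinical = clinical,
       cores = if (keep_cores) cores else NULL,
       truth = list(metric = spec$metric, cutpoint = cut_true,
                    beta = spec$beta, baseline_rate = h0,
                    high = high, tam_count = truth_tam_count,
                    event_fraction = ev_frac))
}

#' Write a synthetic cohort to pipeline input files
#'
#' Writes `cells.csv` (all cores, canonical columns only — no ground
#' truth), `clinical.csv` (covariates and outcome only), and
#' `ground_truth.json` (kept separate so the pipeline inputs carry no
#' leakage).
#'
#' @param cohort Result of [generate_cohort()] (with cores kept).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  if (is.null(cohort$cores)) stop("cohort was generated with keep_cores = FALSE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- file.path(dir, "cells.csv")
  clinical <- file.path(dir, "clinical.csv")
  truth <- file.path(dir, "ground_truth.json")
  write_cell_table(cohort$cores, cells)
  clin <- cohort$clinical
  clin$hr_status <- ifelse(is.na(clin$hrht), NA,
                           ifelse(clin$hrht == "HR-", "HR-", "HR+"))
  clin$hormone_compliance <- ifelse(is.na(clin$hrht) | clin$hrht == "HR-", NA,
                                    ifelse(clin$hrht == "HR+ non-compliant",
                                           "non-compliant", "compliant"))
  keep <- c("patient_id", "pfs_months", "progressed", "age", "race", "grade",
            "node", "size_cat", "her2", "radiation", "hr_status",
            "hormone_compliance")
  utils::write.csv(clin[keep], clinical, row.names = FALSE, quote = FALSE,
                   na = "")
  jsonlite::write_json(cohort$truth[c("metric", "cutpoint", "beta",
                                      "baseline_rate", "event_fraction")],
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(cells = cells, clinical = clinical, truth = truth))
}
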