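#' Run the full spatial-TAM survival pipeline
#'
#' Executes, in the fixed order required by the duplicate-core rule:
#' read cell + clinical tables -> quality-control filter -> per-core
#' background-UTL phenotyping -> duplicate-core resolution -> the seven
#' spatial metrics -> metric/clinical association tests -> per-metric
#' bootstrap cutpoints and optimism-corrected Cox models (univariate and
#' multivariable) -> the combined 3-category marker model. All randomness
#' is governed by `config$seed`; rerunning with the same config and seed
#' reproduces every number.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `cells`, `clinical` (paths); optional `out_dir`; `seed`;
#'   `min_cancer` (10); `utl_content` (0.95), `utl_confidence` (0.99);
#'   `adjacent_um` (12), `communicating_um` (250), `truncation_um` (600);
#'   `markers` (default all seven metrics); `model` ("parsimonious":
#'   grade + hrht + node + size_cat; "full" adds age, race, radiation);
#'   `B_cutpoint` (1000), `B_optimism` (500), `m` (40);
#'   `combined` (TRUE: fit the combined comm_mean/nnd_p50 marker).
#' @return Invisibly, a result bundle: `metrics`, `exclusions`,
#'   `phenotype_summary`, `associations`, `cutpoints` (threshold table),
#'   `fits` (per-marker `otcox` objects), `marker_table` (bias-adjusted
#'   per-marker hazard ratios), `combined_fit`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  get <- function(key, default = NULL) config[[key]] %||% default
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  for (key in c("cells", "clinical"))
    if (is.null(config[[key]]))
      stop("config error: missing required entry '", key, "'")
  seed <- get("seed", 1L)
  seeds <- derive_seeds(seed, 64)

  cores <- stage("read_cells", read_cell_table(get("cells")))
  clinical <- stage("read_clinical", read_clinical_table(get("clinical")))
  qc <- stage("qc_filter", qc_filter(cores, min_cancer = get("min_cancer", 10)))
  spec <- utl_spec(content = get("utl_content", 0.95),
                   confidence = get("utl_confidence", 0.99))
  ph <- stage("phenotype", phenotype_cores(qc$kept, spec))
  dd <- stage("dedup", dedup_cores(ph$cores))
  metrics <- stage("metrics", compute_metrics(
    dd$kept, adjacent_um = get("adjacent_um", 12),
    communicating_um = get("communicating_um", 250),
    truncation_um = get("truncation_um", 600)))

  df <- stage("merge", {
    out <- merge(metrics, clinical, by = "patient_id")
    if (nrow(out) == 0) stop("no patients shared between cell and clinical tables")
    out
  })

  markers <- get("markers", .metric_names)
  model <- get("model", "parsimonious")
  covars <- if (identical(model, "full"))
    c("grade", "hrht", "node", "size_cat", "age", "race", "radiation")
  else c("grade", "hrht", "node", "size_cat")
  covars <- intersect(covars, names(df))
  B_cut <- get("B_cutpoint", 1000)
  B_opt <- get("B_optimism", 500)
  m <- get("m", 40)

  fits <- list()
  rows <- list()
  for (i in seq_along(markers)) {
    mk <- markers[i]
    f <- stats::reformulate(covars, response = quote(survival::Surv(pfs_months, progressed)))
    environment(f) <- environment()
    fit <- stage(paste0("otcox_", mk),
                 otcox(f, df, marker = mk, B_cutpoint = B_cut,
                       B_optimism = B_opt, m = m, seed = seeds[[i]]))
    fits[[mk]] <- fit
    ti <- grepl("vs", fit$table$term)
    cr <- fit$cutpoints[[mk]]
    rows[[mk]] <- data.frame(
      metric = mk, threshold = cr$cutpoint,
      threshold_ci90_lower = cr$ci90[1], threshold_ci90_upper = cr$ci90[2],
      contrast = fit$table$term[ti][1],
      hr = fit$table$hr[ti][1],
      ci_lower = fit$table$ci_lower[ti][1],
      ci_upper = fit$table$ci_upper[ti][1],
      p = fit$table$p[ti][1], stringsAsFactors = FALSE)
    df[[paste0(mk, "_high")]] <- .marker_group(df, mk, cr$cutpoint,
                                               fit$direction)
  }
  marker_table <- do.call(rbind, rows)
  marker_table$p_adjusted <- holm_adjust(marker_table$p)
  rownames(marker_table) <- NULL

  assoc <- stage("associations", associate_metrics(
    df[c("patient_id", intersect(.metric_names, names(df)),
         paste0(markers, "_high"))],
    clinical))

  combined_fit <- NULL
  if (isTRUE(get("combined", TRUE)) &&
      all(c("comm_mean", "nnd_p50") %in% names(df))) {
    f <- stats::reformulate(covars, response = quote(survival::Surv(pfs_months, progressed)))
    environment(f) <- environment()
    combined_fit <- stage("otcox_combined",
                          otcox(f, df, marker = c("comm_mean", "nnd_p50"),
                                B_cutpoint = B_cut, B_optimism = B_opt,
                                m = m, seed = seeds[[length(markers) + 1]]))
  }

  manifest <- list(
    seed = seed, n_cores_read = length(cores),
    n_excluded_qc = nrow(qc$excluded), n_dropped_duplicates = nrow(dd$dropped),
    n_patients = nrow(df), n_events = sum(df$progressed),
    utl = list(content = spec$content, confidence = spec$confidence),
    radii = list(adjacent_um = get("adjacent_um", 12),
                 communicating_um = get("communicating_um", 250),
                 truncation_um = get("truncation_um", 600)),
    min_cancer = get("min_cancer", 10),
    B_cutpoint = B_cut, B_optimism = B_opt, m = m, model = model,
    markers = markers)

  bundle <- list(metrics = metrics, exclusions = qc$excluded,
                 dropped_duplicates = dd$dropped,
                 phenotype_summary = ph$summary, associations = assoc,
                 marker_table = marker_table, fits = fits,
                 combined_fit = combined_fit, manifest = manifest)

  out_dir <- get("out_dir")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(marker_table, file.path(out_dir, "marker_table.csv"),
                     row.names = FALSE)
    if (!is.null(assoc))
      utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
    for (mk in names(fits))
      utils::write.csv(fits[[mk]]$table,
                       file.path(out_dir, paste0("cox_", mk, ".csv")),
                       row.names = FALSE)
    if (!is.null(combined_fit))
      utils::write.csv(combined_fit$table,
                       file.path(out_dir, "cox_combined.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
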