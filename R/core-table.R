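#' Per-core cell table
#'
#' A `core_table` holds one tissue core's segmented cells: centroid
#' coordinates in micrometres, the compartment call from upstream
#' segmentation (`"cancer"` or `"stromal"`), the CD163 mean intensity in
#' arbitrary units, and (after phenotyping) a logical TAM label per cell.
#' The observation window is a circle, by default 600 um in diameter (the
#' TMA core size), centred at the centroid bounding-box centre when no
#' centre is supplied.
#'
#' @param core_id,patient_id Identifiers (coerced to character).
#' @param cells `data.frame` with columns `cell_id`, `x`, `y`,
#'   `compartment`, `cd163` and optionally `tam`.
#' @param window Optional list with elements `cx`, `cy`, `diameter` (um).
#' @param diameter_um Window diameter used when `window` is `NULL`.
#' @return An object of class `core_table`.
#' @export
core_table <- function(core_id, patient_id, cells, window = NULL,
                       diameter_um = 600) {
  stopifnot(is.data.frame(cells))
  req <- c("x", "y", "compartment", "cd163")
  miss <- setdiff(req, names(cells))
  if (length(miss) > 0)
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(cells$cell_id)) cells$cell_id <- as.character(seq_len(nrow(cells)))
  if (is.null(cells$tam)) cells$tam <- rep(NA, nrow(cells))
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("non-finite cell coordinates in core ", core_id)
  if (!all(cells$compartment %in% c("cancer", "stromal")))
    stop("compartment must be 'cancer' or 'stromal' (core ", core_id, ")")
  if (any(cells$cd163 < 0, na.rm = TRUE) || anyNA(cells$cd163))
    stop("cd163 intensities must be non-negative and non-missing (core ",
         core_id, ")")
  if (is.null(window)) {
    cx <- if (nrow(cells)) mean(range(cells$x)) else 0
    cy <- if (nrow(cells)) mean(range(cells$y)) else 0
    window <- list(cx = cx, cy = cy, diameter = diameter_um)
  }
  if (!is.numeric(window$diameter) || window$diameter <= 0)
    stop("window diameter must be positive")
  r2 <- (window$diameter / 2)^2
  d2 <- (cells$x - window$cx)^2 + (cells$y - window$cy)^2
  if (any(d2 > r2 * (1 + 1e-9)))
    stop("core ", core_id, ": ", sum(d2 > r2), " cell(s) fall outside the ",
         window$diameter, " um circular window; supply a larger window")
  structure(
    list(core_id = as.character(core_id),
         patient_id = as.character(patient_id),
         cells = cells[c("cell_id", "x", "y", "compartment", "cd163", "tam")],
         window = window),
    class = "core_table")
}

#' @export
print.core_table <- function(x, ...) {
  nc <- sum(x$cells$compartment == "cancer")
  ns <- sum(x$cells$compartment == "stromal")
  nt <- sum(x$cells$tam %in% TRUE)
  cat("<core_table> core", x$core_id, "patient", x$patient_id, "\n")
  cat("  cells:", nrow(x$cells), "(", nc, "cancer /", ns, "stromal,",
      if (all(is.na(x$cells$tam))) "unphenotyped" else paste(nt, "CD163+ TAM"),
      ")\n")
  cat("  window: circle d =", x$window$diameter, "um\n")
  invisible(x)
}

n_cancer <- function(core) sum(core$cells$compartment == "cancer")
n_stromal <- function(core) sum(core$cells$compartment == "stromal")
n_tam <- function(core) sum(core$cells$tam %in% TRUE)

.default_cell_cols <- c(core_id = "core_id", patient_id = "patient_id",
                        x = "x_um", y = "y_um", compartment = "compartment",
                        cd163 = "cd163_intensity", cell_id = "cell_id")

#' Read a delimited cell table into per-core tables
#'
#' Reads a delimited text file with one row per segmented cell and splits it
#' into one [core_table] per distinct core identifier. Expected columns
#' (renameable through `column_map`): `core_id`, `patient_id`, `x_um`,
#' `y_um`, `compartment`, `cd163_intensity` and optionally `cell_id`.
#' Coordinates are taken as micrometres.
#'
#' @param path Path to a CSV (`sep = ","`) or TSV file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`core_id`, `x`, `y`, ...) to the file's column names.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @param diameter_um Window diameter passed to [core_table()].
#' @return A named list of `core_table` objects.
#' @export
read_cell_table <- function(path, column_map = NULL, sep = NULL,
                            diameter_um = 600) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cols <- .default_cell_cols
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  for (canon in c("core_id", "patient_id", "x", "y", "compartment", "cd163")) {
    if (!cols[[canon]] %in% names(raw))
      stop("cell table '", basename(path), "' lacks required column '",
           cols[[canon]], "' (", canon, ")")
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0)
      stop("non-numeric ", what, " in column '", col, "' at data row ",
           bad[1])
    v
  }
  df <- data.frame(
    core_id = raw[[cols[["core_id"]]]],
    patient_id = raw[[cols[["patient_id"]]]],
    x = num(cols[["x"]], "coordinate"),
    y = num(cols[["y"]], "coordinate"),
    compartment = raw[[cols[["compartment"]]]],
    cd163 = num(cols[["cd163"]], "intensity"),
    stringsAsFactors = FALSE)
  df$cell_id <- if (cols[["cell_id"]] %in% names(raw))
    raw[[cols[["cell_id"]]]] else as.character(seq_len(nrow(df)))
  split_idx <- split(seq_len(nrow(df)), df$core_id)
  cores <- lapply(split_idx, function(i) {
    sub <- df[i, , drop = FALSE]
    pid <- unique(sub$patient_id)
    if (length(pid) != 1)
      stop("core '", sub$core_id[1], "' maps to multiple patient ids")
    # default window: bounding-box center; widen (with a warning) if the
    # centroids spread beyond the nominal core diameter
    cx <- mean(range(sub$x)); cy <- mean(range(sub$y))
    need <- 2 * sqrt(max((sub$x - cx)^2 + (sub$y - cy)^2)) * (1 + 1e-9)
    # around a bounding-box center, points from a genuine circular core of
    # this diameter can need up to ~1.15x the nominal diameter
    if (need > diameter_um * 1.15)
      warning("core '", sub$core_id[1], "': centroids span ",
              signif(need, 4), " um; window widened beyond ", diameter_um,
              " um")
    core_table(sub$core_id[1], pid,
               sub[c("cell_id", "x", "y", "compartment", "cd163")],
               window = list(cx = cx, cy = cy,
                             diameter = max(diameter_um, need)))
  })
  names(cores) <- vapply(cores, `[[`, "", "core_id")
  cores
}

#' Write per-core tables back to a delimited cell file
#'
#' Inverse of [read_cell_table()]; writes the canonical columns only, so
#' any per-cell annotation beyond the TAM label (and in particular any
#' synthetic ground truth carried as attributes) never reaches disk.
#'
#' @param cores List of [core_table] objects.
#' @param path Output CSV path.
#' @param include_tam Write the phenotyped `tam` column as 0/1?
#' @export
write_cell_table <- function(cores, path, include_tam = FALSE) {
  rows <- lapply(cores, function(core) {
    df <- data.frame(core_id = core$core_id, patient_id = core$patient_id,
                     cell_id = core$cells$cell_id,
                     x_um = core$cells$x, y_um = core$cells$y,
                     compartment = core$cells$compartment,
                     cd163_intensity = core$cells$cd163,
                     stringsAsFactors = FALSE)
    if (include_tam) df$tam <- as.integer(core$cells$tam)
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-control filter on minimum cancer-cell count
#'
#' Cores in which fewer than `min_cancer` cancer cells were segmented are
#' excluded (the background tolerance limit needs a minimal background
#' sample); the exclusion log records a machine-readable reason per core.
#'
#' @param cores List of [core_table] objects.
#' @param min_cancer Minimum cancer-cell count (inclusive), default 10.
#' @return List with `kept` (list of cores) and `excluded`
#'   (`data.frame` with `core_id`, `patient_id`, `reason`).
#' @export
qc_filter <- function(cores, min_cancer = 10) {
  keep <- vapply(cores, function(core) n_cancer(core) >= min_cancer, NA)
  excluded <- data.frame(
    core_id = vapply(cores[!keep], `[[`, "", "core_id"),
    patient_id = vapply(cores[!keep], `[[`, "", "patient_id"),
    reason = rep("min_cancer", sum(!keep)),
    stringsAsFactors = FALSE)
  list(kept = cores[keep], excluded = excluded)
}

#' Resolve duplicated cores to one core per patient
#'
#' For patients represented by more than one tissue core, the core with the
#' higher CD163+ TAM count is retained; ties are broken deterministically by
#' the lexicographically smallest core id. Requires phenotyping to have run
#' (the TAM counts), hence the fixed pipeline order
#' read -> QC -> phenotype -> dedup -> metrics.
#'
#' @param cores List of phenotyped [core_table] objects.
#' @param tam_counts Optional named numeric vector of CD163+ counts per
#'   core id; computed from the `tam` labels when `NULL`.
#' @return List with `kept` (one core per patient) and `dropped`
#'   (`data.frame` of removed duplicates).
#' @export
dedup_cores <- function(cores, tam_counts = NULL) {
  if (length(cores) == 0) return(list(kept = cores, dropped = data.frame()))
  ids <- vapply(cores, `[[`, "", "core_id")
  pids <- vapply(cores, `[[`, "", "patient_id")
  if (is.null(tam_counts)) {
    if (any(vapply(cores, function(core) anyNA(core$cells$tam), NA)))
      stop("dedup_cores requires phenotyped cores (or explicit tam_counts)")
    tam_counts <- vapply(cores, n_tam, 0)
    names(tam_counts) <- ids
  }
  counts <- tam_counts[ids]
  keep <- logical(length(cores))
  for (p in unique(pids)) {
    i <- which(pids == p)
    # highest TAM count wins; ties -> smallest core_id
    best <- i[order(-counts[i], ids[i])][1]
    keep[best] <- TRUE
  }
  dropped <- data.frame(core_id = ids[!keep], patient_id = pids[!keep],
                        reason = rep("duplicate_core", sum(!keep)),
                        stringsAsFactors = FALSE)
  list(kept = cores[keep], dropped = dropped)
}

#' Read the per-patient clinical table
#'
#' One row per patient. Canonical columns: `patient_id`, `pfs_months`,
#' `progressed` (0/1), `age`, `race` (white / non-white), `grade` (1/2/3),
#' `node` (negative / positive), `size_cat` (`<2cm`, `2-5cm`, `>5cm`),
#' `hr_status` (`HR+` / `HR-`), `her2`, `radiation` (0/1),
#' `hormone_compliance` (compliant / non-compliant; blank for HR-).
#' Empty strings are read as missing. Hormone-receptor status and
#' hormone-therapy compliance are combined into the 3-level factor `hrht`
#' with reference level `HR+ compliant` (HR- tumors form their own level,
#' since compliance is only meaningful for HR+ disease).
#'
#' @param path CSV path.
#' @return `data.frame` with typed columns and factor references set
#'   (grade 1, size `<2cm`, node negative, `HR+ compliant`).
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("patient_id", "pfs_months", "progressed")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clinical table lacks required column(s): ",
         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (any(df$pfs_months < 0, na.rm = TRUE)) stop("negative pfs_months")
  if (anyNA(df$pfs_months) || anyNA(df$progressed))
    stop("pfs_months/progressed must be complete (missingness is supported ",
         "in covariates only)")
  df$progressed <- as.integer(df$progressed)
  fct <- function(x, levels) factor(x, levels = levels)
  if (!is.null(df$race)) df$race <- fct(df$race, c("white", "non-white"))
  if (!is.null(df$grade)) df$grade <- fct(as.character(df$grade), c("1", "2", "3"))
  if (!is.null(df$node)) df$node <- fct(df$node, c("negative", "positive"))
  if (!is.null(df$size_cat)) df$size_cat <- fct(df$size_cat, c("<2cm", "2-5cm", ">5cm"))
  if (!is.null(df$her2)) df$her2 <- fct(df$her2, c("negative", "positive"))
  if (!is.null(df$radiation)) df$radiation <- as.integer(df$radiation)
  if (!is.null(df$hr_status) && !is.null(df$hormone_compliance))
    df$hrht <- make_hrht(df$hr_status, df$hormone_compliance)
  df
}

#' Combined hormone-receptor / hormone-therapy compliance factor
#'
#' @param hr_status Character/factor, `"HR+"` or `"HR-"`.
#' @param compliance Character/factor, `"compliant"` or `"non-compliant"`;
#'   ignored (may be missing) for HR- tumors.
#' @return Factor with levels `HR+ compliant` (reference),
#'   `HR+ non-compliant`, `HR-`.
#' @export
make_hrht <- function(hr_status, compliance) {
  hr <- as.character(hr_status)
  cp <- as.character(compliance)
  out <- ifelse(is.na(hr), NA_character_,
         ifelse(hr == "HR-", "HR-",
         ifelse(is.na(cp), NA_character_,
         ifelse(cp == "non-compliant", "HR+ non-compliant", "HR+ compliant"))))
  factor(out, levels = c("HR+ compliant", "HR+ non-compliant", "HR-"))
}
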