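#' @keywords internal
"_PACKAGE"

#' Immune markers quantified on the tissue microarray
#'
#' The nine immunohistochemistry markers whose positive-cell densities
#' (cells per mm2) enter the immune-profiling panel: CD3 (pan T cells),
#' CD8 and GZMB (cytotoxic T cells), FOXP3 (regulatory T cells), CD56
#' (NK cells), CD68 (macrophages), and the checkpoints CTLA4, LAG3, PD1.
#' @export
PANEL_MARKERS <- c("CD3", "CD8", "FOXP3", "CD56", "CD68",
                   "CTLA4", "LAG3", "PD1", "GZMB")

#' Tissue microarray sampling regions
#' @export
TMA_REGIONS <- c("invasion_front", "tumor_center")

#' PD-L1 companion diagnostic assays
#' @export
PDL1_ASSAYS <- c("SP142", "SP263", "22C3", "28-8")

#' Tumor immune microenvironment phenotype labels
#'
#' The four spatially organized immune phenotypes: `Evasion` (constitutive
#' PD-L1 tumor-cell expression, intermediate infiltration), `InflamedHigh`
#' (high PD-L1 immune-cell expression, high infiltration), `InflamedLow`
#' (moderate infiltration, low PD-L1), and `Uninflamed` (mostly absent
#' inflammation and PD-L1 expression).
#' @export
TIME_PHENOTYPES <- c("Evasion", "InflamedHigh", "InflamedLow", "Uninflamed")

# canonical spelling for assay aliases seen in the wild
canonicalize_assay <- function(x) {
  key <- toupper(gsub("[^0-9A-Za-z]", "", x))
  map <- c(SP142 = "SP142", SP263 = "SP263",
           `22C3` = "22C3", C22C3 = "22C3",
           `288` = "28-8", C288 = "28-8", `28_8` = "28-8")
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("unknown PD-L1 assay name(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

fail_rows <- function(what, rows) {
  stop(what, " (row", if (length(rows) > 1) "s", " ",
       paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) ", ...", ")", call. = FALSE)
}

require_columns <- function(df, cols, file_label) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", file_label, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

as_logical_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  chr <- tolower(trimws(as.character(x)))
  out[chr %in% c("true", "t", "1", "yes")] <- TRUE
  out[chr %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !all(is.na(x) == is.na(out))) {
    fail_rows(paste0("validation error: non-boolean values in '", name, "'"),
              which(is.na(out) & !is.na(x)))
  }
  out
}

validate_densities <- function(df) {
  require_columns(df, c("patient_id", "core_id", "region", "marker",
                        "density", "qc_pass"), "density table")
  df$patient_id <- as.character(df$patient_id)
  df$core_id <- as.character(df$core_id)
  df$region <- as.character(df$region)
  df$marker <- as.character(df$marker)
  df$density <- as.numeric(df$density)
  df$qc_pass <- as_logical_flag(df$qc_pass, "qc_pass")

  bad <- which(!df$region %in% TMA_REGIONS)
  if (length(bad)) fail_rows("validation error: region not in {invasion_front, tumor_center}", bad)
  bad <- which(!df$marker %in% PANEL_MARKERS)
  if (length(bad)) fail_rows("validation error: unknown marker", bad)
  bad <- which(is.na(df$density) | df$density < 0)
  if (length(bad)) fail_rows("validation error: density must be a non-negative number", bad)
  key <- paste(df$patient_id, df$core_id, df$marker, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) fail_rows("validation error: duplicate (patient_id, core_id, marker)", bad)
  df[, c("patient_id", "core_id", "region", "marker", "density", "qc_pass")]
}

validate_assays <- function(df) {
  require_columns(df, c("patient_id", "assay", "ic_percent", "tc_percent", "cps"),
                  "assay table")
  df$patient_id <- as.character(df$patient_id)
  df$assay <- canonicalize_assay(as.character(df$assay))
  for (col in c("ic_percent", "tc_percent", "cps")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
    if (length(bad)) fail_rows(paste0("validation error: ", col, " outside [0, 100]"), bad)
  }
  key <- paste(df$patient_id, df$assay, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) fail_rows("validation error: duplicate (patient_id, assay)", bad)
  df[, c("patient_id", "assay", "ic_percent", "tc_percent", "cps")]
}

ANNOTATION_COLS <- c("patient_id", "stils_percent",
                     "dss_time", "dss_event", "dfs_time", "dfs_event",
                     "pT", "pN", "L", "age", "gender", "margin",
                     "adj_chemo", "grade")

validate_annotations <- function(df) {
  require_columns(df, ANNOTATION_COLS, "annotation table")
  df$patient_id <- as.character(df$patient_id)
  bad <- which(duplicated(df$patient_id))
  if (length(bad)) fail_rows("validation error: duplicate patient_id in annotations", bad)
  df$stils_percent <- as.numeric(df$stils_percent)
  bad <- which(!is.na(df$stils_percent) &
                 (df$stils_percent < 0 | df$stils_percent > 100))
  if (length(bad)) fail_rows("validation error: stils_percent outside [0, 100]", bad)
  for (col in c("dss_time", "dfs_time")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) fail_rows(paste0("validation error: negative ", col), bad)
  }
  df$dss_event <- as_logical_flag(df$dss_event, "dss_event")
  df$dfs_event <- as_logical_flag(df$dfs_event, "dfs_event")
  df$age <- as.numeric(df$age)
  df$adj_chemo <- as_logical_flag(df$adj_chemo, "adj_chemo")
  for (col in c("pT", "pN", "L", "gender", "margin", "grade")) {
    df[[col]] <- as.character(df[[col]])
  }
  df[, ANNOTATION_COLS]
}

#' Assemble a validated cohort
#'
#' Bundles per-core marker densities, per-patient per-assay PD-L1 readouts,
#' and per-patient clinical annotations (sTILs, survival, covariates) into a
#' single validated `pdl1_cohort` object, the input container for all
#' downstream scoring, phenotyping and survival stages.
#'
#' @param densities data frame with columns `patient_id`, `core_id`, `region`
#'   (`invasion_front`/`tumor_center`), `marker` (one of [PANEL_MARKERS]),
#'   `density` (positive cells per mm2, non-negative), `qc_pass` (logical).
#' @param assays data frame with columns `patient_id`, `assay` (SP142, SP263,
#'   22C3, 28-8; common alias spellings accepted), `ic_percent`, `tc_percent`,
#'   `cps`, all percentages in \[0, 100\].
#' @param annotations data frame with columns `patient_id`, `stils_percent`,
#'   `dss_time`, `dss_event`, `dfs_time`, `dfs_event` plus the adjustment
#'   covariates `pT`, `pN`, `L`, `age`, `gender`, `margin`, `adj_chemo`,
#'   `grade`. Times are in months.
#' @return An object of class `pdl1_cohort`: a list with elements
#'   `densities`, `assays`, `annotations` (validated data frames).
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 8, seed = 1))
#' new_cohort(coh$densities, coh$assays, coh$annotations)
#' @export
new_cohort <- function(densities, assays, annotations) {
  out <- list(densities = validate_densities(as.data.frame(densities)),
              assays = validate_assays(as.data.frame(assays)),
              annotations = validate_annotations(as.data.frame(annotations)))
  structure(out, class = "pdl1_cohort")
}

#' @export
print.pdl1_cohort <- function(x, ...) {
  pats <- cohort_patients(x)
  cat("pdl1_cohort:", length(pats), "patients\n")
  cat("  density records:", nrow(x$densities),
      sprintf("(%d qc-pass)", sum(x$densities$qc_pass)), "\n")
  cat("  assay readouts: ", nrow(x$assays), "\n")
  cat("  annotations:    ", nrow(x$annotations), "\n")
  invisible(x)
}

#' Patients referenced anywhere in a cohort
#' @param cohort a [new_cohort()] object
#' @return character vector of unique patient ids, in first-appearance order
#' @export
cohort_patients <- function(cohort) {
  unique(c(cohort$densities$patient_id, cohort$assays$patient_id,
           cohort$annotations$patient_id))
}

#' Read a cohort from three CSV files
#'
#' Files are UTF-8, comma-separated with a header row and `.` decimal mark.
#' Rows failing validation abort the read with a diagnostic naming the
#' offending column or row.
#'
#' @param density_path CSV with columns
#'   `patient_id,core_id,region,marker,density,qc_pass`
#' @param assay_path CSV with columns
#'   `patient_id,assay,ic_percent,tc_percent,cps`
#' @param annotation_path CSV with columns
#'   `patient_id,stils_percent,dss_time,dss_event,dfs_time,dfs_event,pT,pN,L,age,gender,margin,adj_chemo,grade`
#' @return a validated [new_cohort()] object
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(density_path, assay_path, annotation_path) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  new_cohort(rd(density_path), rd(assay_path), rd(annotation_path))
}

#' Write a cohort to three CSV files
#'
#' Inverse of [read_cohort()]: writes `densities.csv`, `assays.csv` and
#' `annotations.csv` into `dir`. Numeric fields round-trip at full double
#' precision (15 significant digits).
#'
#' @param cohort a [new_cohort()] object
#' @param dir output directory, created if needed
#' @return invisibly, the three file paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pdl1_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("densities.csv", "assays.csv", "annotations.csv"))
  utils::write.csv(cohort$densities, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$assays, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$annotations, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Drop cores that failed quality control
#'
#' Cores without representative tumor tissue (less than 5% of the core area)
#' or with staining artifacts are flagged `qc_pass = FALSE` upstream (the
#' judgment is an input, not computed here). This filter retains only
#' qc-passing density records; patients losing all their cores are removed
#' from the cohort entirely and reported via a message. Patients are never
#' excluded merely for having fewer than four cores.
#'
#' @param cohort a [new_cohort()] object
#' @return a `pdl1_cohort` containing only `qc_pass = TRUE` density records.
#'   Idempotent: applying it twice equals applying it once.
#' @export
filter_qc <- function(cohort) {
  stopifnot(inherits(cohort, "pdl1_cohort"))
  keep <- cohort$densities[cohort$densities$qc_pass, , drop = FALSE]
  lost <- setdiff(unique(cohort$densities$patient_id), unique(keep$patient_id))
  if (length(lost)) {
    message("filter_qc: dropping ", length(lost),
            " patient(s) with no qc-passing core: ",
            paste(lost, collapse = ", "))
  }
  out <- cohort
  out$densities <- keep
  out$assays <- cohort$assays[!cohort$assays$patient_id %in% lost, , drop = FALSE]
  out$annotations <-
    cohort$annotations[!cohort$annotations$patient_id %in% lost, , drop = FALSE]
  rownames(out$densities) <- rownames(out$assays) <-
    rownames(out$annotations) <- NULL
  out
}
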