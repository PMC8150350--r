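# assays eligible for tumor-cell-dependent consensus scores: SP142 is
# excluded due to its decreased TC detection sensitivity
TC_ELIGIBLE_ASSAYS <- c("SP263", "22C3", "28-8")

#' Combined positive score (CPS)
#'
#' CPS = 100 x (PD-L1 positive tumor cells + PD-L1 positive immune cells) /
#' viable tumor cells, capped at 100. The clinical cut-off for pembrolizumab
#' eligibility is CPS >= 10.
#'
#' @param pos_tc count of PD-L1 positive tumor cells (non-negative)
#' @param pos_ic count of PD-L1 positive immune cells (non-negative)
#' @param total_viable_tc count of viable tumor cells (>= 1)
#' @return CPS in \[0, 100\]; vectorized over its arguments
#' @examples
#' compute_cps(5, 5, 100)   # 10
#' compute_cps(80, 40, 100) # capped at 100
#' @export
compute_cps <- function(pos_tc, pos_ic, total_viable_tc) {
  if (any(is.na(total_viable_tc)) || any(total_viable_tc < 1)) {
    stop("CPS undefined: total_viable_tc must be >= 1", call. = FALSE)
  }
  if (any(pos_tc < 0) || any(pos_ic < 0)) {
    stop("positive-cell counts must be non-negative", call. = FALSE)
  }
  pmin(100, 100 * (pos_tc + pos_ic) / total_viable_tc)
}

#' Cross-assay PD-L1 consensus scores
#'
#' Builds per-patient consensus scores as the median of each PD-L1 score
#' across companion diagnostic assays, minimizing inter-assay and section
#' influences. TC-dependent scores (`cps_consensus`, `tc_area_consensus`)
#' use SP263, 22C3 and 28-8 only — SP142 is excluded because of its reduced
#' tumor-cell detection sensitivity — while the immune-cell scores
#' (`ventana_ic_consensus`, `ic_area_consensus`, both the median of
#' `ic_percent`) use all four assays. The median of an even number of assays
#' is the mean of the two middle values. Missing assays degrade gracefully
#' to the median of the available eligible assays; a score with no eligible
#' assay at all is returned as `NA` with a warning naming the patient.
#'
#' @param readouts data frame of assay readouts
#'   (`patient_id,assay,ic_percent,tc_percent,cps`), one or more patients
#' @return data frame with one row per patient: `patient_id`,
#'   `cps_consensus`, `tc_area_consensus`, `ventana_ic_consensus`,
#'   `ic_area_consensus`
#' @export
build_consensus <- function(readouts) {
  readouts <- validate_assays(as.data.frame(readouts))
  if (!nrow(readouts)) stop("no assay readouts supplied", call. = FALSE)
  pats <- unique(readouts$patient_id)
  med <- function(x) if (length(x)) stats::median(x[!is.na(x)]) else NA_real_
  rows <- lapply(pats, function(p) {
    r <- readouts[readouts$patient_id == p, , drop = FALSE]
    tc_rows <- r[r$assay %in% TC_ELIGIBLE_ASSAYS, , drop = FALSE]
    data.frame(patient_id = p,
               cps_consensus = med(tc_rows$cps),
               tc_area_consensus = med(tc_rows$tc_percent),
               ventana_ic_consensus = med(r$ic_percent),
               ic_area_consensus = med(r$ic_percent),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  incomplete <- pats[!stats::complete.cases(out[-1])]
  if (length(incomplete)) {
    warning("missing consensus score(s): no eligible assay for patient(s) ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  }
  out
}

#' Binary PD-L1 status under the three clinical scoring algorithms
#'
#' Applies the drug-linked cut-offs to consensus scores, all inclusive (>=):
#' * `cps10` — pembrolizumab: `cps_consensus >= 10`
#' * `ventana_ic5` — atezolizumab: `ventana_ic_consensus >= 5`
#' * `tcic25` — durvalumab: `tc_area_consensus >= 25` OR
#'   `ic_area_consensus >= 25`
#'
#' @param consensus data frame from [build_consensus()]
#' @return data frame `patient_id`, `cps10`, `ventana_ic5`, `tcic25`
#'   (logical; `TRUE` = PD-L1 positive)
#' @export
classify_pdl1 <- function(consensus) {
  need <- list(cps10 = "cps_consensus",
               ventana_ic5 = "ventana_ic_consensus",
               tcic25 = c("tc_area_consensus", "ic_area_consensus"))
  for (alg in names(need)) {
    cols <- need[[alg]]
    missing_col <- setdiff(cols, names(consensus))
    if (length(missing_col)) {
      stop("cannot classify ", alg, ": missing consensus field(s) ",
           paste(missing_col, collapse = ", "), call. = FALSE)
    }
    if (anyNA(consensus[cols])) {
      stop("cannot classify ", alg, ": NA consensus score for patient(s) ",
           paste(consensus$patient_id[!stats::complete.cases(consensus[cols])],
                 collapse = ", "), call. = FALSE)
    }
  }
  data.frame(patient_id = consensus$patient_id,
             cps10 = consensus$cps_consensus >= 10,
             ventana_ic5 = consensus$ventana_ic_consensus >= 5,
             tcic25 = consensus$tc_area_consensus >= 25 |
                      consensus$ic_area_consensus >= 25,
             stringsAsFactors = FALSE)
}
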