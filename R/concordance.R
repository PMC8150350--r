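ALGORITHMS <- c("cps10", "ventana_ic5", "tcic25")

#' Overall percentage agreement (OPA)
#'
#' Fraction of cases on which two binary classifications agree (both
#' positive or both negative). Symmetric, and invariant to flipping the
#' positive/negative coding consistently in both vectors.
#'
#' @param a,b logical vectors of equal length, no missing entries
#' @return agreement in \[0, 1\]
#' @export
overall_percentage_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("status vectors differ in length",
                                   call. = FALSE)
  if (!length(a)) stop("empty status vectors", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing entries in status vectors",
                                 call. = FALSE)
  mean(as.logical(a) == as.logical(b))
}

#' Pairwise OPA matrix for the three scoring algorithms
#'
#' @param statuses data frame from [classify_pdl1()]
#' @return symmetric 3 x 3 matrix of agreements, unit diagonal
#' @export
opa_matrix <- function(statuses) {
  m <- diag(1, length(ALGORITHMS))
  dimnames(m) <- list(ALGORITHMS, ALGORITHMS)
  for (i in seq_along(ALGORITHMS)) for (j in seq_along(ALGORITHMS)) {
    if (i < j) {
      m[i, j] <- m[j, i] <-
        overall_percentage_agreement(statuses[[ALGORITHMS[i]]],
                                     statuses[[ALGORITHMS[j]]])
    }
  }
  m
}

VENN_REGIONS <- c("triple_positive", "cps_tcic_only", "ventana_tcic_only",
                  "cps_ventana_only", "cps_only", "ventana_only",
                  "tcic_only", "all_negative")

#' Venn partition of the three PD-L1 statuses
#'
#' Partitions the cohort into the eight regions of the three binary
#' PD-L1 statuses (which algorithms call the patient positive), together
#' with per-algorithm totals and the union-positive count. Region counts
#' always sum to the cohort size.
#'
#' @param statuses data frame from [classify_pdl1()] with complete
#'   `cps10`, `ventana_ic5`, `tcic25`
#' @return list with `regions` (named integer vector over the 8 regions),
#'   `totals` (positives per algorithm), `union_positive`, `n`
#' @export
venn_partition <- function(statuses) {
  cps <- as.logical(statuses$cps10)
  ven <- as.logical(statuses$ventana_ic5)
  tci <- as.logical(statuses$tcic25)
  if (anyNA(cps) || anyNA(ven) || anyNA(tci)) {
    stop("incomplete statuses", call. = FALSE)
  }
  regions <- c(
    triple_positive   = sum(cps & ven & tci),
    cps_tcic_only     = sum(cps & !ven & tci),
    ventana_tcic_only = sum(!cps & ven & tci),
    cps_ventana_only  = sum(cps & ven & !tci),
    cps_only          = sum(cps & !ven & !tci),
    ventana_only      = sum(!cps & ven & !tci),
    tcic_only         = sum(!cps & !ven & tci),
    all_negative      = sum(!cps & !ven & !tci)
  )
  list(regions = regions,
       totals = c(cps10 = sum(cps), ventana_ic5 = sum(ven),
                  tcic25 = sum(tci)),
       union_positive = sum(cps | ven | tci),
       n = length(cps))
}

#' Coverage of immune phenotypes by each scoring algorithm
#'
#' Cross-tabulates phenotype membership against PD-L1 positivity: for every
#' (phenotype, algorithm) pair, how many members of the phenotype the
#' algorithm classifies PD-L1 positive, as a count and a fraction.
#'
#' @param statuses data frame from [classify_pdl1()]
#' @param phenotypes data frame from [label_phenotypes()] (needs
#'   `patient_id`, `phenotype`)
#' @return data frame `phenotype`, `algorithm`, `n_phenotype`, `n_positive`,
#'   `coverage` (= n_positive / n_phenotype)
#' @export
phenotype_coverage <- function(statuses, phenotypes) {
  unmatched <- c(setdiff(statuses$patient_id, phenotypes$patient_id),
                 setdiff(phenotypes$patient_id, statuses$patient_id))
  if (length(unmatched)) {
    stop("patients without both a status and a phenotype: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  idx <- match(phenotypes$patient_id, statuses$patient_id)
  phen <- as.character(phenotypes$phenotype)
  out <- expand.grid(phenotype = unique(phen), algorithm = ALGORITHMS,
                     stringsAsFactors = FALSE)
  out$n_phenotype <- NA_integer_
  out$n_positive <- NA_integer_
  for (r in seq_len(nrow(out))) {
    members <- phen == out$phenotype[r]
    out$n_phenotype[r] <- sum(members)
    out$n_positive[r] <- sum(statuses[[out$algorithm[r]]][idx][members])
  }
  out$coverage <- out$n_positive / out$n_phenotype
  out
}

#' CD8/sTILs rescue of PD-L1-negative "Inflamed: Low" tumors
#'
#' Tumors of the `InflamedLow` phenotype carry relevant immune infiltrates
#' yet are frequently PD-L1 negative. Restricted to `InflamedLow` patients
#' classified PD-L1 negative by at least one algorithm, a patient is
#' "rescued" — flagged as harboring a relevant anti-tumoral immune
#' infiltrate despite PD-L1 negativity — when digital CD8 density meets the
#' cut-off (default >= 201 CD8+ cells per mm2, the cohort median) OR the
#' HE-slide sTILs score does (default >= 10%, the cohort median). Both
#' comparisons are inclusive.
#'
#' @param statuses data frame from [classify_pdl1()]
#' @param phenotypes data frame from [label_phenotypes()]
#' @param cd8_densities data frame `patient_id`, `cd8_density`:
#'   patient-level CD8 aggregate, the median across all qc-passing cores
#'   with both regions pooled (see [patient_cd8_density()])
#' @param stils data frame `patient_id`, `stils_percent`
#' @param cd8_cutoff,stils_cutoff positivity cut-offs; the defaults are
#'   this cohort's medians and should be re-derived for other cohorts
#' @return list with `results` (one row per eligible patient: `patient_id`,
#'   `pdl1_negative_by`, `cd8_density`, `stils_percent`, `rescued`) and
#'   `summary` (`n_eligible`, `n_negative_by_algorithm`,
#'   `n_triple_negative`, `n_rescued`, `rescued_fraction`)
#' @export
rescue_inflamed_low <- function(statuses, phenotypes, cd8_densities, stils,
                                cd8_cutoff = 201, stils_cutoff = 10) {
  il <- phenotypes$patient_id[phenotypes$phenotype == "InflamedLow"]
  s <- statuses[statuses$patient_id %in% il, , drop = FALSE]
  neg_any <- !(s$cps10 & s$ventana_ic5 & s$tcic25)
  s <- s[neg_any, , drop = FALSE]
  cd8 <- cd8_densities$cd8_density[match(s$patient_id,
                                         cd8_densities$patient_id)]
  st <- stils$stils_percent[match(s$patient_id, stils$patient_id)]
  if (anyNA(cd8) || anyNA(st)) {
    stop("missing CD8 density or sTILs value for eligible patient(s): ",
         paste(s$patient_id[is.na(cd8) | is.na(st)], collapse = ", "),
         call. = FALSE)
  }
  neg_by <- apply(!s[ALGORITHMS], 1,
                  function(v) paste(ALGORITHMS[v], collapse = "+"))
  results <- data.frame(patient_id = s$patient_id,
                        pdl1_negative_by = unname(neg_by),
                        cd8_density = cd8,
                        stils_percent = st,
                        rescued = cd8 >= cd8_cutoff | st >= stils_cutoff,
                        stringsAsFactors = FALSE)
  summary <- list(
    n_eligible = nrow(s),
    n_negative_by_algorithm = c(cps10 = sum(!s$cps10),
                                ventana_ic5 = sum(!s$ventana_ic5),
                                tcic25 = sum(!s$tcic25)),
    n_triple_negative = sum(!s$cps10 & !s$ventana_ic5 & !s$tcic25),
    n_rescued = sum(results$rescued),
    rescued_fraction = if (nrow(s)) mean(results$rescued) else NA_real_
  )
  list(results = results, summary = summary)
}

#' Patient-level CD8 density aggregate
#'
#' Median CD8+ density across a patient's qc-passing cores, invasion front
#' and tumor center pooled — the "overall CD8 infiltration" feeding the
#' rescue rule.
#'
#' @param densities qc-filtered density records
#' @return data frame `patient_id`, `cd8_density`
#' @export
patient_cd8_density <- function(densities) {
  cd8 <- densities[densities$marker == "CD8", , drop = FALSE]
  agg <- stats::aggregate(density ~ patient_id, data = cd8,
                          FUN = stats::median)
  names(agg)[2] <- "cd8_density"
  agg
}
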