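PDL1_FEATURES <- c("cps_consensus", "tc_area_consensus",
                   "ventana_ic_consensus", "ic_area_consensus")

#' Aggregate per-core densities to patient-level medians
#'
#' For each (patient, marker, region) the median density across that
#' patient's qc-passing cores in that region. With the standard TMA design
#' (two cores per region) this is the mean of the duplicate cores; single
#' surviving cores contribute their own value.
#'
#' @param records density records (data frame as in a cohort's `densities`
#'   element), already qc-filtered via [filter_qc()]
#' @return data frame `patient_id`, `marker`, `region`, `density` (median,
#'   cells per mm2); combinations with no core are absent (resolved later by
#'   the imputation policy in [transform_features()])
#' @export
aggregate_densities <- function(records) {
  records <- as.data.frame(records)
  agg <- stats::aggregate(density ~ patient_id + marker + region,
                          data = records, FUN = stats::median)
  agg <- agg[order(agg$patient_id, agg$marker, agg$region), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# z-score with population SD (divisor n); zero-variance columns -> all 0
zscore_pop <- function(x) {
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) return(rep(0, length(x)))
  (x - mu) / sd_pop
}

#' Build the clustering feature matrix
#'
#' Assembles the patients x features matrix used for phenotype clustering:
#' 18 density features (9 markers x 2 regions), transformed
#' `x -> log2(x + 1)` and then Z-scored per feature with the population SD
#' (divisor n), plus the four PD-L1 consensus scores Z-scored on their
#' native percent scale (no log transform). Missing density cells (a patient
#' with no qc-passing core for a marker/region) are imputed with the
#' feature's cohort median before the Z transform. Zero-variance features
#' become all-zero columns.
#'
#' @param density_table output of [aggregate_densities()]
#' @param pdl1_consensus output of [build_consensus()] for the same patients
#' @param pseudocount added inside the log2 (default 1, mapping density 0
#'   to feature value 0)
#' @return a `feature_matrix` object: a numeric matrix (rownames =
#'   patient ids) with attribute `density_features` naming the 18 density
#'   columns (the ICIS components)
#' @export
transform_features <- function(density_table, pdl1_consensus, pseudocount = 1) {
  pats <- sort(unique(c(density_table$patient_id, pdl1_consensus$patient_id)))
  dens_feats <- as.vector(outer(PANEL_MARKERS, TMA_REGIONS, paste, sep = "_"))
  m <- matrix(NA_real_, nrow = length(pats),
              ncol = length(dens_feats) + length(PDL1_FEATURES),
              dimnames = list(pats, c(dens_feats, PDL1_FEATURES)))
  feat <- paste(density_table$marker, density_table$region, sep = "_")
  m[cbind(match(density_table$patient_id, pats), match(feat, dens_feats))] <-
    density_table$density
  idx <- match(pdl1_consensus$patient_id, pats)
  for (f in PDL1_FEATURES) m[idx, f] <- pdl1_consensus[[f]]

  # impute missing cells with the feature's cohort median, then transform;
  # a feature with no observed value at all becomes a constant (zero) column
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (all(miss)) m[, j] <- 0
    else if (any(miss)) m[miss, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  m[, dens_feats] <- log2(m[, dens_feats] + pseudocount)
  dn <- dimnames(m)
  m <- apply(m, 2, zscore_pop)
  if (length(pats) == 1) m <- matrix(m, nrow = 1)
  dimnames(m) <- dn
  structure(m, density_features = dens_feats, class = c("feature_matrix",
                                                        class(m)))
}

#' Combined immune cell infiltration score (ICIS)
#'
#' ICIS summarizes a patient's overall immune infiltration as the arithmetic
#' mean of the 18 Z-scored log2 density features (PD-L1 consensus features
#' are not part of ICIS). By construction the cohort mean ICIS is 0; units
#' are Z-score units.
#'
#' @param matrix a [transform_features()] feature matrix
#' @return data frame `patient_id`, `icis`
#' @export
compute_icis <- function(matrix) {
  dens <- attr(matrix, "density_features")
  if (is.null(dens)) dens <- setdiff(colnames(matrix), PDL1_FEATURES)
  data.frame(patient_id = rownames(matrix),
             icis = rowMeans(matrix[, dens, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' WPGMA clustering of patients
#'
#' Unsupervised agglomerative clustering of the patient rows of the feature
#' matrix with the weighted pair-group method using arithmetic averages
#' (WPGMA; the `"mcquitty"` linkage of [stats::hclust()]) on Euclidean
#' distances, with the tree cut to exactly `k` flat clusters. Deterministic
#' given the input row order.
#'
#' @param matrix numeric matrix, patients x features
#' @param k number of flat clusters (default 4, the number of tumor immune
#'   phenotypes)
#' @return named integer vector of cluster ids in `1:k` (names = patient
#'   ids), numbered by order of first appearance in the row order
#' @export
wpgma_cluster <- function(matrix, k = 4) {
  n <- nrow(matrix)
  if (n < k) stop("cannot cut ", n, " patients into ", k, " clusters",
                  call. = FALSE)
  if (anyNA(matrix)) stop("feature matrix contains missing values", call. = FALSE)
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "mcquitty")
  cl <- stats::cutree(hc, k = k)
  # renumber by first appearance so ids are stable in the row order
  stats::setNames(match(cl, unique(cl)), rownames(matrix))
}

cluster_rank_stat <- function(values, clusters) {
  vapply(split(values, clusters), mean, numeric(1))
}

#' Label clusters as tumor immune microenvironment phenotypes
#'
#' Maps the `k = 4` flat clusters onto the four phenotype labels with a
#' deterministic rule reflecting their defining PD-L1/infiltration
#' signatures:
#' 1. `Evasion` — the cluster with the highest mean Z of
#'    `tc_area_consensus` (constitutive PD-L1 tumor-cell expression);
#' 2. `InflamedHigh` — of the remaining clusters, the highest mean Z of
#'    `ic_area_consensus` (PD-L1 on immune cells);
#' 3. of the last two, `InflamedLow` has the higher mean ICIS and
#'    `Uninflamed` the lower.
#'
#' Ties in a ranking statistic are broken toward the lower cluster id, with
#' a warning.
#'
#' @param assignments cluster vector from [wpgma_cluster()] (k = 4)
#' @param matrix the [transform_features()] matrix used for clustering
#' @param icis output of [compute_icis()] on the same matrix
#' @return data frame `patient_id`, `cluster_id`, `phenotype` (factor with
#'   levels [TIME_PHENOTYPES]), `icis`
#' @export
label_phenotypes <- function(assignments, matrix, icis) {
  ids <- sort(unique(assignments))
  if (length(ids) != 4 || !all(ids == 1:4)) {
    stop("phenotype labelling requires exactly 4 clusters numbered 1-4, got {",
         paste(ids, collapse = ", "), "}", call. = FALSE)
  }
  pick <- function(stat, candidates) {
    s <- stat[as.character(candidates)]
    top <- candidates[s == max(s)]
    if (length(top) > 1) {
      warning("tie in phenotype ranking statistic; resolved toward lower ",
              "cluster id", call. = FALSE)
    }
    min(top)
  }
  tc_stat <- cluster_rank_stat(matrix[, "tc_area_consensus"], assignments)
  ic_stat <- cluster_rank_stat(matrix[, "ic_area_consensus"], assignments)
  icis_by_pat <- stats::setNames(icis$icis, icis$patient_id)
  icis_stat <- cluster_rank_stat(icis_by_pat[names(assignments)], assignments)

  evasion <- pick(tc_stat, ids)
  rest <- setdiff(ids, evasion)
  inflamed_high <- pick(ic_stat, rest)
  last2 <- setdiff(rest, inflamed_high)
  inflamed_low <- pick(icis_stat, last2)
  uninflamed <- setdiff(last2, inflamed_low)

  label_of <- character(4)
  label_of[c(evasion, inflamed_high, inflamed_low, uninflamed)] <-
    TIME_PHENOTYPES
  data.frame(patient_id = names(assignments),
             cluster_id = unname(assignments),
             phenotype = factor(label_of[assignments], levels = TIME_PHENOTYPES),
             icis = unname(icis_by_pat[names(assignments)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full phenotyping pipeline on a cohort
#'
#' Convenience wrapper chaining [filter_qc()], [aggregate_densities()],
#' [build_consensus()], [transform_features()], [compute_icis()],
#' [wpgma_cluster()] and [label_phenotypes()].
#'
#' @param cohort a [new_cohort()] object
#' @param k number of clusters (default 4)
#' @return list with elements `consensus`, `status` (from
#'   [classify_pdl1()]), `features`, `icis`, `phenotypes`
#' @export
phenotype_cohort <- function(cohort, k = 4) {
  cohort <- filter_qc(cohort)
  dens <- aggregate_densities(cohort$densities)
  consensus <- build_consensus(cohort$assays)
  features <- transform_features(dens, consensus)
  icis <- compute_icis(features)
  clusters <- wpgma_cluster(features, k = k)
  phen <- if (k == 4) label_phenotypes(clusters, features, icis) else {
    data.frame(patient_id = names(clusters), cluster_id = unname(clusters),
               phenotype = factor(NA, levels = TIME_PHENOTYPES),
               icis = icis$icis[match(names(clusters), icis$patient_id)],
               stringsAsFactors = FALSE)
  }
  list(consensus = consensus,
       status = classify_pdl1(consensus),
       features = features,
       icis = icis,
       phenotypes = phen)
}
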