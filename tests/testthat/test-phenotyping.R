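dens_rec <- function(patient, core, region, marker, density) {
  data.frame(patient_id = patient, core_id = core, region = region,
             marker = marker, density = density, qc_pass = TRUE,
             stringsAsFactors = FALSE)
}

test_that("aggregate_densities takes per-region medians across cores", {
  recs <- rbind(
    dens_rec("P1", c("IF1", "IF2"), "invasion_front", "CD8", c(100, 300)),
    dens_rec("P1", "TC1", "tumor_center", "CD8", 150),
    dens_rec("P2", c("IF1", "IF2", "IF3", "IF4"), "invasion_front", "CD8",
             c(0, 0, 10, 1000)))
  agg <- aggregate_densities(recs)
  get <- function(p, r) agg$density[agg$patient_id == p & agg$region == r]
  expect_equal(get("P1", "invasion_front"), 200) # median of two cores
  expect_equal(get("P1", "tumor_center"), 150)   # single core
  expect_equal(get("P2", "invasion_front"), 5)   # median of {0,0,10,1000}
})

two_patient_matrix <- function(d1, d2) {
  recs <- dens_rec(c("P1", "P2"), "IF1", "invasion_front", "CD8", c(d1, d2))
  cons <- data.frame(patient_id = c("P1", "P2"), cps_consensus = c(10, 20),
                     tc_area_consensus = c(5, 5),
                     ventana_ic_consensus = c(1, 3),
                     ic_area_consensus = c(1, 3))
  transform_features(aggregate_densities(recs), cons)
}

test_that("transform_features applies log2(x+1) then a population-SD Z-score", {
  m <- two_patient_matrix(1, 3) # log2 {1, 2} -> Z {-1, +1}
  expect_equal(unname(m[, "CD8_invasion_front"]), c(-1, 1))
  # constant feature -> all-zero column (zero-variance policy)
  expect_equal(unname(m[, "tc_area_consensus"]), c(0, 0))
  # density 0 maps to feature value 0 before Z (pseudocount)
  m0 <- two_patient_matrix(0, 3)
  expect_equal(attr(m0, "density_features")[1:2],
               c("CD3_invasion_front", "CD8_invasion_front"))
  expect_equal(unname(m0[, "CD8_invasion_front"]), c(-1, 1)) # symmetric Z
})

test_that("non-constant feature columns are centred and scaled to population SD 1", {
  coh <- filter_qc(generate_cohort(simulation_config(n_patients = 40,
                                                     seed = 5)))
  m <- transform_features(aggregate_densities(coh$densities),
                          build_consensus(coh$assays))
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    expect_lt(abs(mean(m[, j])), 1e-9)
    sd_pop <- sqrt(mean((m[, j] - mean(m[, j]))^2))
    expect_true(abs(sd_pop - 1) < 1e-9 || sd_pop == 0)
  }
})

test_that("missing density cells are median-imputed, preserving Z-centring", {
  recs <- rbind(
    dens_rec(c("P1", "P2", "P3"), "IF1", "invasion_front", "CD8",
             c(10, 20, 40)),
    dens_rec(c("P1", "P2"), "TC1", "tumor_center", "CD8", c(10, 30)))
  cons <- data.frame(patient_id = c("P1", "P2", "P3"),
                     cps_consensus = 1:3, tc_area_consensus = 1:3,
                     ventana_ic_consensus = 1:3, ic_area_consensus = 1:3)
  m <- transform_features(aggregate_densities(recs), cons)
  expect_false(anyNA(m))
  # P3 has no tumor_center core; imputed with the feature median (20),
  # which sits between P1 and P2 on the transformed scale
  v <- m[, "CD8_tumor_center"]
  expect_true(v[["P1"]] < v[["P3"]] && v[["P3"]] < v[["P2"]])
})

test_that("ICIS is the mean of density Z-scores and ignores feature order", {
  m <- two_patient_matrix(1, 3)
  icis <- compute_icis(m)
  # single non-constant density feature among 2 density features used here
  expect_equal(icis$icis, rowMeans(m[, attr(m, "density_features")]),
               ignore_attr = TRUE)
  expect_lt(abs(mean(icis$icis)), 1e-9) # cohort mean 0 by construction

  perm <- m[, sample(ncol(m)), drop = FALSE]
  attr(perm, "density_features") <- attr(m, "density_features")
  expect_equal(compute_icis(perm), icis)

  # patient uniformly +1 SD on every density feature has ICIS 1
  fake <- matrix(c(1, -1), nrow = 2, ncol = 5,
                 dimnames = list(c("A", "B"), paste0("f", 1:5)))
  attr(fake, "density_features") <- paste0("f", 1:5)
  expect_equal(compute_icis(fake)$icis, c(1, -1))
})

test_that("wpgma_cluster reproduces hand-computed linkage on small cases", {
  # 1-D points {0, 1, 10}: merge (0,1) at d=1; cluster-to-point distance
  # to 10 is (10+9)/2 = 9.5, so k=2 gives {0,1} vs {10}
  x <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "f"))
  cl <- wpgma_cluster(x, k = 2)
  expect_equal(unname(cl), c(1, 1, 2))

  # two tight pairs far apart
  y <- matrix(c(0, 0.1, 50, 50.1), ncol = 1,
              dimnames = list(letters[1:4], "f"))
  expect_equal(unname(wpgma_cluster(y, k = 2)), c(1, 1, 2, 2))

  # identical duplicate rows co-cluster (zero distance merges first)
  z <- matrix(c(5, 5, 0, 9), ncol = 1, dimnames = list(letters[1:4], "f"))
  cl <- wpgma_cluster(z, k = 3)
  expect_equal(cl[["a"]], cl[["b"]])

  expect_error(wpgma_cluster(x, k = 5), "cannot cut")
})

test_that("wpgma_cluster matches a brute-force agglomerative oracle", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    p <- sample(2:4, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    k <- sample(2:4, 1)
    expect_true(same_partition(unname(wpgma_cluster(x, k)),
                               oracle_wpgma_cut(x, k)),
                info = sprintf("instance %d (n=%d, k=%d)", i, n, k))
  }
})

test_that("label_phenotypes applies the TC -> IC -> ICIS ranking rule", {
  # four well-separated archetype clusters, 2 patients each
  feats <- c("tc_area_consensus", "ic_area_consensus", "d1", "d2")
  arche <- rbind(
    Evasion = c(3, -1, 0, 0),
    InflamedHigh = c(-1, 3, 2, 2),
    InflamedLow = c(-1, -0.5, 0.5, 0.5),
    Uninflamed = c(-1, -1.5, -3, -3))
  m <- arche[rep(1:4, each = 2), ]
  rownames(m) <- sprintf("P%d", 1:8)
  colnames(m) <- feats
  attr(m, "density_features") <- c("d1", "d2")
  cl <- setNames(rep(1:4, each = 2), rownames(m))
  icis <- compute_icis(m)
  lab <- label_phenotypes(cl, m, icis)
  expect_equal(as.character(lab$phenotype),
               rep(c("Evasion", "InflamedHigh", "InflamedLow", "Uninflamed"),
                   each = 2))

  # a cluster maximizing both TC and IC is assigned Evasion (TC rule first)
  m2 <- m
  m2[1:2, "ic_area_consensus"] <- 5
  lab2 <- label_phenotypes(cl, m2, compute_icis(m2))
  expect_equal(as.character(lab2$phenotype[1]), "Evasion")
  # and InflamedHigh falls to the next-highest IC cluster
  expect_equal(as.character(lab2$phenotype[3]), "InflamedHigh")

  # degenerate all-zero matrix: ties resolved by cluster id with a warning
  m0 <- m * 0
  w <- capture_warnings(lab0 <- label_phenotypes(cl, m0, compute_icis(m0)))
  expect_match(w, "tie", all = TRUE)
  expect_length(w, 3) # one tie per ranking step
  expect_equal(as.character(lab0$phenotype),
               rep(TIME_PHENOTYPES, each = 2))
})

test_that("phenotype labels recover the generating phenotypes on a synthetic cohort", {
  coh <- generate_cohort(simulation_config(n_patients = 120, seed = 2))
  res <- phenotype_cohort(coh)
  truth <- attr(coh, "true_phenotypes")
  est <- res$phenotypes$phenotype[match(truth$patient_id,
                                        res$phenotypes$patient_id)]
  expect_gte(mean(as.character(est) == truth$phenotype), 0.9)
  expect_equal(sort(unique(res$phenotypes$cluster_id)), 1:4)
})
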