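# base log2 density (cells per mm2) per marker, typical of urothelial
# cancer immune infiltrates: T-cell markers abundant, NK cells sparse
MARKER_BASE_LOG2 <- c(CD3 = 7, CD8 = 6.5, FOXP3 = 5, CD56 = 3, CD68 = 6,
                      CTLA4 = 4, LAG3 = 3.5, PD1 = 5, GZMB = 4)
# cores at the invasion front run slightly denser than the tumor center
REGION_SHIFT_LOG2 <- c(invasion_front = 0.4, tumor_center = 0)

#' Default phenotype simulation profiles
#'
#' One profile per tumor immune microenvironment phenotype, encoding the
#' data-generating signature the analysis assumes:
#' * `Evasion` — high PD-L1 tumor-cell expression (TC ~ 60%), low
#'   immune-cell expression, intermediate infiltration; poor outcome
#'   (5-year DSS 29.8%).
#' * `InflamedHigh` — high PD-L1 IC expression (~30%), low TC, high
#'   infiltration; favorable outcome (5-year DSS 74.7%).
#' * `InflamedLow` — moderate infiltration, low PD-L1 on IC and TC;
#'   5-year DSS 43.1%.
#' * `Uninflamed` — mostly absent inflammation and PD-L1; 5-year DSS 27.7%.
#'
#' `density_log2_means` is a 9 x 2 (marker x region) matrix of mean log2
#' densities; `density_log2_sd` the per-core log2 SD; `pdl1_*_mean` /
#' `pdl1_sd` the between-patient mean/SD of the percent-scale PD-L1 scores;
#' `five_year_dss` / `five_year_dfs` parameterize the exponential survival
#' component.
#'
#' @param infiltration_shift named numeric, log2 shift added to the marker
#'   base densities per phenotype (controls phenotype separation)
#' @return named list of four profile lists, in [TIME_PHENOTYPES] order
#' @export
phenotype_profiles <- function(infiltration_shift = c(Evasion = 0.8,
                                                      InflamedHigh = 2.5,
                                                      InflamedLow = 0,
                                                      Uninflamed = -2.5)) {
  pdl1 <- list(
    Evasion      = list(ic = 2,   tc = 60,  cps = 65),
    InflamedHigh = list(ic = 30,  tc = 5,   cps = 35),
    InflamedLow  = list(ic = 1.5, tc = 0.5, cps = 6),
    Uninflamed   = list(ic = 0.3, tc = 0.3, cps = 1)
  )
  dss <- c(Evasion = 0.298, InflamedHigh = 0.747, InflamedLow = 0.431,
           Uninflamed = 0.277)
  dfs <- c(Evasion = 0.258, InflamedHigh = 0.751, InflamedLow = 0.437,
           Uninflamed = 0.237)
  out <- lapply(TIME_PHENOTYPES, function(ph) {
    means <- outer(MARKER_BASE_LOG2 + infiltration_shift[[ph]],
                   REGION_SHIFT_LOG2, `+`)
    dimnames(means) <- list(PANEL_MARKERS, TMA_REGIONS)
    list(phenotype = ph,
         density_log2_means = means,
         density_log2_sd = 0.8,
         pdl1_ic_mean = pdl1[[ph]]$ic,
         pdl1_tc_mean = pdl1[[ph]]$tc,
         pdl1_cps_mean = pdl1[[ph]]$cps,
         pdl1_sd = 8,
         five_year_dss = unname(dss[ph]),
         five_year_dfs = unname(dfs[ph]))
  })
  stats::setNames(out, TIME_PHENOTYPES)
}

#' Simulation configuration
#'
#' @param n_patients cohort size (default 193, the study cohort)
#' @param prevalences phenotype prevalences in [TIME_PHENOTYPES] order,
#'   summing to 1. The default (0.14, 0.14, 0.35, 0.37) allocates 27
#'   patients each to Evasion and InflamedHigh at n = 193; the
#'   InflamedLow/Uninflamed split is an assumption.
#' @param seed RNG seed; the generator is fully reproducible from it
#' @param assay_noise_sd within-patient between-assay SD of the percent
#'   scores (default 5)
#' @param sp142_tc_attenuation fraction of tumor-cell signal the SP142
#'   assay fails to detect; SP142 `tc_percent` is multiplied by
#'   `1 - sp142_tc_attenuation` (default 0.8)
#' @param censoring_rate target fraction of censored observations
#'   (default 0.3); censoring times are uniform on a scaled \[0, 120\]
#'   month window solved to hit this rate under each phenotype's hazard
#' @param cores_per_region TMA cores per region per patient (default 2,
#'   i.e. four cores per patient)
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_patients = 193,
                              prevalences = c(0.14, 0.14, 0.35, 0.37),
                              seed = 1,
                              assay_noise_sd = 5,
                              sp142_tc_attenuation = 0.8,
                              censoring_rate = 0.3,
                              cores_per_region = 2) {
  if (length(prevalences) != 4 || any(prevalences < 0) ||
      abs(sum(prevalences) - 1) > 1e-9) {
    stop("prevalences must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 prevalences = prevalences, seed = as.integer(seed),
                 assay_noise_sd = assay_noise_sd,
                 sp142_tc_attenuation = sp142_tc_attenuation,
                 censoring_rate = censoring_rate,
                 cores_per_region = as.integer(cores_per_region)),
            class = "simulation_config")
}

# exact integer allocation of n among proportions by largest remainder,
# ties toward the earlier class
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    rank <- order(-(raw - base), seq_along(p))
    base[rank[seq_len(short)]] <- base[rank[seq_len(short)]] + 1
  }
  as.integer(base)
}

clip01 <- function(x) pmin(100, pmax(0, x))

# uniform censoring window [0, b] with b solved so that
# P(C < T) = target under T ~ Exp(rate)
censoring_window <- function(rate, target) {
  if (target <= 0) return(Inf)
  p_cens <- function(b) (1 - exp(-rate * b)) / (rate * b) - target
  stats::uniroot(p_cens, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Simulates a cohort with the statistical structure the analysis assumes:
#' patients are allocated to the four immune phenotypes by exact
#' largest-remainder rounding of the prevalences; per-core marker densities
#' are log-normal around the phenotype's (marker, region) mean
#' (`density = 2^z - 1`, `z ~ N(mean, sd)`, truncated at 0, so the
#' `log2(x + 1)` feature transform recovers the mean); per-assay PD-L1
#' percent scores are the patient's phenotype-level latent value plus
#' Gaussian assay noise, clipped to \[0, 100\], with the SP142 tumor-cell
#' score attenuated; survival is exponential with the rate solving
#' `S(60) = ` the phenotype's five-year rate, under independent uniform
#' censoring scaled to the target censoring rate. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()]
#' @param profiles four [phenotype_profiles()] entries
#' @return a validated [new_cohort()] with all cores `qc_pass = TRUE`; the
#'   generating phenotype of every patient is attached as attribute
#'   `true_phenotypes` (data frame `patient_id`, `phenotype`)
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 20, seed = 7))
#' table(attr(coh, "true_phenotypes")$phenotype)
#' @export
generate_cohort <- function(config = simulation_config(),
                            profiles = phenotype_profiles()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  n <- config$n_patients
  counts <- largest_remainder(n, config$prevalences)
  phen <- rep(TIME_PHENOTYPES, counts)
  ids <- sprintf("P%04d", seq_len(n))

  # per-core densities: patients x markers x regions x cores
  cpr <- config$cores_per_region
  grid <- expand.grid(patient = seq_len(n), marker = PANEL_MARKERS,
                      region = TMA_REGIONS, core = seq_len(cpr),
                      stringsAsFactors = FALSE)
  mu_arr <- vapply(TIME_PHENOTYPES,
                   function(ph) profiles[[ph]]$density_log2_means,
                   matrix(0, length(PANEL_MARKERS), length(TMA_REGIONS)))
  phi <- match(phen[grid$patient], TIME_PHENOTYPES)
  mu <- mu_arr[cbind(match(grid$marker, PANEL_MARKERS),
                     match(grid$region, TMA_REGIONS), phi)]
  sd_by_phen <- vapply(profiles, `[[`, numeric(1), "density_log2_sd")
  sd_core <- sd_by_phen[phi]
  dens <- pmax(0, 2^stats::rnorm(nrow(grid), mu, sd_core) - 1)
  core_id <- paste0(ifelse(grid$region == "invasion_front", "IF", "TC"),
                    grid$core)
  densities <- data.frame(patient_id = ids[grid$patient],
                          core_id = core_id,
                          region = grid$region,
                          marker = grid$marker,
                          density = dens,
                          qc_pass = TRUE,
                          stringsAsFactors = FALSE)

  # PD-L1 readouts: patient latent level + assay noise
  latent <- function(field) {
    means <- vapply(phen, function(ph) profiles[[ph]][[field]], numeric(1))
    sds <- vapply(phen, function(ph) profiles[[ph]]$pdl1_sd, numeric(1))
    clip01(stats::rnorm(n, means, sds))
  }
  lat_ic <- latent("pdl1_ic_mean")
  lat_tc <- latent("pdl1_tc_mean")
  lat_cps <- latent("pdl1_cps_mean")
  agrid <- expand.grid(patient = seq_len(n), assay = PDL1_ASSAYS,
                       stringsAsFactors = FALSE)
  noise <- function() stats::rnorm(nrow(agrid), 0, config$assay_noise_sd)
  ic <- clip01(lat_ic[agrid$patient] + noise())
  tc <- clip01(lat_tc[agrid$patient] + noise())
  cps <- clip01(lat_cps[agrid$patient] + noise())
  sp142 <- agrid$assay == "SP142"
  tc[sp142] <- tc[sp142] * (1 - config$sp142_tc_attenuation)
  assays <- data.frame(patient_id = ids[agrid$patient], assay = agrid$assay,
                       ic_percent = ic, tc_percent = tc, cps = cps,
                       stringsAsFactors = FALSE)

  # survival: exponential with S(60) = five-year rate, uniform censoring
  sim_endpoint <- function(rate_field) {
    time <- obs_event <- numeric(n)
    for (ph in TIME_PHENOTYPES) {
      sel <- phen == ph
      if (!any(sel)) next
      lambda <- -log(profiles[[ph]][[rate_field]]) / 60
      tt <- stats::rexp(sum(sel), lambda)
      b <- censoring_window(lambda, config$censoring_rate)
      cc <- if (is.finite(b)) stats::runif(sum(sel), 0, b) else Inf
      time[sel] <- pmin(tt, cc)
      obs_event[sel] <- tt <= cc
    }
    list(time = time, event = as.logical(obs_event))
  }
  dss <- sim_endpoint("five_year_dss")
  dfs <- sim_endpoint("five_year_dfs")

  # sTILs track the infiltration level (InflamedHigh high, Uninflamed low)
  stils_mean <- c(Evasion = 12, InflamedHigh = 40, InflamedLow = 15,
                  Uninflamed = 2)
  stils <- clip01(stats::rnorm(n, stils_mean[phen], 6))

  annotations <- data.frame(
    patient_id = ids,
    stils_percent = stils,
    dss_time = dss$time, dss_event = dss$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    pT = sample(c("pT2", "pT3", "pT4"), n, TRUE, c(0.35, 0.45, 0.2)),
    pN = sample(c("pN0", "pN+"), n, TRUE, c(0.65, 0.35)),
    L = sample(c("L0", "L1"), n, TRUE, c(0.6, 0.4)),
    age = round(stats::rnorm(n, 69.7, 9), 1),
    gender = sample(c("male", "female"), n, TRUE, c(0.72, 0.28)),
    margin = sample(c("R0", "R1"), n, TRUE, c(0.85, 0.15)),
    adj_chemo = stats::runif(n) < 0.254,
    grade = sample(c("G2", "G3"), n, TRUE, c(0.2, 0.8)),
    stringsAsFactors = FALSE)

  cohort <- new_cohort(densities, assays, annotations)
  attr(cohort, "true_phenotypes") <-
    data.frame(patient_id = ids, phenotype = phen, stringsAsFactors = FALSE)
  cohort
}

#' Exact in-study Venn fixture (n = 193)
#'
#' A deterministic binary-status table whose three-way Venn partition
#' reproduces the published 193-patient cohort exactly: 54 triple-positive;
#' 21 CPS10 & TC/IC only; 10 Ventana & TC/IC only; 1 CPS10 & Ventana only;
#' 8 CPS10-only; 5 Ventana-only; 4 TC/IC-only; 90 all-negative (hence
#' per-algorithm totals 84 / 70 / 89 and 103 union-positive). Which
#' individual patient occupies which region is arbitrary (ids sequential);
#' only the region counts are meaningful.
#'
#' @return data frame `patient_id`, `cps10`, `ventana_ic5`, `tcic25`
#' @export
fixture_from_venn <- function() {
  region_counts <- c(triple_positive = 54, cps_tcic_only = 21,
                     ventana_tcic_only = 10, cps_ventana_only = 1,
                     cps_only = 8, ventana_only = 5, tcic_only = 4,
                     all_negative = 90)
  membership <- list(
    triple_positive   = c(TRUE, TRUE, TRUE),
    cps_tcic_only     = c(TRUE, FALSE, TRUE),
    ventana_tcic_only = c(FALSE, TRUE, TRUE),
    cps_ventana_only  = c(TRUE, TRUE, FALSE),
    cps_only          = c(TRUE, FALSE, FALSE),
    ventana_only      = c(FALSE, TRUE, FALSE),
    tcic_only         = c(FALSE, FALSE, TRUE),
    all_negative      = c(FALSE, FALSE, FALSE))
  m <- do.call(rbind, rep(membership, times = region_counts))
  data.frame(patient_id = sprintf("V%03d", seq_len(nrow(m))),
             cps10 = m[, 1], ventana_ic5 = m[, 2], tcic25 = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact phenotype cross-tabulation fixture (n = 193)
#'
#' Deterministic statuses, phenotype assignments, CD8 densities and sTILs
#' values encoding the published phenotype-coverage and rescue
#' cross-tabulations: Evasion (n = 27) fully captured by CPS10 and TC/IC
#' but missed 13 times by Ventana IC5; InflamedHigh (n = 27) captured
#' 26/27 by Ventana IC5 and TC/IC and 25/27 by CPS10; InflamedLow (n = 67)
#' containing 48 patients PD-L1-negative by at least one algorithm — all
#' 48 CPS10-negative, 46 Ventana-negative, 33 congruently triple-negative
#' — of whom exactly 39 meet CD8 >= 201/mm2 OR sTILs >= 10%; Uninflamed
#' (n = 72) triple-negative. The published per-algorithm negative counts
#' within the 48 are mutually inconsistent as sets (46 + 44 negatives among
#' 48 all-CPS10-negative cases force at least 42 triple-negatives, not 33);
#' this fixture keeps the CPS10, Ventana and triple-negative counts and
#' caps TC/IC-negatives at the feasible 35.
#'
#' @return list with `statuses`, `phenotypes` (both n = 193 data frames),
#'   `cd8` (`patient_id`, `cd8_density`), `stils` (`patient_id`,
#'   `stils_percent`)
#' @export
fixture_crosstab <- function() {
  n_by_phen <- c(Evasion = 27, InflamedHigh = 27, InflamedLow = 67,
                 Uninflamed = 72)
  phen <- rep(names(n_by_phen), n_by_phen)
  n <- length(phen)
  ids <- sprintf("X%03d", seq_len(n))
  cps <- ven <- tci <- rep(NA, n)

  ev <- which(phen == "Evasion")
  cps[ev] <- TRUE; tci[ev] <- TRUE
  ven[ev] <- c(rep(TRUE, 14), rep(FALSE, 13))

  ih <- which(phen == "InflamedHigh")
  cps[ih] <- c(rep(TRUE, 25), FALSE, FALSE)
  ven[ih] <- c(rep(TRUE, 26), FALSE)
  tci[ih] <- c(rep(TRUE, 26), FALSE)

  il <- which(phen == "InflamedLow")
  # first 48: PD-L1 negative by >= 1 algorithm (all CPS10-negative);
  # 1-33 triple-negative, 34-46 Ventana-negative only among {ven, tci},
  # 47-48 TC/IC-negative only; remaining 19 triple-positive
  neg48 <- il[1:48]
  cps[neg48] <- FALSE
  ven[neg48] <- c(rep(FALSE, 46), TRUE, TRUE)
  tci[neg48] <- c(rep(FALSE, 33), rep(TRUE, 13), FALSE, FALSE)
  rest <- il[49:67]
  cps[rest] <- ven[rest] <- tci[rest] <- TRUE

  un <- which(phen == "Uninflamed")
  cps[un] <- ven[un] <- tci[un] <- FALSE

  # CD8/sTILs: exactly 39 of the 48 rescued, exercising both cut-off
  # boundaries; everyone else gets unremarkable mid-range values
  cd8 <- rep(150, n)
  stils <- rep(5, n)
  cd8[neg48[1:30]] <- 320; stils[neg48[1:30]] <- 4      # CD8 arm
  cd8[neg48[31:35]] <- 201; stils[neg48[31:35]] <- 0     # CD8 boundary
  cd8[neg48[36:39]] <- 0; stils[neg48[36:39]] <- 10      # sTILs boundary
  cd8[neg48[40:48]] <- 100; stils[neg48[40:48]] <- 5     # not rescued

  list(statuses = data.frame(patient_id = ids, cps10 = cps,
                             ventana_ic5 = ven, tcic25 = tci,
                             stringsAsFactors = FALSE),
       phenotypes = data.frame(patient_id = ids,
                               phenotype = factor(phen, TIME_PHENOTYPES),
                               stringsAsFactors = FALSE),
       cd8 = data.frame(patient_id = ids, cd8_density = cd8,
                        stringsAsFactors = FALSE),
       stils = data.frame(patient_id = ids, stils_percent = stils,
                          stringsAsFactors = FALSE))
}
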