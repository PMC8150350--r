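# small hand-built cohort tables for io tests
tiny_density_df <- function() {
  expand.grid(patient_id = c("P1", "P2"), core_id = c("IF1", "TC1"),
              marker = c("CD8", "CD3"), stringsAsFactors = FALSE) |>
    transform(region = ifelse(core_id == "IF1", "invasion_front",
                              "tumor_center"),
              density = c(100, 300, 50, 150, 200, 250, 20, 40),
              qc_pass = TRUE)
}

tiny_assay_df <- function() {
  expand.grid(patient_id = c("P1", "P2"), assay = c("SP142", "SP263"),
              stringsAsFactors = FALSE) |>
    transform(ic_percent = c(5, 10, 6, 12), tc_percent = c(0, 1, 30, 40),
              cps = c(5, 12, 35, 45))
}

tiny_annotation_df <- function() {
  data.frame(patient_id = c("P1", "P2"), stils_percent = c(10, 40),
             dss_time = c(24, 60), dss_event = c(TRUE, FALSE),
             dfs_time = c(20, 60), dfs_event = c(TRUE, FALSE),
             pT = "pT2", pN = "pN0", L = "L0", age = c(65, 72),
             gender = c("male", "female"), margin = "R0",
             adj_chemo = c(TRUE, FALSE), grade = "G3",
             stringsAsFactors = FALSE)
}

write_tiny_csvs <- function(dir, densities = tiny_density_df(),
                            assays = tiny_assay_df(),
                            annotations = tiny_annotation_df()) {
  paths <- file.path(dir, c("densities.csv", "assays.csv",
                            "annotations.csv"))
  utils::write.csv(densities, paths[1], row.names = FALSE)
  utils::write.csv(assays, paths[2], row.names = FALSE)
  utils::write.csv(annotations, paths[3], row.names = FALSE)
  paths
}
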