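#' Re-run the confirmatory analyses on a deposited study dataset
#'
#' Convenience wrapper for validating the package against the original
#' study export once it is available locally (it is distributed through the
#' journal as a supplementary XLSX and is not bundled here). Expects the
#' deposited layout: first column the global unique identifier, followed by
#' the 17 map-input CDEs, GOS-E at 3/6 months and the SNP columns; supply
#' `name_map` to translate the export's column headers to the canonical
#' names of [default_variable_specs()].
#'
#' Returns the quantities usually checked first against such a cohort:
#' per-variable descriptive statistics, the PARP1 GLM inclusion counts, the
#' Type III factorial tables on the 3-month, 6-month and change scores, the
#' CT-stratified models, and the Tukey-Kramer change-score comparisons.
#'
#' @param table_path Path to the deposited cohort table (XLSX or CSV).
#' @param name_map Optional `c(source = canonical)` column renaming.
#' @param snp SNP to test (default `"PARP1"`).
#' @param genotype_labels Labels for genotype codes 1:3.
#' @return List with `cohort`, `descriptives`, `glm_dataset`, `report`.
#' @export
reproduce_study_analysis <- function(table_path, name_map = NULL,
                                     snp = "PARP1",
                                     genotype_labels = c("A/A", "A/T", "T/T")) {
  cohort <- load_cohort(table_path, name_map = name_map)
  ds <- build_glm_dataset(cohort, snp, genotype_labels = genotype_labels)
  list(cohort = cohort,
       descriptives = summarize_variables(cohort),
       glm_dataset = ds,
       report = repeated_measures_suite(ds))
}
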