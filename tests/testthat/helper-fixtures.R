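# Fixtures and independent oracles shared across the test files.

# A complete 17-CDE toy table for n patients (no missing values).
toy_cde_table <- function(n = 3, seed = 99) {
  set.seed(seed)
  df <- data.frame(patient_id = sprintf("T%02d", seq_len(n)))
  for (v in c("ct_pathology", "skull_fracture", "skull_base_fracture",
              "facial_fracture", "epidural_hematoma", "subdural_hematoma",
              "subarachnoid_hemorrhage", "contusion", "midline_shift",
              "cisternal_compression", "ptsd_dx"))
    df[[v]] <- sample(0:1, n, replace = TRUE)
  df$marshall <- sample(1:6, n, replace = TRUE)
  df$rotterdam <- sample(1:6, n, replace = TRUE)
  df$pcl <- round(runif(n, 17, 85), 1)
  df$wais_psi <- round(runif(n, 60, 140), 1)
  df$cvlt_sdcr <- round(runif(n, -3, 2), 2)
  df$cvlt_ldcr <- round(runif(n, -3, 2), 2)
  df
}

# Eq-style product-moment correlation written independently of the package
# (raw sums), used as the nested-loop oracle for the metric stage.
oracle_r <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_norm_corr_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    d[i, j] <- 1 - oracle_r(m[i, ], m[j, ])
  d
}

# Brute-force two-sample KS statistic: maximum ECDF gap over all data points.
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}

# Closed-form chi-square statistic sum (O - E)^2 / E of a contingency table.
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Hand-built subgroup_selection (patient-level, bypassing the graph).
manual_selection <- function(member_ids, complement_ids) {
  structure(list(node_ids = integer(0), member_ids = member_ids,
                 complement_ids = complement_ids),
            class = "subgroup_selection")
}

# Hand-built glm_dataset from a plain data frame.
manual_glm_dataset <- function(dat, snp = "toy") {
  structure(list(data = dat, snp = snp,
                 exclusions = dat[0, "patient_id", drop = FALSE],
                 cell_counts = table(dat$genotype, dat$ct)),
            class = "glm_dataset")
}

# One full syndromic-map run over a synthetic cohort; returns the pieces the
# recovery/enrichment checks need.
run_map_pipeline <- function(config) {
  cohort <- generate_cohort(config)
  d <- pairwise_distances(standardize_columns(cohort))
  lens <- suppressWarnings(optimize_lens(d))
  graph <- build_graph(lens, d, cohort)
  list(cohort = cohort, distance = d, lens = lens, graph = graph,
       truth = truth_labels(cohort))
}

# Subgroup selection + enrichment panel with the default low-recovery
# predicate; NULL when no node qualifies.
select_and_enrich <- function(run) {
  sel <- tryCatch(
    select_subgroup(run$graph, "gose_6m < 5 & ct_pathology == 0"),
    error = function(e) NULL)
  if (is.null(sel)) return(NULL)
  list(selection = sel, panel = enrichment_panel(sel, run$cohort))
}
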