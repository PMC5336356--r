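test_that("subgroup selection assigns overlap patients to the subgroup", {
  run <- run_map_pipeline(simulation_config(n_patients = 200, seed = 25))
  sel <- select_subgroup(run$graph, "ct_pathology == 0")
  expect_length(intersect(sel$member_ids, sel$complement_ids), 0)
  expect_setequal(c(sel$member_ids, sel$complement_ids),
                  run$cohort$data$patient_id)
  # complementary predicates pick disjoint node sets
  sel_hi <- select_subgroup(run$graph, "ct_pathology > 0.5")
  sel_lo <- select_subgroup(run$graph, "ct_pathology <= 0.5")
  expect_length(intersect(sel_hi$node_ids, sel_lo$node_ids), 0)
  # a configurable comparison set restricts the complement
  sel_cmp <- select_subgroup(run$graph, "gose_6m < 5 & ct_pathology == 0",
                             comparison = "ct_pathology == 0")
  expect_true(length(sel_cmp$complement_ids) <
                length(select_subgroup(run$graph,
                  "gose_6m < 5 & ct_pathology == 0")$complement_ids))

  expect_error(select_subgroup(run$graph, "gose_6m < -1"), "empty selection")
  expect_error(select_subgroup(run$graph,
                               node_ids = run$graph$node_table$node_id),
               "empty complement")
  expect_error(select_subgroup(run$graph, "nonexistent_var > 1"),
               "unknown node statistic")
})

test_that("KS enrichment matches the ECDF-gap oracle and its edge cases", {
  specs <- default_variable_specs()
  ids <- sprintf("K%03d", 1:90)
  set.seed(33)
  # identical distributions: statistic 0, p 1
  df <- data.frame(patient_id = ids, pcl = rep(c(20, 30, 40), 30))
  co <- cohort_table(df, specs)
  r0 <- ks_enrichment(manual_selection(ids[1:9], ids[10:90]), co, "pcl")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # full separation: statistic 1
  df$pcl <- c(rep(18, 10), rep(60, 80))
  co <- cohort_table(df, specs)
  r1 <- ks_enrichment(manual_selection(ids[1:10], ids[11:90]), co, "pcl")
  expect_equal(r1$statistic, 1)
  # shifted normals: statistic equals the brute-force max ECDF gap
  for (rep in 1:8) {
    x <- rnorm(30) + 1
    y <- rnorm(60)
    df2 <- data.frame(patient_id = ids, pcl = pmin(pmax(c(x, y) * 5 + 40,
                                                        17), 85))
    co2 <- cohort_table(df2, specs)
    sel <- manual_selection(ids[1:30], ids[31:90])
    r <- ks_enrichment(sel, co2, "pcl")
    expect_equal(r$statistic,
                 oracle_ks_stat(df2$pcl[1:30], df2$pcl[31:90]),
                 tolerance = 1e-12)
  }
  # too little data: untestable, excluded from the BH family
  df$pcl[3:90] <- NA
  co <- cohort_table(df, specs)
  r2 <- ks_enrichment(manual_selection(ids[1:10], ids[11:90]), co, "pcl")
  expect_false(r2$testable)
  expect_true(is.na(adjust_bh(list(r2))[[1]]$q_value))
})

test_that("genotype enrichment reproduces the closed-form chi-square", {
  specs <- default_variable_specs()
  # counts in the style of a mapped subgroup vs the genotyped remainder
  sub_counts <- c(9, 9, 6)
  comp_counts <- c(58, 107, 109)
  geno <- c(rep(1:3, sub_counts), rep(1:3, comp_counts))
  ids <- sprintf("G%03d", seq_along(geno))
  co <- cohort_table(data.frame(patient_id = ids, PARP1 = geno), specs)
  sel <- manual_selection(ids[1:sum(sub_counts)], ids[-(1:sum(sub_counts))])
  r <- categorical_enrichment(sel, co, "PARP1")
  expect_equal(r$test, "chi-square")
  expect_equal(r$statistic,
               oracle_chisq_stat(rbind(sub_counts, comp_counts)),
               tolerance = 1e-12)
  expect_equal(unname(r$detail$contingency["subgroup", ]), sub_counts,
               ignore_attr = TRUE)
  # identical proportions: statistic 0
  geno2 <- rep(rep(1:3, c(2, 3, 5)), 10)
  ids2 <- sprintf("H%03d", 1:100)
  co2 <- cohort_table(data.frame(patient_id = ids2, PARP1 = geno2), specs)
  r2 <- categorical_enrichment(manual_selection(ids2[1:10], ids2[11:100]),
                               co2, "PARP1")
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  # two observed categories: Fisher's exact test takes over
  co3 <- cohort_table(data.frame(patient_id = ids2,
                                 ptsd_dx = rep(c(0, 1), 50)), specs)
  r3 <- categorical_enrichment(manual_selection(ids2[1:10], ids2[11:100]),
                               co3, "ptsd_dx")
  expect_equal(r3$test, "Fisher")
  # constant variable: untestable
  co4 <- cohort_table(data.frame(patient_id = ids2, PARP1 = rep(2, 100)),
                      specs)
  r4 <- categorical_enrichment(manual_selection(ids2[1:10], ids2[11:100]),
                               co4, "PARP1")
  expect_false(r4$testable)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  mk <- function(p) lapply(p, function(pi)
    syndromap:::enrichment_row("v", "KS", 0.1, pi, list()))
  expect_equal(adjust_bh(mk(0.03))[[1]]$q_value, 0.03)
  q <- vapply(adjust_bh(mk(c(0.01, 0.02, 0.03, 0.04))),
              function(r) r$q_value, numeric(1))
  expect_equal(q, rep(0.04, 4))
  expect_true(all(vapply(adjust_bh(mk(rep(1, 5))),
                         function(r) r$q_value, numeric(1)) == 1))
  # q >= p within the family
  set.seed(5)
  p <- runif(10)
  q2 <- vapply(adjust_bh(mk(p)), function(r) r$q_value, numeric(1))
  expect_true(all(q2 >= p - 1e-12))
})

test_that("genotype false-positive rate is controlled under the null", {
  # selections of CT-negative patients with no genotype effect: the planted
  # SNP's q-value should rarely clear 0.05
  cfg <- simulation_config(n_patients = 586, seed = 1,
                           planted_subgroup = list(fraction = 0.2,
                                                   decrement = 3.5,
                                                   ptsd_prob = 1, het_or = 1,
                                                   snp = "PARP1"))
  hits <- 0
  n_sims <- 200
  set.seed(77)
  for (s in seq_len(n_sims)) {
    cfg$seed <- 1000 + s
    co <- generate_cohort(cfg)
    ids <- co$data$patient_id
    pick <- sample(which(co$data$ct_pathology == 0), 60)
    sel <- manual_selection(ids[pick], ids[-pick])
    panel <- enrichment_panel(sel, co, continuous = character(0))
    if (any(panel$q_value < 0.05, na.rm = TRUE)) hits <- hits + 1
  }
  expect_lte(hits / n_sims, 0.07)
})
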