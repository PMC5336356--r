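toy_glm_data <- function(n, seed = 1, geno_probs = c(1, 1, 1) / 3) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("x%03d", seq_len(n)),
    ct = factor(sample(c("CT-", "CT+"), n, TRUE), levels = c("CT-", "CT+")),
    genotype = factor(sample(c("A/A", "A/T", "T/T"), n, TRUE, geno_probs)),
    change = rnorm(n), gose_3m = rnorm(n, 6), gose_6m = rnorm(n, 6.5))
}

test_that("listwise inclusion logs exclusions and keeps complete rows", {
  specs <- default_variable_specs()
  df <- data.frame(patient_id = sprintf("p%d", 1:5),
                   gose_3m = c(5, 6, 7, 8, 4), gose_6m = c(6, NA, 7, 8, 5),
                   ct_pathology = c(0, 0, 1, 1, 0), PARP1 = c(1, 2, 3, 2, 1))
  ds <- build_glm_dataset(cohort_table(df, specs), "PARP1")
  expect_equal(nrow(ds$data), 4)
  expect_equal(ds$exclusions$patient_id, "p2")
  expect_match(ds$exclusions$reason, "gose_6m")
  expect_equal(ds$data$change, c(1, 0, 0, 1))

  co <- generate_cohort(simulation_config(n_patients = 400, seed = 30))
  ds2 <- build_glm_dataset(co, "PARP1")
  brute <- sum(!is.na(co$data$gose_3m) & !is.na(co$data$gose_6m) &
                 !is.na(co$data$ct_pathology) & !is.na(co$data$PARP1))
  expect_equal(nrow(ds2$data), brute)
})

test_that("the balanced one-factor toy reproduces the hand-computed F", {
  dat <- data.frame(genotype = factor(rep(c("a", "b"), each = 3)),
                    y = c(1, 2, 3, 4, 5, 6))
  tab <- anova_type3(dat, response = "y", factors = "genotype")
  expect_equal(tab$F[tab$source == "genotype"], 13.5, tolerance = 1e-12)
  expect_equal(tab$SS[tab$source == "genotype"], 13.5, tolerance = 1e-12)
  expect_equal(tab$df, c(1, 4))
})

test_that("identical responses give zero F throughout", {
  dat <- expand.grid(ct = c("CT-", "CT+"),
                     genotype = c("A/A", "A/T", "T/T"), rep = 1:3)
  dat$change <- 2
  tab <- anova_type3(dat, response = "change", factors = c("ct", "genotype"))
  expect_true(all(tab$F[tab$source != "Residuals"] == 0))
})

test_that("Type III SS on unbalanced designs matches the regression oracle", {
  for (seed in 1:5) {
    dat <- toy_glm_data(24 + seed, seed = seed, geno_probs = c(0.5, 0.3, 0.2))
    if (any(table(dat$ct, dat$genotype) == 0)) next
    tab <- anova_type3(dat, response = "change", factors = c("ct", "genotype"))
    m <- lm(change ~ ct * genotype, dat,
            contrasts = list(ct = "contr.sum", genotype = "contr.sum"))
    oracle <- car::Anova(m, type = 3)
    for (term in c("ct", "genotype", "ct:genotype")) {
      expect_equal(tab$SS[tab$source == term], oracle[term, "Sum Sq"],
                   tolerance = 1e-8, label = paste("SS", term, "seed", seed))
      expect_equal(tab$F[tab$source == term], oracle[term, "F value"],
                   tolerance = 1e-8, label = paste("F", term, "seed", seed))
    }
  }
})

test_that("Type III SS is invariant to level relabeling and row order", {
  dat <- toy_glm_data(40, seed = 6)
  tab1 <- anova_type3(dat, response = "change", factors = c("ct", "genotype"))
  dat2 <- dat[sample(nrow(dat)), ]
  dat2$genotype <- factor(dat2$genotype,
                          levels = c("T/T", "A/A", "A/T"),
                          labels = c("zz", "aa", "mm"))
  tab2 <- anova_type3(dat2, response = "change", factors = c("ct", "genotype"))
  expect_equal(tab1$SS, tab2$SS, tolerance = 1e-10)
})

test_that("balanced designs collapse Type III onto sequential SS", {
  set.seed(7)
  dat <- expand.grid(ct = c("CT-", "CT+"), genotype = c("A/A", "A/T", "T/T"),
                     rep = 1:4)
  dat$change <- rnorm(nrow(dat))
  tab <- anova_type3(dat, response = "change", factors = c("ct", "genotype"))
  seq_tab <- anova(lm(change ~ ct * genotype, dat))
  for (term in c("ct", "genotype", "ct:genotype"))
    expect_equal(tab$SS[tab$source == term], seq_tab[term, "Sum Sq"],
                 tolerance = 1e-10)
})

test_that("change-score effects equal the repeated-measures oracle", {
  for (seed in 1:4) {
    dat <- toy_glm_data(36, seed = 40 + seed)
    dat$change <- dat$gose_6m - dat$gose_3m
    if (any(table(dat$ct, dat$genotype) == 0)) next
    tab <- anova_type3(dat, response = "change", factors = c("ct", "genotype"))
    mlm <- lm(cbind(gose_3m, gose_6m) ~ ct * genotype, dat,
              contrasts = list(ct = "contr.sum", genotype = "contr.sum"))
    idata <- data.frame(time = factor(c("3m", "6m")))
    rm_tab <- summary(suppressWarnings(
      car::Anova(mlm, idata = idata, idesign = ~time, type = 3)),
      multivariate = FALSE)$univariate.tests
    expect_equal(tab$F[tab$source == "ct:genotype"],
                 unname(rm_tab["ct:genotype:time", "F value"]),
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$source == "genotype"],
                 unname(rm_tab["genotype:time", "F value"]),
                 tolerance = 1e-8)
  }
})

test_that("a genotype shift common to both timepoints cancels in change", {
  set.seed(9)
  dat <- toy_glm_data(30, seed = 9)
  eff <- c("A/A" = 0, "A/T" = 1, "T/T" = 2)[as.character(dat$genotype)]
  dat$gose_3m <- sample(4:7, 30, replace = TRUE) + eff  # integer scores
  dat$gose_6m <- dat$gose_3m + 1
  dat$change <- dat$gose_6m - dat$gose_3m
  tab <- anova_type3(dat, response = "change", factors = "genotype")
  expect_equal(tab$F[tab$source == "genotype"], 0, tolerance = 1e-12)
})

test_that("empty design cells and degenerate factors are reported", {
  dat <- toy_glm_data(20, seed = 10)
  dat$genotype[dat$ct == "CT+"] <- "A/A"
  dat <- droplevels(dat)
  expect_error(anova_type3(dat, response = "change",
                           factors = c("ct", "genotype")), "empty design cell")
})

test_that("Tukey-Kramer comparisons match TukeyHSD and its limits", {
  # identical groups: adjusted p = 1
  dat <- data.frame(patient_id = sprintf("i%d", 1:8),
                    ct = factor(rep("CT-", 8), levels = c("CT-", "CT+")),
                    genotype = factor(rep(c("A/A", "A/T"), each = 4)),
                    change = rep(c(1, 2, 3, 4), 2))
  ds <- manual_glm_dataset(dat)
  tk <- tukey_posthoc(ds, "change", "CT-")
  expect_equal(tk$p_adjusted, 1)

  # balanced 3 groups vs stats::TukeyHSD
  set.seed(11)
  dat2 <- data.frame(patient_id = sprintf("j%d", 1:18),
                     ct = factor(rep("CT-", 18), levels = c("CT-", "CT+")),
                     genotype = factor(rep(c("A/A", "A/T", "T/T"), each = 6)),
                     change = rnorm(18) + rep(c(0, 0.5, 1.5), each = 6))
  tk2 <- tukey_posthoc(manual_glm_dataset(dat2), "change", "CT-")
  hsd <- TukeyHSD(aov(change ~ genotype, dat2))$genotype
  expect_equal(sort(tk2$p_adjusted), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-8)

  # single group: error
  dat3 <- dat; dat3$genotype <- factor("A/A")
  expect_error(tukey_posthoc(manual_glm_dataset(dat3), "change", "CT-"),
               "at least 2")
})

test_that("the full report carries overall, stratified and posthoc tables", {
  co <- generate_cohort(simulation_config(seed = 31))
  rep <- repeated_measures_suite(build_glm_dataset(co, "PARP1"))
  expect_named(rep$overall, c("gose_3m", "gose_6m", "change"))
  expect_named(rep$strata, c("CT-", "CT+"))
  expect_true(all(c("pair", "p_adjusted") %in% names(rep$tukey$all)))
  tab <- rep$overall$change
  expect_true(all(tab$SS >= 0))
  expect_equal(tab$MS, tab$SS / tab$df, tolerance = 1e-12)
  expect_true(all(tab$p[!is.na(tab$p)] >= 0 & tab$p[!is.na(tab$p)] <= 1))
  # the planted CT-negative deficit drives the change-score interaction
  expect_lt(tab$p[tab$source == "ct:genotype"], 0.05)
  dir <- withr::local_tempdir()
  files <- write_anova_report(rep, dir)
  expect_true(all(file.exists(files)))
})
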