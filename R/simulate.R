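#' Configuration for the synthetic TBI cohort generator
#'
#' Defaults emulate the marginal structure of the published multicenter
#' cohort: 586 patients, a CT-positive latent class prevalence of 0.44, the
#' reported CT-finding rates, 6-month neuropsychological outcome means/SDs,
#' missingness concentrated in the 6-month variables, and genotype
#' frequencies for six 3-level SNP columns. A plantable subgroup of
#' CT-negative, PTSD-positive patients with a 6-month GOS-E decrement and a
#' heterozygote-enriched genotype provides ground truth for recovery tests.
#'
#' @param n_patients Cohort size.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   byte-identical cohort.
#' @param severity_prevalence Probability of the CT-positive latent class.
#' @param binary_rates Named marginal rates for the 10 binary CT findings
#'   (`ct_pathology` is the class indicator itself).
#' @param outcome_means_sds Named list of `c(mean, sd)` for the continuous
#'   6-month measures (`pcl`, `wais_psi`, `cvlt_sdcr`, `cvlt_ldcr`).
#' @param ptsd_rate Target marginal PTSD diagnosis rate among patients with
#'   an observed 6-month assessment.
#' @param missing_rates Named missingness probabilities; nonzero only for
#'   6-month variables by default.
#' @param genotype_freqs Named list of length-3 genotype frequency vectors
#'   (homozygote-1, heterozygote, homozygote-2), each summing to 1.
#' @param planted_subgroup List with elements `fraction` (share of
#'   CT-negative patients planted), `decrement` (latent GOS-E points lost
#'   between 3 and 6 months instead of the default +0.5 improvement),
#'   `ptsd_prob` (probability a planted member carries a PTSD diagnosis),
#'   `het_or` (heterozygote enrichment odds ratio for `snp`), and `snp`.
#' @return A `simulation_config` object (a validated list).
#' @export
simulation_config <- function(
  n_patients = 586,
  seed = 1,
  severity_prevalence = 0.44,
  binary_rates = c(
    skull_fracture = 0.22, skull_base_fracture = 0.11, facial_fracture = 0.17,
    epidural_hematoma = 0.05, subdural_hematoma = 0.26,
    subarachnoid_hemorrhage = 0.26, contusion = 0.24,
    midline_shift = 0.07, cisternal_compression = 0.12),
  outcome_means_sds = list(
    pcl = c(32.98, 14.80), wais_psi = c(99.20, 15.96),
    cvlt_sdcr = c(-0.08, 1.14), cvlt_ldcr = c(-0.19, 1.17)),
  ptsd_rate = 0.24,
  missing_rates = c(
    ptsd_dx = 248 / 586, pcl = 248 / 586, wais_psi = 281 / 586,
    cvlt_sdcr = 290 / 586, cvlt_ldcr = 291 / 586),
  genotype_freqs = list(
    PARP1            = c(67, 116, 115) / 298,
    ANKK1_rs1800497  = c(0.46, 0.43, 0.11),
    ANKK1_rs4938016  = c(0.42, 0.46, 0.12),
    ANKK1_rs11604671 = c(0.30, 0.50, 0.20),
    COMT_rs4680      = c(0.25, 0.50, 0.25),
    DRD2_rs6277      = c(0.30, 0.50, 0.20)),
  planted_subgroup = list(fraction = 0.20, decrement = 3.5, ptsd_prob = 1.0,
                          het_or = 4.0, snp = "PARP1")
) {
  cfg <- list(n_patients = n_patients, seed = seed,
              severity_prevalence = severity_prevalence,
              binary_rates = binary_rates,
              outcome_means_sds = outcome_means_sds,
              ptsd_rate = ptsd_rate,
              missing_rates = missing_rates,
              genotype_freqs = genotype_freqs,
              planted_subgroup = planted_subgroup)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2, cfg$seed == round(cfg$seed))
  probs <- c(cfg$severity_prevalence, cfg$binary_rates, cfg$ptsd_rate,
             cfg$missing_rates, cfg$planted_subgroup$ptsd_prob)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  for (snp in names(cfg$genotype_freqs)) {
    f <- cfg$genotype_freqs[[snp]]
    if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop("genotype frequencies for ", snp,
           " must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  pl <- cfg$planted_subgroup
  if (pl$fraction < 0 || pl$fraction > 1)
    stop("planted fraction must lie within the CT-negative class ",
         "(a proportion in [0, 1])", call. = FALSE)
  if (pl$het_or <= 0) stop("heterozygote odds ratio must be positive",
                           call. = FALSE)
  if (!pl$snp %in% names(cfg$genotype_freqs))
    stop("planted SNP '", pl$snp, "' has no configured genotype frequencies",
         call. = FALSE)
  invisible(cfg)
}

# intercept a such that E[plogis(a + slope * s)] = target for s ~ N(0,1)
# restricted to s > lower (lower = -Inf for the whole population)
logistic_intercept <- function(target, slope, lower = -Inf) {
  target <- min(max(target, 1e-6), 1 - 1e-6)
  mass <- stats::pnorm(lower, lower.tail = FALSE)
  f <- function(a) {
    stats::integrate(function(s) stats::plogis(a + slope * s) * stats::dnorm(s),
                     lower, Inf, rel.tol = 1e-10)$value / mass - target
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# assign ordinal categories to scores so that category proportions match pmf
# exactly (up to integer rounding); ties broken by stable order
quantile_assign <- function(scores, categories, pmf) {
  n <- length(scores)
  counts <- diff(round(cumsum(c(0, pmf)) * n))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  out <- rep(categories[1], n)
  out[order(scores)] <- rep(categories, counts)
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic TBI cohort
#'
#' A single latent severity factor per patient drives the CT-positive class,
#' correlated binary CT findings (logistic links calibrated by numerical
#' integration so that marginal rates match the configured targets),
#' Marshall/Rotterdam CT grades, PTSD risk, cognitive scores and GOS-E
#' recovery. Planted subgroup members are CT-negative, PTSD-positive with
#' high PCL symptom scores, lose GOS-E points between 3 and 6 months, and
#' draw their planted SNP with heterozygote-enriched odds. Missingness is
#' applied only where the configured rates are nonzero (the 6-month
#' variables by default), as patient-level loss to follow-up plus
#' instrument-specific attrition; planted members keep complete 6-month data
#' since the subgroup emulates patients observed at follow-up. Background
#' marginals are compensated for the planted shift so that cohort-level
#' rates stay at their configured values.
#'
#' @param config A [simulation_config()].
#' @return A [cohort_table()] carrying generator ground truth (see
#'   [truth_labels()]).
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  n <- config$n_patients
  prev <- config$severity_prevalence
  pl <- config$planted_subgroup
  set.seed(config$seed)

  s <- stats::rnorm(n)                       # latent severity
  tau <- stats::qnorm(1 - prev)
  ct <- as.integer(s > tau)
  ct_neg <- which(ct == 0L)
  n_planted <- floor(pl$fraction * length(ct_neg))
  planted <- rep(FALSE, n)
  if (n_planted > 0) planted[sample(ct_neg, n_planted)] <- TRUE

  # --- binary CT findings: zero in the CT-negative class, logistic in s above
  findings <- lapply(names(config$binary_rates), function(v) {
    p_marg <- config$binary_rates[[v]]
    p_cond <- min(p_marg / max(prev, 1e-9), 0.999)
    a <- logistic_intercept(p_cond, slope = 1, lower = tau)
    as.integer(ct == 1L & stats::runif(n) < stats::plogis(a + s))
  })
  names(findings) <- names(config$binary_rates)

  # --- CT severity grades: quantile-mapped within the CT-positive class;
  # the class pmfs imply overall moments near Marshall 1.76/1.10 and
  # Rotterdam 2.45/0.83
  marshall <- rep(1, n)
  rotterdam <- rep(2, n)
  if (sum(ct) >= 1) {
    idx <- which(ct == 1L)
    sc1 <- 0.8 * s[idx] + 0.6 * stats::rnorm(length(idx))
    marshall[idx] <- quantile_assign(sc1, 2:6, c(0.60, 0.22, 0.10, 0.05, 0.03))
    sc2 <- 0.8 * s[idx] + 0.6 * stats::rnorm(length(idx))
    rotterdam[idx] <- quantile_assign(sc2, 2:6, c(0.40, 0.35, 0.15, 0.07, 0.03))
  }

  # --- expected planted share among patients observed at 6 months, used to
  # compensate background marginals so cohort-level targets stay honest
  miss <- config$missing_rates
  core_missing <- if (any(miss > 0)) min(miss[miss > 0]) else 0
  exp_planted <- pl$fraction * (1 - prev) * n
  exp_obs <- exp_planted + (n - exp_planted) * (1 - core_missing)
  w_pl <- exp_planted / exp_obs

  ptsd_bg_target <- (config$ptsd_rate - w_pl * pl$ptsd_prob) / (1 - w_pl)
  ptsd_bg_target <- min(max(ptsd_bg_target, 0.001), 0.999)
  a_ptsd <- logistic_intercept(ptsd_bg_target, slope = 1.5)
  ptsd <- as.integer(stats::runif(n) < stats::plogis(a_ptsd + 1.5 * s))
  ptsd[planted] <- as.integer(stats::runif(sum(planted)) < pl$ptsd_prob)

  # --- PCL symptom score: PTSD-linked mixture of floor-anchored gamma
  # components (the checklist minimum is 17, and asymptomatic patients pile
  # up near it); component moments are set so the cohort-level mean/SD land
  # on their configured targets, with planted members scoring high
  pcl_pars <- config$outcome_means_sds$pcl
  planted_pcl_mean <- 60
  planted_pcl_sd <- 6
  pcl_bg_target <- (pcl_pars[1] - w_pl * planted_pcl_mean) / max(1 - w_pl, 1e-9)
  # cohort-level mean/SD targets include the planted high-PCL slice, so the
  # background variance absorbs the planted between-group spread
  v_bg <- (pcl_pars[2]^2 - w_pl * planted_pcl_sd^2 -
             w_pl * (planted_pcl_mean - pcl_pars[1])^2 -
             (1 - w_pl) * (pcl_bg_target - pcl_pars[1])^2) / max(1 - w_pl, 1e-9)
  delta <- 18                                # PTSD-positive symptom shift
  between_var <- delta^2 * ptsd_bg_target * (1 - ptsd_bg_target)
  comp_sd <- sqrt(max(v_bg - between_var, 16))
  comp_mu <- pmax(pcl_bg_target - delta * ptsd_bg_target + delta * ptsd - 17,
                  0.5)
  shape <- (comp_mu / comp_sd)^2
  pcl <- 17 + stats::rgamma(n, shape = shape, scale = comp_sd^2 / comp_mu)
  pcl[planted] <- planted_pcl_mean + planted_pcl_sd * stats::rnorm(sum(planted))
  pcl <- clip(pcl, 17, 85)

  # --- cognition: loads negatively on severity; CVLT scores share a memory factor
  wa <- config$outcome_means_sds$wais_psi
  wais <- clip(wa[1] + wa[2] * (-0.35 * s + sqrt(1 - 0.35^2) * stats::rnorm(n)),
               50, 150)
  mem <- stats::rnorm(n)
  cvlt_load <- function(pars, lo, hi) {
    e <- stats::rnorm(n)
    clip(pars[1] + pars[2] * (-0.35 * s + 0.6 * mem +
                                sqrt(1 - 0.35^2 - 0.36) * e), lo, hi)
  }
  cvlt1 <- cvlt_load(config$outcome_means_sds$cvlt_sdcr, -4, 2.5)
  cvlt2 <- cvlt_load(config$outcome_means_sds$cvlt_ldcr, -3.5, 2.5)

  # --- GOS-E: ordinal via rounded latent; +0.5 latent improvement by 6 months
  # except planted members, who lose `decrement` points
  g3_lat <- 6.5 - 0.8 * s + 0.8 * stats::rnorm(n)
  gose3 <- clip(round(g3_lat), 1, 8)
  change <- 0.5 + 0.5 * stats::rnorm(n)
  change[planted] <- -pl$decrement + 0.5 * stats::rnorm(sum(planted))
  gose6 <- clip(round(g3_lat + change), 1, 8)

  # --- genotypes: independent SNPs; planted SNP heterozygote-boosted
  genos <- lapply(names(config$genotype_freqs), function(snp) {
    f <- config$genotype_freqs[[snp]]
    g <- sample.int(3, n, replace = TRUE, prob = f)
    if (snp == pl$snp && any(planted) && pl$het_or != 1) {
      p2 <- pl$het_or * f[2] / (f[1] + f[3] + pl$het_or * f[2])
      fp <- c(f[1] * (1 - p2) / (f[1] + f[3]), p2,
              f[3] * (1 - p2) / (f[1] + f[3]))
      g[planted] <- sample.int(3, sum(planted), replace = TRUE, prob = fp)
    }
    g
  })
  names(genos) <- names(config$genotype_freqs)

  # --- missingness: follow-up loss hits all 6-month instruments together,
  # instrument-specific attrition on top; planted members stay complete
  lost <- stats::runif(n) < core_missing
  lost[planted] <- FALSE
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   ct_pathology = ct, stringsAsFactors = FALSE)
  for (v in names(findings)) df[[v]] <- findings[[v]]
  df$marshall <- marshall
  df$rotterdam <- rotterdam
  df$ptsd_dx <- ptsd
  df$pcl <- pcl
  df$wais_psi <- wais
  df$cvlt_sdcr <- cvlt1
  df$cvlt_ldcr <- cvlt2
  df$gose_3m <- gose3
  df$gose_6m <- gose6
  for (snp in names(genos)) df[[snp]] <- genos[[snp]]
  for (v in names(miss)) {
    if (!v %in% names(df) || miss[[v]] <= 0) next
    extra <- (miss[[v]] - core_missing) / max(1 - core_missing, 1e-9)
    drop <- lost | (stats::runif(n) < max(extra, 0))
    drop[planted] <- FALSE
    df[[v]][drop] <- NA
  }

  cohort <- cohort_table(df)
  cohort$truth <- data.frame(patient_id = df$patient_id, severity = s,
                             ct_latent = ct == 1L, planted = planted,
                             followup_lost = lost, stringsAsFactors = FALSE)
  cohort$config <- config
  cohort
}

#' Ground-truth generator labels for a synthetic cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Data frame with `patient_id`, latent `severity`, `ct_latent`,
#'   `planted` and `followup_lost` flags.
#' @export
truth_labels <- function(cohort) {
  if (is.null(cohort$truth))
    stop("truth labels are only available for cohorts produced by ",
         "generate_cohort()", call. = FALSE)
  cohort$truth
}
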