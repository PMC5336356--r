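#' Assemble the repeated-measures GLM dataset for one SNP
#'
#' Listwise inclusion of patients with non-missing GOS-E at 3 and 6 months,
#' CT pathology status, and the chosen genotype; the change score is
#' `gose_6m - gose_3m`. Excluded patients are logged with the reason.
#'
#' @param cohort A `cohort_table` with `gose_3m`, `gose_6m`, `ct_pathology`
#'   and the SNP column.
#' @param snp Genotype column name.
#' @param genotype_labels Optional length-3 labels for codes 1:3 (e.g.
#'   `c("A/A", "A/T", "T/T")`).
#' @return A `glm_dataset`: list with `data` (patient_id, gose_3m, gose_6m,
#'   change, ct, genotype), `snp`, `exclusions`, `cell_counts`.
#' @export
build_glm_dataset <- function(cohort, snp, genotype_labels = NULL) {
  need <- c("gose_3m", "gose_6m", "ct_pathology", snp)
  absent <- setdiff(need, names(cohort$data))
  if (length(absent) > 0)
    stop("cohort lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  d <- cohort$data
  miss <- cbind(gose_3m = is.na(d$gose_3m), gose_6m = is.na(d$gose_6m),
                ct = is.na(d$ct_pathology), genotype = is.na(d[[snp]]))
  keep <- rowSums(miss) == 0
  exclusions <- data.frame(
    patient_id = d$patient_id[!keep],
    reason = apply(miss[!keep, , drop = FALSE], 1, function(r)
      paste("missing", paste(colnames(miss)[r], collapse = "+"))),
    stringsAsFactors = FALSE)
  labs <- if (is.null(genotype_labels)) as.character(1:3) else genotype_labels
  dat <- data.frame(
    patient_id = d$patient_id[keep],
    gose_3m = d$gose_3m[keep], gose_6m = d$gose_6m[keep],
    change = d$gose_6m[keep] - d$gose_3m[keep],
    ct = factor(ifelse(d$ct_pathology[keep] > 0, "CT+", "CT-"),
                levels = c("CT-", "CT+")),
    genotype = factor(labs[d[[snp]][keep]], levels = labs),
    stringsAsFactors = FALSE)
  dat$genotype <- droplevels(dat$genotype)
  if (nlevels(dat$ct) < 2 || length(unique(dat$ct)) < 2)
    stop("need both CT-positive and CT-negative patients", call. = FALSE)
  if (length(unique(dat$genotype)) < 2)
    stop("need at least 2 observed genotype groups", call. = FALSE)
  dat$genotype <- droplevels(dat$genotype)
  dat$ct <- droplevels(dat$ct)
  structure(list(data = dat, snp = snp, exclusions = exclusions,
                 cell_counts = table(dat$genotype, dat$ct)),
            class = "glm_dataset")
}

#' @export
print.glm_dataset <- function(x, ...) {
  cat(sprintf("<glm_dataset> %s: %d included, %d excluded\n", x$snp,
              nrow(x$data), nrow(x$exclusions)))
  print(x$cell_counts)
  invisible(x)
}

# Type III sum of squares for one term: residual-SS difference between the
# full sum-to-zero-coded model and the model with that term's columns
# removed (all other terms, including interactions, retained).
type3_term <- function(y, X, assign, term_idx) {
  fit_rss <- function(cols) {
    q <- qr(X[, cols, drop = FALSE])
    sum(qr.resid(q, y)^2)
  }
  full_cols <- seq_len(ncol(X))
  rss_full <- fit_rss(full_cols)
  drop_cols <- which(assign == term_idx)
  rss_red <- fit_rss(setdiff(full_cols, drop_cols))
  list(ss = rss_red - rss_full, df = length(drop_cols), rss_full = rss_full)
}

#' Factorial ANOVA with Type III sums of squares
#'
#' Fits the full factorial between-subjects linear model for the chosen
#' response under sum-to-zero contrasts and computes each term's marginal
#' (each-term-last) sum of squares by model comparison, which is valid under
#' imbalance. `F = MS_term / MS_error`, p from the F distribution.
#'
#' @param dataset A `glm_dataset`, or a data frame holding the response and
#'   factor columns.
#' @param response One of `"gose_3m"`, `"gose_6m"`, `"change"` (for a
#'   `glm_dataset`), or any numeric column of a supplied data frame.
#' @param factors Factor column names (default `c("ct", "genotype")`); the
#'   model is their full factorial.
#' @return Data frame with `source, SS, df, MS, F, p` plus a `Residuals`
#'   row.
#' @export
anova_type3 <- function(dataset, response = c("change", "gose_3m", "gose_6m"),
                        factors = c("ct", "genotype")) {
  dat <- if (inherits(dataset, "glm_dataset")) dataset$data else dataset
  response <- if (inherits(dataset, "glm_dataset")) match.arg(response) else
    response
  y <- dat[[response]]
  for (f in factors) dat[[f]] <- droplevels(as.factor(dat[[f]]))
  if (length(factors) > 1) {
    cells <- table(dat[, factors])
    if (any(cells == 0))
      stop("empty design cell(s); term(s) would be aliased: ",
           paste(names(which(cells == 0)), collapse = ", "), call. = FALSE)
  }
  form <- stats::as.formula(paste("~", paste(factors, collapse = "*")))
  contr <- stats::setNames(
    replicate(length(factors), "contr.sum", simplify = FALSE), factors)
  X <- stats::model.matrix(form, dat, contrasts.arg = contr)
  if (qr(X)$rank < ncol(X)) stop("singular design", call. = FALSE)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  df_res <- nrow(X) - ncol(X)
  rows <- lapply(seq_along(labels), function(ti) {
    t3 <- type3_term(y, X, assign, ti)
    data.frame(source = labels[ti], SS = t3$ss, df = t3$df,
               stringsAsFactors = FALSE)
  })
  rss_full <- sum(qr.resid(qr(X), y)^2)
  tab <- do.call(rbind, rows)
  # sums of squares below fp noise (relative to the response scale) are zero
  ss_tol <- 1e-12 * max(sum(y * y), 1)
  tab$SS[tab$SS < ss_tol] <- 0
  tab$MS <- tab$SS / tab$df
  mse <- rss_full / df_res
  tab$F <- ifelse(tab$MS == 0, 0, tab$MS / mse)  # zero effect stays F = 0
  tab$p <- stats::pf(tab$F, tab$df, df_res, lower.tail = FALSE)
  tab <- rbind(tab, data.frame(source = "Residuals", SS = rss_full,
                               df = df_res, MS = mse, F = NA, p = NA))
  rownames(tab) <- NULL
  tab
}

#' Tukey-Kramer posthoc comparisons between genotype groups
#'
#' All-pairs comparisons of genotype means on the chosen response using the
#' studentized-range distribution; unequal group sizes are handled with the
#' Kramer harmonic form. The error term is the stratum's model MSE: the full
#' `ct * genotype` factorial for `stratum = "all"`, the one-way genotype
#' model within a CT stratum otherwise.
#'
#' @param dataset A `glm_dataset`.
#' @param response `"change"`, `"gose_3m"` or `"gose_6m"`.
#' @param stratum `"all"`, `"CT-"` or `"CT+"`.
#' @return Data frame with `pair, diff, p_adjusted` (and group sizes).
#' @export
tukey_posthoc <- function(dataset, response = c("change", "gose_3m", "gose_6m"),
                          stratum = c("all", "CT-", "CT+")) {
  response <- match.arg(response)
  stratum <- match.arg(stratum)
  dat <- dataset$data
  if (stratum != "all") dat <- dat[dat$ct == stratum, ]
  dat$genotype <- droplevels(dat$genotype)
  groups <- levels(dat$genotype)
  if (length(groups) < 2)
    stop("Tukey comparisons need at least 2 genotype groups", call. = FALSE)
  n_g <- table(dat$genotype)
  if (any(n_g < 2))
    stop("every genotype group needs at least 2 observations", call. = FALSE)
  factors <- if (stratum == "all" && length(unique(dat$ct)) > 1)
    c("ct", "genotype") else "genotype"
  tab <- anova_type3(dat, response = response, factors = factors)
  mse <- tab$MS[tab$source == "Residuals"]
  df_err <- tab$df[tab$source == "Residuals"]
  means <- tapply(dat[[response]], dat$genotype, mean)
  pairs <- utils::combn(groups, 2)
  out <- apply(pairs, 2, function(pr) {
    diff <- means[pr[1]] - means[pr[2]]
    se <- sqrt((mse / 2) * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    q_obs <- abs(diff) / se
    data.frame(pair = paste(pr[1], "vs", pr[2]), diff = unname(diff),
               n1 = as.integer(n_g[pr[1]]), n2 = as.integer(n_g[pr[2]]),
               p_adjusted = stats::ptukey(q_obs, nmeans = length(groups),
                                          df = df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full repeated-measures report for one SNP
#'
#' With two timepoints, the within-subject time-by-factor effects of the
#' repeated-measures factorial are algebraically identical to the
#' between-subjects effects on the 3-to-6-month change score, so the report
#' runs the Type III factorial (`ct * genotype`) on the 3-month score, the
#' 6-month score and the change score, adds genotype-only models within each
#' CT stratum, and Tukey-Kramer posthoc tables for the change score.
#'
#' @param dataset A `glm_dataset`.
#' @return An `anova_report`: list with `overall` (named list of effect
#'   tables per response), `strata` (per CT stratum per response), `tukey`
#'   (overall + per stratum, change score), `counts`, `snp`.
#' @export
repeated_measures_suite <- function(dataset) {
  responses <- c("gose_3m", "gose_6m", "change")
  overall <- lapply(responses, function(r) anova_type3(dataset, r))
  names(overall) <- responses
  strata <- list()
  for (s in c("CT-", "CT+")) {
    sub <- dataset$data[dataset$data$ct == s, ]
    strata[[s]] <- lapply(responses, function(r)
      anova_type3(sub, response = r, factors = "genotype"))
    names(strata[[s]]) <- responses
  }
  tukey <- list(all = tukey_posthoc(dataset, "change", "all"))
  for (s in c("CT-", "CT+"))
    tukey[[s]] <- tryCatch(tukey_posthoc(dataset, "change", s),
                           error = function(e) NULL)
  structure(list(overall = overall, strata = strata, tukey = tukey,
                 counts = dataset$cell_counts, snp = dataset$snp),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, digits = 3, ...) {
  cat(sprintf("<anova_report> %s (N = %d)\n", x$snp, sum(x$counts)))
  for (r in names(x$overall)) {
    cat("\n--", r, "(Type III, ct * genotype) --\n")
    print(x$overall[[r]], digits = digits)
  }
  cat("\n-- Tukey-Kramer, change score, all patients --\n")
  print(x$tukey$all, digits = digits)
  invisible(x)
}

#' Write an ANOVA report as CSV tables
#' @param report An `anova_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_anova_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  for (r in names(report$overall))
    emit(report$overall[[r]], paste0("overall_", r))
  for (s in names(report$strata))
    for (r in names(report$strata[[s]]))
      emit(report$strata[[s]][[r]],
           paste0("stratum_", gsub("[+]", "pos", gsub("-", "neg", s)), "_", r))
  for (s in names(report$tukey))
    if (!is.null(report$tukey[[s]]))
      emit(report$tukey[[s]],
           paste0("tukey_", gsub("[+]", "pos", gsub("-", "neg", s))))
  invisible(written)
}
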