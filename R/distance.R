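#' Standardize the map-input columns of a cohort
#'
#' Builds the patient-by-variable matrix over the 17 map-input CDEs (or any
#' chosen variable set), imputes missing cells, then z-scores each column
#' using the population SD convention (divide by N). Degenerate
#' (zero-variance) columns are set to all-zero and flagged with a warning.
#'
#' @param cohort A `cohort_table` containing the requested variables.
#' @param impute Missing-cell strategy applied before standardization:
#'   `"median"` (default), `"mean"`, or `"none"` (missing cells stay `NA`
#'   and distances fall back to pairwise-complete correlation).
#' @param variables Character vector of columns to use; defaults to the 17
#'   map inputs.
#' @return A `standardized_matrix`: list with `values` (patients x
#'   variables), `impute_mask` (logical matrix of imputed cells),
#'   `column_stats` (per-variable mean/SD used), `patient_ids`.
#' @export
standardize_columns <- function(cohort, impute = c("median", "mean", "none"),
                                variables = tda_variables(cohort$specs)) {
  impute <- match.arg(impute)
  absent <- setdiff(variables, names(cohort$data))
  if (length(absent) > 0)
    stop("variable(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(cohort$data[, variables, drop = FALSE])
  rownames(m) <- cohort$data$patient_id
  mask <- is.na(m)
  degenerate <- character(0)
  stats_tab <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                          stringsAsFactors = FALSE)
  for (j in seq_along(variables)) {
    x <- m[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == 0)
      stop("column '", variables[j], "' is entirely missing", call. = FALSE)
    if (any(is.na(x)) && impute != "none") {
      fill <- if (impute == "median") stats::median(obs) else mean(obs)
      x[is.na(x)] <- fill
    }
    mu <- mean(x, na.rm = TRUE)
    sd_pop <- sqrt(mean((x[!is.na(x)] - mu)^2))    # population convention
    stats_tab$mean[j] <- mu
    stats_tab$sd[j] <- sd_pop
    if (sd_pop < 1e-12) {
      degenerate <- c(degenerate, variables[j])
      m[, j] <- ifelse(is.na(x), NA, 0)
    } else {
      m[, j] <- (x - mu) / sd_pop
    }
  }
  if (length(degenerate) > 0)
    warning("zero-variance column(s) set to 0: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  structure(list(values = m, impute_mask = mask, column_stats = stats_tab,
                 patient_ids = cohort$data$patient_id,
                 degenerate = degenerate),
            class = "standardized_matrix")
}

#' Pearson correlation, product-moment form
#'
#' Direct evaluation of the N-weighted product-moment formula
#' \deqn{r = \frac{N\sum x_i y_i - \sum x_i \sum y_i}
#'   {\sqrt{N\sum x_i^2 - (\sum x_i)^2}\sqrt{N\sum y_i^2 - (\sum y_i)^2}}.}
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 paired values", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  den2x <- n * sum(x^2) - sx^2
  den2y <- n * sum(y^2) - sy^2
  if (den2x <= 0 || den2y <= 0)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  r <- (n * sum(x * y) - sx * sy) / (sqrt(den2x) * sqrt(den2y))
  min(max(r, -1), 1)
}

#' Norm-correlation distance between two standardized patient profiles
#'
#' One minus the Pearson correlation of the two profiles, computed across
#' the standardized variables; 0 for identical profiles, 2 for sign-opposite
#' profiles.
#'
#' @param x_std,y_std Rows of the same `standardized_matrix`.
#' @return Distance in `[0, 2]`.
#' @export
norm_corr <- function(x_std, y_std) 1 - pearson_r(x_std, y_std)

#' All pairwise norm-correlation distances
#'
#' Computes the full symmetric patient-by-patient distance matrix
#' `1 - r(x_i, x_j)` over profile rows of a standardized matrix. Patients
#' whose profile is constant across all variables have undefined
#' correlation: with `degenerate_max = TRUE` (default) their distances are
#' set to the theoretical maximum 2 with a warning, isolating them instead
#' of aborting.
#'
#' @param m A `standardized_matrix` (or plain numeric matrix of profiles).
#' @param degenerate_max Fallback for constant patient profiles.
#' @return A `distance_matrix`: list with `values` (symmetric, zero
#'   diagonal, entries in `[0, 2]`), `metric_name`, `patient_ids`.
#' @export
pairwise_distances <- function(m, degenerate_max = TRUE) {
  vals <- if (inherits(m, "standardized_matrix")) m$values else as.matrix(m)
  ids <- if (inherits(m, "standardized_matrix")) m$patient_ids else
    rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
  if (nrow(vals) < 2) stop("need at least 2 patients", call. = FALSE)
  use <- if (anyNA(vals)) "pairwise.complete.obs" else "everything"
  r <- suppressWarnings(stats::cor(t(vals), use = use))
  d <- 1 - r
  if (anyNA(d)) {
    bad <- unique(ids[rowSums(is.na(d)) > 0])
    if (!degenerate_max)
      stop("undefined correlation for patient pair(s) involving: ",
           paste(bad, collapse = ", "), call. = FALSE)
    warning("constant or non-overlapping profile(s); affected distances set ",
            "to the maximum 2: ", paste(bad, collapse = ", "), call. = FALSE)
    d[is.na(d)] <- 2
  }
  d[d < 0] <- 0
  d[d > 2] <- 2
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(values = d, metric_name = "norm-correlation",
                 patient_ids = ids),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d patients, metric = %s, range [%.3f, %.3f]\n",
              length(x$patient_ids), x$metric_name,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Export a distance matrix as square CSV with id header row/column
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(patient_id = d$patient_ids, d$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
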