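#' Variable dictionary for the default TBI common-data-element set
#'
#' Returns the metadata dictionary describing the variables the pipeline
#' expects: the 17 clinical/imaging/neuropsychological common data elements
#' (CDEs) used to build the syndromic map, the Glasgow Outcome Scale-Extended
#' (GOS-E) at 3 and 6 months, and six 3-level SNP genotype columns.
#'
#' Each row is one variable with:
#' \describe{
#'   \item{name}{column name in the cohort table}
#'   \item{kind}{`"binary"`, `"ordinal"`, `"continuous"` or `"genotype"`}
#'   \item{min,max}{valid range (genotypes are coded 1 = first homozygote,
#'     2 = heterozygote, 3 = second homozygote)}
#'   \item{role}{`"tda-input"` (one of the 17 map variables), `"outcome"`
#'     (GOS-E) or `"genotype"`}
#' }
#'
#' Binary variables are coded 0/1 with 1 = pathology present.
#'
#' @return A data frame with one row per variable.
#' @export
default_variable_specs <- function() {
  spec <- function(name, kind, min, max, role) {
    data.frame(name = name, kind = kind, min = min, max = max, role = role,
               stringsAsFactors = FALSE)
  }
  rbind(
    spec("ct_pathology",          "binary",      0,  1,  "tda-input"),
    spec("skull_fracture",        "binary",      0,  1,  "tda-input"),
    spec("skull_base_fracture",   "binary",      0,  1,  "tda-input"),
    spec("facial_fracture",       "binary",      0,  1,  "tda-input"),
    spec("epidural_hematoma",     "binary",      0,  1,  "tda-input"),
    spec("subdural_hematoma",     "binary",      0,  1,  "tda-input"),
    spec("subarachnoid_hemorrhage", "binary",    0,  1,  "tda-input"),
    spec("contusion",             "binary",      0,  1,  "tda-input"),
    spec("midline_shift",         "binary",      0,  1,  "tda-input"),
    spec("cisternal_compression", "binary",      0,  1,  "tda-input"),
    spec("marshall",              "ordinal",     1,  6,  "tda-input"),
    spec("rotterdam",             "ordinal",     1,  6,  "tda-input"),
    spec("ptsd_dx",               "binary",      0,  1,  "tda-input"),
    spec("pcl",                   "continuous", 17, 85,  "tda-input"),
    spec("wais_psi",              "continuous", 50, 150, "tda-input"),
    spec("cvlt_sdcr",             "continuous", -4,  2.5, "tda-input"),
    spec("cvlt_ldcr",             "continuous", -3.5, 2.5, "tda-input"),
    spec("gose_3m",               "ordinal",     1,  8,  "outcome"),
    spec("gose_6m",               "ordinal",     1,  8,  "outcome"),
    spec("PARP1",                 "genotype",    1,  3,  "genotype"),
    spec("ANKK1_rs1800497",       "genotype",    1,  3,  "genotype"),
    spec("ANKK1_rs4938016",       "genotype",    1,  3,  "genotype"),
    spec("ANKK1_rs11604671",      "genotype",    1,  3,  "genotype"),
    spec("COMT_rs4680",           "genotype",    1,  3,  "genotype"),
    spec("DRD2_rs6277",           "genotype",    1,  3,  "genotype")
  )
}

#' Names of the 17 syndromic-map input variables
#' @param specs A variable dictionary, as from [default_variable_specs()].
#' @return Character vector of `tda-input` variable names.
#' @export
tda_variables <- function(specs = default_variable_specs()) {
  specs$name[specs$role == "tda-input"]
}

validate_specs <- function(specs) {
  needed <- c("name", "kind", "min", "max", "role")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols) > 0)
    stop("metadata dictionary lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(specs$name))
    stop("duplicate variable name(s) in metadata: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "),
         call. = FALSE)
  bad_kind <- setdiff(specs$kind, c("binary", "ordinal", "continuous", "genotype"))
  if (length(bad_kind) > 0)
    stop("unknown variable kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(specs$min)) || any(!is.finite(specs$max)) ||
      any(specs$min >= specs$max))
    stop("every variable needs a non-empty valid range (min < max)", call. = FALSE)
  # genotype columns carry exactly the 3 codes homozygote-1 / het / homozygote-2
  geno <- specs$kind == "genotype"
  if (any(specs$min[geno] != 1 | specs$max[geno] != 3))
    stop("genotype variables must use codes 1 (homozygote), 2 (heterozygote), ",
         "3 (homozygote)", call. = FALSE)
  invisible(specs)
}

#' Construct a validated cohort table
#'
#' A `cohort_table` holds a patient-by-variable data frame (first column
#' `patient_id`), the variable dictionary, and an explicit missing state
#' (`NA`). Values are checked against each variable's valid range.
#'
#' @param data Data frame whose first column is the patient identifier.
#' @param specs Variable dictionary (see [default_variable_specs()]); every
#'   non-id column of `data` must appear in it.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, specs = default_variable_specs()) {
  validate_specs(specs)
  if (ncol(data) < 2) stop("cohort table needs an id column plus variables",
                           call. = FALSE)
  ids <- as.character(data[[1]])
  if (anyDuplicated(ids))
    stop("duplicate patient id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vars <- names(data)[-1]
  unknown <- setdiff(vars, specs$name)
  if (length(unknown) > 0)
    stop("column(s) absent from metadata dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (v in vars) {
    x <- data[[v]]
    if (is.character(x)) {
      xt <- trimws(x)
      xt[xt %in% c("", "NA", "na", "NaN")] <- NA
      xn <- suppressWarnings(as.numeric(xt))
      bad <- which(!is.na(xt) & is.na(xn))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     x[bad[1]], v, bad[1]), call. = FALSE)
      x <- xn
    }
    x <- as.numeric(x)
    x[is.nan(x)] <- NA
    sp <- specs[specs$name == v, ]
    out <- which(!is.na(x) & (x < sp$min | x > sp$max))
    if (length(out) > 0)
      stop(sprintf("value %g out of range [%g, %g] in column '%s', row %d",
                   x[out[1]], sp$min, sp$max, v, out[1]), call. = FALSE)
    df[[v]] <- x
  }
  structure(list(data = df, specs = specs), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  nv <- ncol(x$data) - 1L
  cat(sprintf("<cohort_table> %d patients x %d variables\n", nrow(x$data), nv))
  cat("  map inputs present:",
      sum(tda_variables(x$specs) %in% names(x$data)), "of",
      length(tda_variables(x$specs)), "\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$data)

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package", call. = FALSE)
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Load a cohort from delimited or spreadsheet files
#'
#' Reads a patient-by-variable table (CSV or XLSX; the first column is taken
#' as the patient identifier) and a metadata dictionary with columns
#' `name, kind, min, max, role`. Blank cells, `"NA"`, and any value in
#' `na_codes` are normalized to the internal missing state. An optional
#' `name_map` renames source columns to the canonical variable names, so
#' external exports with their own headers can be loaded without editing.
#'
#' @param table_path Path to the cohort table (CSV or XLSX).
#' @param metadata_path Path to the metadata dictionary (CSV or XLSX), or
#'   `NULL` to use [default_variable_specs()].
#' @param name_map Optional named character vector: `c(source_name = canonical_name)`.
#' @param na_codes Numeric sentinel values to treat as missing.
#' @param require_tda If `TRUE`, fail unless all 17 map-input columns are present.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(table_path, metadata_path = NULL, name_map = NULL,
                        na_codes = numeric(0), require_tda = FALSE) {
  raw <- read_table_any(table_path)
  specs <- if (is.null(metadata_path)) default_variable_specs() else
    read_table_any(metadata_path)
  if (!is.null(name_map)) {
    hit <- names(raw) %in% names(name_map)
    names(raw)[hit] <- unname(name_map[names(raw)[hit]])
  }
  known <- c(names(raw)[1], specs$name)
  raw <- raw[, names(raw) %in% known, drop = FALSE]
  if (length(na_codes) > 0) {
    for (v in names(raw)[-1]) {
      x <- suppressWarnings(as.numeric(raw[[v]]))
      raw[[v]][!is.na(x) & x %in% na_codes] <- NA
    }
  }
  cohort <- cohort_table(raw, specs)
  if (require_tda) {
    absent <- setdiff(tda_variables(specs), names(cohort$data))
    if (length(absent) > 0)
      stop("required map-input column(s) missing: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write a cohort table to UTF-8 CSV
#'
#' Missing values are written as empty cells; [load_cohort()] on the output
#' reproduces all values and missing flags exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$data
  for (v in names(out)[-1])   # %.17g survives the double -> text -> double trip
    out[[v]] <- ifelse(is.na(out[[v]]), "", sprintf("%.17g", out[[v]]))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-variable descriptive statistics
#'
#' One row per variable with the non-missing count, missing count, range,
#' mean and standard deviation (sample SD, over non-missing values only).
#' An all-missing column yields `N = 0` and `NA` moments.
#'
#' @param cohort A `cohort_table`.
#' @return Data frame with columns `variable, N, missing, min, max, mean, sd`.
#' @export
summarize_variables <- function(cohort) {
  vars <- names(cohort$data)[-1]
  rows <- lapply(vars, function(v) {
    x <- cohort$data[[v]]
    ok <- !is.na(x)
    data.frame(
      variable = v,
      N = sum(ok),
      missing = sum(!ok),
      min = if (any(ok)) min(x[ok]) else NA_real_,
      max = if (any(ok)) max(x[ok]) else NA_real_,
      mean = if (any(ok)) mean(x[ok]) else NA_real_,
      sd = if (sum(ok) > 1) stats::sd(x[ok]) else if (sum(ok) == 1) 0 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
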