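#' Select a subgroup of patients from a Mapper graph
#'
#' Nodes are picked either by an explicit id list or by a predicate
#' expression evaluated over the node statistics (the per-node means, named
#' as the cohort variables, plus `size`). The subgroup is the union of the
#' selected nodes' patients; patients appearing in both selected and
#' unselected nodes (through cover overlap) are assigned to the subgroup and
#' removed from the complement, so the two-sample tests compare disjoint
#' patient sets.
#'
#' @param graph A `mapper_graph`.
#' @param predicate A one-sided formula or expression over node statistics,
#'   e.g. `~ gose_6m < 5 & ct_pathology == 0`; ignored when `node_ids` given.
#' @param node_ids Optional explicit node-id vector.
#' @param comparison `"all-others"` (default) or a second predicate/formula
#'   evaluated over node statistics to define the comparison set (e.g. other
#'   CT-negative patients); subgroup members are always excluded from it.
#' @return A `subgroup_selection`: list with `node_ids`, `member_ids`,
#'   `complement_ids`.
#' @export
select_subgroup <- function(graph, predicate = NULL, node_ids = NULL,
                            comparison = "all-others") {
  stats_df <- as.data.frame(graph$stats)
  stats_df$size <- graph$node_table$size
  if (is.null(node_ids)) {
    if (is.null(predicate)) stop("give a predicate or explicit node ids",
                                 call. = FALSE)
    keep <- eval_node_predicate(predicate, stats_df)
    node_ids <- graph$node_table$node_id[keep]
  }
  if (length(node_ids) == 0) stop("empty selection: no node satisfies the ",
                                  "predicate", call. = FALSE)
  member_idx <- sort(unique(unlist(graph$members[node_ids])))
  member_ids <- graph$patient_ids[member_idx]
  if (identical(comparison, "all-others")) {
    complement_ids <- setdiff(graph$patient_ids, member_ids)
  } else {
    keep <- eval_node_predicate(comparison, stats_df)
    comp_idx <- sort(unique(unlist(graph$members[graph$node_table$node_id[keep]])))
    complement_ids <- setdiff(graph$patient_ids[comp_idx], member_ids)
  }
  if (length(complement_ids) == 0)
    stop("empty complement: the selection covers every patient", call. = FALSE)
  structure(list(node_ids = node_ids, member_ids = member_ids,
                 complement_ids = complement_ids),
            class = "subgroup_selection")
}

eval_node_predicate <- function(predicate, stats_df) {
  expr <- if (inherits(predicate, "formula")) predicate[[2]] else
    if (is.character(predicate)) str2lang(predicate) else predicate
  bad <- setdiff(all.vars(expr), names(stats_df))
  if (length(bad) > 0)
    stop("predicate references unknown node statistic(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  keep <- eval(expr, stats_df, baseenv())
  if (!is.logical(keep) || length(keep) != nrow(stats_df))
    stop("predicate must evaluate to one logical per node", call. = FALSE)
  keep & !is.na(keep)
}

#' @export
print.subgroup_selection <- function(x, ...) {
  cat(sprintf("<subgroup_selection> %d nodes, %d members vs %d comparison\n",
              length(x$node_ids), length(x$member_ids),
              length(x$complement_ids)))
  invisible(x)
}

enrichment_row <- function(variable, test, statistic, p_value, detail) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 p_value = p_value, q_value = NA_real_, detail = detail,
                 testable = is.finite(p_value)),
            class = "enrichment_result")
}

#' Two-sample Kolmogorov-Smirnov enrichment of a continuous variable
#'
#' Compares the subgroup's distribution against the complement's with the
#' two-sample KS statistic (maximum ECDF gap) and its asymptotic p-value.
#' Fewer than 3 non-missing values on either side flags the variable as
#' untestable (excluded from the BH family).
#'
#' @param sel A `subgroup_selection`.
#' @param cohort The `cohort_table`.
#' @param variable Continuous variable name.
#' @return An `enrichment_result`.
#' @export
ks_enrichment <- function(sel, cohort, variable) {
  x <- cohort_values(cohort, variable, sel$member_ids)
  y <- cohort_values(cohort, variable, sel$complement_ids)
  if (length(x) < 3 || length(y) < 3)
    return(enrichment_row(variable, "KS", NA_real_, NA_real_,
                          list(n_subgroup = length(x), n_complement = length(y))))
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  enrichment_row(variable, "KS", unname(kt$statistic), kt$p.value,
                 list(n_subgroup = length(x), n_complement = length(y),
                      mean_subgroup = mean(x), mean_complement = mean(y)))
}

cohort_values <- function(cohort, variable, ids) {
  if (!variable %in% names(cohort$data))
    stop("unknown variable: ", variable, call. = FALSE)
  x <- cohort$data[[variable]][match(ids, cohort$data$patient_id)]
  x[!is.na(x)]
}

#' Categorical (genotype) enrichment of a subgroup
#'
#' Builds the R x 2 contingency table of category counts in the subgroup
#' versus the complement. Tables with more than 2 observed categories use
#' the chi-square test of independence without continuity correction; 2 x 2
#' tables use Fisher's exact test. A variable constant across both groups is
#' flagged untestable.
#'
#' @param sel A `subgroup_selection`.
#' @param cohort The `cohort_table`.
#' @param variable Categorical / genotype variable name.
#' @return An `enrichment_result` whose `detail` carries the contingency
#'   table.
#' @export
categorical_enrichment <- function(sel, cohort, variable) {
  x <- cohort_values(cohort, variable, sel$member_ids)
  y <- cohort_values(cohort, variable, sel$complement_ids)
  levels_all <- sort(unique(c(x, y)))
  if (length(levels_all) < 2 || length(x) == 0 || length(y) == 0)
    return(enrichment_row(variable, "chi-square", NA_real_, NA_real_,
                          list(note = "constant or empty variable")))
  tab <- rbind(subgroup = table(factor(x, levels = levels_all)),
               complement = table(factor(y, levels = levels_all)))
  if (length(levels_all) == 2) {
    ft <- stats::fisher.test(tab)
    enrichment_row(variable, "Fisher", unname(ft$estimate), ft$p.value,
                   list(contingency = tab))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    enrichment_row(variable, "chi-square", unname(ct$statistic), ct$p.value,
                   list(contingency = tab, df = unname(ct$parameter)))
  }
}

#' Benjamini-Hochberg adjustment within a family of enrichment results
#'
#' Untestable results (missing p) are excluded from the family and keep
#' `q = NA`.
#'
#' @param results List of `enrichment_result` objects.
#' @return The same list with `q_value` filled in.
#' @export
adjust_bh <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  ok <- is.finite(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  for (i in seq_along(results)) results[[i]]$q_value <- q[i]
  results
}

#' Run the standard enrichment panel for a subgroup
#'
#' KS tests for continuous variables and chi-square/Fisher tests for
#' genotype columns, BH-adjusted within each family.
#'
#' @param sel A `subgroup_selection`.
#' @param cohort The `cohort_table`.
#' @param continuous,categorical Variable name vectors; defaults cover the
#'   continuous map inputs and all genotype columns.
#' @return Data frame with `variable, test, statistic, p_value, q_value`,
#'   sorted by q then p within each family, categorical family first.
#' @export
enrichment_panel <- function(sel, cohort,
                             continuous = NULL, categorical = NULL) {
  specs <- cohort$specs
  present <- names(cohort$data)[-1]
  if (is.null(continuous))
    continuous <- intersect(specs$name[specs$kind == "continuous"], present)
  if (is.null(categorical))
    categorical <- intersect(specs$name[specs$kind == "genotype"], present)
  cat_res <- adjust_bh(lapply(categorical, function(v)
    categorical_enrichment(sel, cohort, v)))
  con_res <- adjust_bh(lapply(continuous, function(v)
    ks_enrichment(sel, cohort, v)))
  to_df <- function(rs, family) {
    if (length(rs) == 0) return(NULL)
    df <- do.call(rbind, lapply(rs, function(r)
      data.frame(variable = r$variable, family = family, test = r$test,
                 statistic = r$statistic, p_value = r$p_value,
                 q_value = r$q_value, stringsAsFactors = FALSE)))
    df[order(df$q_value, df$p_value), ]
  }
  out <- rbind(to_df(cat_res, "categorical"), to_df(con_res, "continuous"))
  rownames(out) <- NULL
  out
}
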