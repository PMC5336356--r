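#' Cover parameters for the Mapper stage
#'
#' @param resolution Intervals per lens axis (default 30).
#' @param gain Overlap multiplier (default 3): each base interval is dilated
#'   about its center so the overlap fraction with each neighbor is
#'   `1 - 1/gain` and a point lies in at most `gain` consecutive intervals
#'   per axis.
#' @param equalize If `TRUE` (default) intervals are built at empirical
#'   quantile breakpoints so every base interval holds ~n/resolution
#'   patients; if `FALSE`, equal-width intervals on the normalized lens.
#' @return A `cover_config` list.
#' @export
cover_config <- function(resolution = 30, gain = 3, equalize = TRUE) {
  stopifnot(resolution >= 1, gain >= 1)
  structure(list(resolution = as.integer(resolution), gain = gain,
                 equalize = isTRUE(equalize)), class = "cover_config")
}

# per-axis interval memberships: for each point, the consecutive interval
# indices whose dilated range contains it. Equalized covers work in rank
# (ECDF) space, where quantile base intervals have equal width and the
# "at most `gain` intervals per point" guarantee is exact; ties are broken
# by stable patient order.
axis_intervals <- function(x, resolution, gain, equalize) {
  n <- length(x)
  if (length(unique(x)) < resolution)
    stop("resolution (", resolution, ") exceeds the number of distinct lens ",
         "values on an axis (", length(unique(x)), "); lower the resolution",
         call. = FALSE)
  u <- if (equalize) {
    (rank(x, ties.method = "first") - 0.5) / n
  } else {
    pmin(pmax(x, 0), 1 - 1e-12)   # keep the top point inside the last interval
  }
  pos <- u * resolution + 0.5
  k_min <- pmax(1L, as.integer(floor(pos - gain / 2)) + 1L)
  k_max <- pmin(resolution, as.integer(floor(pos + gain / 2)))
  # membership: k in (pos - gain/2, pos + gain/2]
  lapply(seq_len(n), function(i) {
    ks <- k_min[i]:k_max[i]
    ks[ks > pos[i] - gain / 2 & ks <= pos[i] + gain / 2]
  })
}

#' Build the overlapping 2-D cover of a lens embedding
#'
#' Each lens axis is split into `resolution` base intervals (at empirical
#' quantile breakpoints when `equalize = TRUE`, so patients are spread
#' evenly), every interval is dilated by the gain, and the 2-D bins are the
#' Cartesian products of the per-axis intervals. Every lens point lies in at
#' least one bin, and in at most `gain` intervals per axis.
#'
#' @param lens A `lens_embedding` with normalized coordinates.
#' @param cfg A [cover_config()].
#' @return List of cover bins, each a list with `axis_index` (interval index
#'   per axis) and `member_idx` (patient row indices).
#' @export
build_cover <- function(lens, cfg = cover_config()) {
  coords <- lens$coords
  n <- nrow(coords)
  ax1 <- axis_intervals(coords[, 1], cfg$resolution, cfg$gain, cfg$equalize)
  ax2 <- axis_intervals(coords[, 2], cfg$resolution, cfg$gain, cfg$equalize)
  key_of <- function(i, j) (i - 1L) * cfg$resolution + j
  keys <- unlist(lapply(seq_len(n), function(p) key_of(
    rep(ax1[[p]], each = length(ax2[[p]])), rep(ax2[[p]], length(ax1[[p]])))))
  pts <- unlist(lapply(seq_len(n), function(p)
    rep(p, length(ax1[[p]]) * length(ax2[[p]]))))
  by_bin <- split(pts, keys)
  lapply(names(by_bin), function(k) {
    k <- as.integer(k)
    list(axis_index = c((k - 1L) %/% cfg$resolution + 1L,
                        (k - 1L) %% cfg$resolution + 1L),
         member_idx = sort(by_bin[[as.character(k)]]))
  })
}

#' Cluster the patients of one cover bin
#'
#' Single-linkage clustering under the supplied distance matrix, cut at the
#' left edge of the first empty bar of a `histogram_bins`-bar histogram of
#' the merge distances (the standard Mapper first-gap heuristic). With no
#' empty bar, or fewer than 3 members, the bin stays one cluster.
#'
#' @param member_idx Patient row indices of the bin.
#' @param d A `distance_matrix`.
#' @param histogram_bins Bars in the merge-distance histogram (default 10).
#' @return List of integer vectors (clusters of patient row indices).
#' @export
cluster_bin <- function(member_idx, d, histogram_bins = 10) {
  m <- length(member_idx)
  if (m == 0) stop("empty bin", call. = FALSE)
  if (m == 1) return(list(member_idx))
  vals <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  sub <- vals[member_idx, member_idx, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  rng <- range(h)
  if (diff(rng) < 1e-12) return(list(member_idx))
  breaks <- seq(rng[1], rng[2], length.out = histogram_bins + 1)
  bar <- pmin(findInterval(h, breaks), histogram_bins)
  counts <- tabulate(bar, nbins = histogram_bins)
  empty <- which(counts == 0)
  if (length(empty) == 0) return(list(member_idx))
  threshold <- breaks[empty[1]]
  cl <- stats::cutree(hc, h = threshold)
  unname(lapply(split(member_idx, cl), as.integer))
}

#' Build the Mapper graph of a cohort
#'
#' Nodes are the clusters found within every cover bin; two nodes are joined
#' by an edge exactly when they share at least one patient. Per-node summary
#' statistics (mean over non-missing member values) are computed for every
#' cohort variable.
#'
#' @param lens A `lens_embedding`.
#' @param d The `distance_matrix` used for in-bin clustering.
#' @param cohort The `cohort_table` (for node statistics and coloring).
#' @param cfg A [cover_config()].
#' @param histogram_bins Passed to [cluster_bin()].
#' @return A `mapper_graph`: list with `members` (list of patient index
#'   vectors), `node_table` (node id, bin, size), `stats` (node-by-variable
#'   means), `counts` (non-missing member counts behind each mean), `edges`
#'   (2-column node-id matrix), `patient_ids`, `cohort`, `lens`, `config`.
#' @export
build_graph <- function(lens, d, cohort, cfg = cover_config(),
                        histogram_bins = 10) {
  if (n_patients(cohort) == 0) stop("empty cohort", call. = FALSE)
  bins <- build_cover(lens, cfg)
  members <- list()
  bin1 <- integer(0); bin2 <- integer(0)
  for (b in bins) {
    cls <- cluster_bin(b$member_idx, d, histogram_bins)
    members <- c(members, cls)
    bin1 <- c(bin1, rep(b$axis_index[1], length(cls)))
    bin2 <- c(bin2, rep(b$axis_index[2], length(cls)))
  }
  n_nodes <- length(members)
  sizes <- lengths(members)
  node_table <- data.frame(node_id = seq_len(n_nodes), bin1 = bin1,
                           bin2 = bin2, size = sizes)

  # node-by-variable means over non-missing member values
  node_of <- rep(seq_len(n_nodes), sizes)
  pat_of <- unlist(members)
  vals <- as.matrix(cohort$data[, -1, drop = FALSE])
  v_long <- vals[pat_of, , drop = FALSE]
  obs <- !is.na(v_long)
  v0 <- v_long; v0[!obs] <- 0
  sums <- rowsum(v0, node_of)
  counts <- rowsum(obs + 0, node_of)
  stats_m <- sums / ifelse(counts > 0, counts, NA)

  # edges: nodes sharing at least one patient (no self-edges)
  by_patient <- split(node_of, pat_of)
  pair_list <- lapply(by_patient, function(ns) {
    if (length(ns) < 2) return(NULL)
    t(utils::combn(sort(unique(ns)), 2))
  })
  edges <- unique(do.call(rbind, pair_list))
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("from", "to")

  structure(list(members = members, node_table = node_table,
                 stats = stats_m, counts = counts, edges = edges,
                 patient_ids = cohort$data$patient_id,
                 cohort = cohort, lens = lens, config = cfg),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf(
    "<mapper_graph> %d nodes, %d edges, %d patients (resolution %d, gain %g%s)\n",
    nrow(x$node_table), nrow(x$edges), length(x$patient_ids),
    x$config$resolution, x$config$gain,
    if (x$config$equalize) ", equalized" else ""))
  invisible(x)
}

#' Per-node coloring values for one variable
#'
#' @param graph A `mapper_graph`.
#' @param variable Cohort variable name.
#' @param statistic `"mean"` or `"proportion"` (proportion of members with a
#'   positive/nonzero value; for 0/1 variables the two coincide).
#' @return Data frame `node_id, value, n` (`value` is `NA`, flagged
#'   uncolored, for nodes with no non-missing member values).
#' @export
color_graph <- function(graph, variable, statistic = c("mean", "proportion")) {
  statistic <- match.arg(statistic)
  if (!variable %in% colnames(graph$stats))
    stop("unknown variable: ", variable, call. = FALSE)
  if (statistic == "mean") {
    value <- graph$stats[, variable]
  } else {
    vals <- graph$cohort$data[[variable]]
    value <- vapply(graph$members, function(idx) {
      x <- vals[idx]
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else mean(x != 0)
    }, numeric(1))
  }
  data.frame(node_id = graph$node_table$node_id, value = as.numeric(value),
             n = as.integer(graph$counts[, variable]))
}

#' Convert a Mapper graph to an igraph object
#'
#' Node attributes: `size` plus the per-variable node means.
#'
#' @param graph A `mapper_graph`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$node_table), directed = FALSE)
  g <- igraph::add_edges(g, t(graph$edges))
  g <- igraph::set_vertex_attr(g, "size", value = graph$node_table$size)
  for (v in colnames(graph$stats))
    g <- igraph::set_vertex_attr(g, paste0("mean_", v),
                                 value = as.numeric(graph$stats[, v]))
  g
}

#' Export a Mapper graph as GraphML and/or JSON
#'
#' The JSON form carries nodes (with member patient ids and per-variable
#' means), edges, and the cover configuration.
#'
#' @param graph A `mapper_graph`.
#' @param graphml_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_mapper_graph <- function(graph, graphml_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(graph), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(json_path)) {
    nodes <- lapply(seq_along(graph$members), function(i) {
      st <- graph$stats[i, ]
      list(node_id = i,
           bin = unname(unlist(graph$node_table[i, c("bin1", "bin2")])),
           members = graph$patient_ids[graph$members[[i]]],
           means = as.list(st[!is.na(st)]))
    })
    jsonlite::write_json(
      list(config = unclass(graph$config), nodes = nodes,
           edges = as.data.frame(graph$edges)),
      json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
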