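#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centered eigendecomposition solution via [stats::cmdscale()],
#' with axes ordered by eigenvalue and a deterministic sign convention:
#' each axis is flipped so that, among the points of maximal absolute
#' coordinate, the one with the lowest index has positive sign.
#'
#' @param d A `distance_matrix` (or symmetric numeric matrix).
#' @param k Embedding dimension (default 2); must be at most patients - 1.
#' @return Patients-by-`k` coordinate matrix.
#' @export
classical_mds <- function(d, k = 2) {
  vals <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  n <- nrow(vals)
  if (n < 3) stop("classical MDS needs at least 3 patients", call. = FALSE)
  if (k > n - 1) stop("embedding dimension must be at most patients - 1",
                      call. = FALSE)
  z <- suppressWarnings(stats::cmdscale(stats::as.dist(vals), k = k))
  if (ncol(z) < k)   # rank-deficient configurations pad with zero axes
    z <- cbind(z, matrix(0, n, k - ncol(z)))
  fix_axis_signs(z)
}

fix_axis_signs <- function(z) {
  for (j in seq_len(ncol(z))) {
    a <- abs(z[, j])
    i <- which(a == max(a))[1]
    if (z[i, j] < 0) z[, j] <- -z[, j]
  }
  z
}

#' Raw stress of an embedding
#'
#' \eqn{\sum_{i<j} (d_{ij} - \lVert z_i - z_j \rVert_2)^2}: the squared
#' discrepancy between the target distances and the Euclidean distances of
#' the embedded points.
#'
#' @param d A `distance_matrix` or symmetric matrix.
#' @param z Coordinate matrix with one row per patient.
#' @return Nonnegative scalar.
#' @export
lens_stress <- function(d, z) {
  vals <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  if (nrow(z) != nrow(vals)) stop("coordinate rows must match distance rows",
                                  call. = FALSE)
  dz <- as.matrix(stats::dist(z))
  sum((vals[upper.tri(vals)] - dz[upper.tri(dz)])^2)
}

#' Two-coordinate MDS lens by stress majorization
#'
#' Starts from the classical MDS configuration and applies SMACOF (Guttman
#' transform) iterations, which decrease the raw stress monotonically, until
#' the relative stress change falls below `tol` or `max_iter` is reached.
#' Axes are then re-ordered by sample variance (lens coordinate 1 carries
#' the highest variance), signs fixed deterministically, and each coordinate
#' is range-normalized to `[0, 1]` (Gower scaling). A degenerate constant
#' coordinate is set to 0.5 with a warning.
#'
#' @param d A `distance_matrix`.
#' @param k Lens dimension (default 2).
#' @param max_iter Maximum majorization iterations (default 300).
#' @param tol Relative stress-change convergence threshold (default 1e-6).
#' @return A `lens_embedding`: list with `coords` (normalized, in
#'   `[0, 1]`), `raw_coords`, `stress`, `stress_trace`, `iterations`,
#'   `converged`, `normalized`, `patient_ids`.
#' @export
optimize_lens <- function(d, k = 2, max_iter = 300, tol = 1e-6) {
  vals <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  ids <- if (inherits(d, "distance_matrix")) d$patient_ids else rownames(vals)
  n <- nrow(vals)
  z0 <- classical_mds(vals, k = k)
  fit <- smacof_engine(vals, z0, as.integer(max_iter), tol)
  z <- fit$z
  s <- fit$stress
  trace <- fit$trace
  iter <- fit$iterations
  converged <- fit$converged
  if (!converged && iter >= max_iter)
    warning("stress majorization stopped at max_iter without meeting tol",
            call. = FALSE)

  vars <- apply(z, 2, stats::var)
  z <- fix_axis_signs(z[, order(vars, decreasing = TRUE), drop = FALSE])
  coords <- z
  degenerate_axes <- integer(0)
  for (j in seq_len(k)) {
    rng <- range(z[, j])
    if (diff(rng) < 1e-12) {
      degenerate_axes <- c(degenerate_axes, j)
      coords[, j] <- 0.5
    } else {
      coords[, j] <- (z[, j] - rng[1]) / diff(rng)
    }
  }
  if (length(degenerate_axes) > 0)
    warning("constant lens coordinate(s) ",
            paste(degenerate_axes, collapse = ", "),
            "; normalized value set to 0.5", call. = FALSE)
  colnames(coords) <- paste0("mds", seq_len(k))
  rownames(coords) <- ids
  structure(list(coords = coords, raw_coords = z, stress = s,
                 stress_trace = trace, iterations = iter,
                 converged = converged, normalized = TRUE,
                 patient_ids = ids),
            class = "lens_embedding")
}

#' @export
print.lens_embedding <- function(x, ...) {
  cat(sprintf(
    "<lens_embedding> %d patients, %d coords, stress %.4g after %d iterations\n",
    nrow(x$coords), ncol(x$coords), x$stress, x$iterations))
  invisible(x)
}

#' Export lens coordinates as CSV
#' @param lens A `lens_embedding`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lens <- function(lens, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# stress: %.12g", lens$stress), con)
  utils::write.csv(data.frame(patient_id = lens$patient_ids, lens$coords,
                              stringsAsFactors = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}
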