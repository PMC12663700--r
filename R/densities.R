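# Aligned histogram densities: each site's (filtered, reduced) point
# cloud becomes a probability vector over a bin grid shared by all sites,
# flattened in a fixed row-major order so the vectors are directly
# comparable ("column stacking").

#' Shared histogram bin edges over the pooled range of all sources
#'
#' Per dimension, the edges are `bins_per_dim + 1` equally spaced values
#' spanning the pooled minimum..maximum over all sources; the upper edge
#' is inclusive. A dimension with zero pooled range collapses to a single
#' unit-width bin centred on the constant value, with a warning.
#'
#' @param points_by_source named list of m_i x k numeric matrices.
#' @param bins_per_dim bins per dimension (default 10).
#' @return list of per-dimension edge vectors.
#' @export
shared_edges <- function(points_by_source, bins_per_dim = 10L) {
  mats <- lapply(points_by_source, as.matrix)
  if (!sum(vapply(mats, nrow, 0L)))
    stop_msvdq("no points to bin", "msvdq_density_error")
  pooled <- do.call(rbind, mats)
  if (!all(is.finite(pooled)))
    stop_msvdq("non-finite coordinates", "msvdq_density_error")
  lapply(seq_len(ncol(pooled)), function(d) {
    lo <- min(pooled[, d]); hi <- max(pooled[, d])
    if (lo == hi) {
      warning(sprintf("dimension %d has zero range; using a single bin", d))
      return(c(lo - 0.5, hi + 0.5))
    }
    seq(lo, hi, length.out = bins_per_dim + 1L)
  })
}

# Row-major flat index of the k-dim bin assignment (first dimension
# varies slowest).
flatten_index <- function(bin_idx, n_bins) {
  idx <- 0
  for (d in seq_along(n_bins)) idx <- idx * n_bins[d] + (bin_idx[, d] - 1L)
  idx + 1L
}

#' Histogram one source on shared edges
#'
#' Counts over the k-dimensional grid are flattened row-major and divided
#' by the number of points, yielding a probability vector of length
#' `prod(bins per dimension)`. Points outside the edge bounds are clamped
#' into the boundary bins with a warning; the upper edge of each
#' dimension is inclusive.
#'
#' @param points m x k numeric matrix (m >= 1).
#' @param edges edge list from [shared_edges()].
#' @return numeric probability vector summing to 1.
#' @export
histogram_source <- function(points, edges) {
  points <- as.matrix(points)
  if (!nrow(points))
    stop_msvdq("empty source", "msvdq_density_error")
  if (ncol(points) != length(edges))
    stop_msvdq("points and edges disagree on dimensionality",
               "msvdq_density_error")
  n_bins <- vapply(edges, length, 0L) - 1L
  bin_idx <- matrix(0L, nrow(points), ncol(points))
  for (d in seq_along(edges)) {
    x <- points[, d]
    if (any(x < edges[[d]][1L] | x > edges[[d]][length(edges[[d]])]))
      warning(sprintf("clamping out-of-range points in dimension %d", d))
    bin_idx[, d] <- findInterval(x, edges[[d]], rightmost.closed = TRUE,
                                 all.inside = TRUE)
  }
  counts <- tabulate(flatten_index(bin_idx, n_bins), nbins = prod(n_bins))
  counts / nrow(points)
}

#' Build aligned densities for a set of sources
#'
#' @param points_by_source named list of m_i x k matrices (one per source).
#' @param bins_per_dim bins per dimension (default 10).
#' @return object of class `"aligned_density"`: list with `densities`
#'   (named list of probability vectors over the shared flattened grid),
#'   `bin_edges`, `n_cases` (points retained per source) and
#'   `bins_per_dim`.
#' @export
align_densities <- function(points_by_source, bins_per_dim = 10L) {
  if (is.null(names(points_by_source)))
    names(points_by_source) <- paste0("source", seq_along(points_by_source))
  edges <- shared_edges(points_by_source, bins_per_dim)
  dens <- lapply(points_by_source, histogram_source, edges = edges)
  structure(list(densities = dens, bin_edges = edges,
                 n_cases = vapply(points_by_source,
                                  function(p) nrow(as.matrix(p)), 0L),
                 bins_per_dim = bins_per_dim),
            class = "aligned_density")
}

#' Column-stacked density matrix
#'
#' @param x an [align_densities()] result.
#' @return matrix with one column per source (bins x sources).
#' @export
as_density_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_density"))
  do.call(cbind, x$densities)
}

#' @export
print.aligned_density <- function(x, ...) {
  cat(sprintf(
    "Aligned densities: %d source(s), %d-dimensional grid, %d bins total\n",
    length(x$densities), length(x$bin_edges), length(x$densities[[1L]])))
  invisible(x)
}
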