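# Per-site outlier filtering in the reduced space via the local outlier
# factor (LOF).

#' Local outlier factor scores
#'
#' Standard LOF with Euclidean distances: the k-distance of a point is the
#' distance to its k-th nearest neighbour; its neighbourhood contains
#' every other point within the k-distance (ties included); the
#' reachability distance is `reach_k(a, b) = max(kdist(b), d(a, b))`; the
#' local reachability density is the inverse mean reachability over the
#' neighbourhood; and `LOF(a)` is the mean ratio of the neighbours'
#' densities to a's own. Density denominators are floored at 1e-12 so
#' coincident points yield finite scores of exactly 1. If `k_neighbors >=
#' m`, `m - 1` is used.
#'
#' @param points m x k numeric matrix.
#' @param k_neighbors neighbourhood size (default 20).
#' @return numeric vector of m scores (all >= 0; ~1 for inliers).
#' @export
lof_scores <- function(points, k_neighbors = 20L) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2L)
    stop_msvdq("LOF needs at least 2 points", "msvdq_outlier_error")
  k <- min(as.integer(k_neighbors), m - 1L)
  if (k < 1L)
    stop_msvdq("k_neighbors must be >= 1", "msvdq_outlier_error")
  D <- as.matrix(stats::dist(points))
  kdist <- numeric(m)
  nbrs <- vector("list", m)
  for (i in seq_len(m)) {
    d <- D[i, -i]
    kdist[i] <- sort(d, partial = k)[k]
    nbrs[[i]] <- setdiff(which(D[i, ] <= kdist[i]), i)
  }
  lrd <- vapply(seq_len(m), function(i) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    1 / max(mean(reach), 1e-12)
  }, 0)
  vapply(seq_len(m), function(i) mean(lrd[nbrs[[i]]] / lrd[i]), 0)
}

#' Filter outliers independently within each site
#'
#' LOF scores are computed within each site; rows scoring above
#' `threshold` are removed, but never more than `max_removed_frac` of a
#' site's rows (the cap protects the downstream density estimate in small
#' sites; when it binds, the largest scores are removed first and the
#' excess is flagged).
#'
#' @param r a `"reduced_scores"` object with per-row `site` labels (or any
#'   list with `scores` and `site`).
#' @param k_neighbors LOF neighbourhood size (default 20).
#' @param threshold LOF removal cutoff (default 1.5).
#' @param max_removed_frac per-site removal cap (default 0.10).
#' @return list with `scores` (the reduced scores restricted to kept
#'   rows), `site` (matching labels) and `report` (an `"outlier_report"`:
#'   per-site kept row indices, LOF scores, applied threshold,
#'   neighbourhood size, and capped-site flags).
#' @export
filter_per_site <- function(r, k_neighbors = 20L, threshold = 1.5,
                            max_removed_frac = 0.10) {
  X <- r$scores
  site <- r$site
  stopifnot(!is.null(site), nrow(X) == length(site))
  sites <- unique(site)
  lof <- numeric(nrow(X))
  keep <- logical(nrow(X))
  kept_index <- list()
  capped <- character()
  for (s in sites) {
    rows <- which(site == s)
    if (length(rows) < 2L)
      stop_msvdq(sprintf("site '%s' has fewer than 2 rows", s),
                 "msvdq_outlier_error")
    sc <- lof_scores(X[rows, , drop = FALSE], k_neighbors)
    lof[rows] <- sc
    out <- which(sc > threshold)
    cap <- floor(max_removed_frac * length(rows))
    if (length(out) > cap) {
      capped <- c(capped, s)
      out <- out[order(-sc[out])][seq_len(cap)]
    }
    kp <- setdiff(seq_along(rows), out)
    if (length(kp) < 2L)
      stop_msvdq(sprintf("site '%s' reduced below 2 rows by filtering", s),
                 "msvdq_outlier_error")
    keep[rows[kp]] <- TRUE
    kept_index[[s]] <- rows[kp]
  }
  report <- structure(list(kept_index = kept_index, lof_scores = lof,
                           threshold = threshold, k_neighbors = k_neighbors,
                           capped_sites = capped),
                      class = "outlier_report")
  kept <- r
  kept$scores <- X[keep, , drop = FALSE]
  kept$site <- site[keep]
  list(scores = kept, site = site[keep], report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  n_kept <- sum(lengths(x$kept_index))
  n_all <- length(x$lof_scores)
  cat(sprintf(
    "LOF filter (k=%d, threshold=%.2f): kept %d/%d rows across %d site(s)\n",
    x$k_neighbors, x$threshold, n_kept, n_all, length(x$kept_index)))
  if (length(x$capped_sites))
    cat("  removal cap hit for:", paste(x$capped_sites, collapse = ", "), "\n")
  invisible(x)
}
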