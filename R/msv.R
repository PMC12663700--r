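# Metric core: Jensen-Shannon distances between source densities, the
# simplex embedding that conserves them, and the two bounded multisource
# variability metrics derived from it -- the per-source probabilistic
# outlyingness (SPO, distance to the case-weighted centroid) and the
# global probabilistic deviation (GPD, weighted mean of those distances).
#
# Both metrics are normalized by c_s = sqrt((s-1)/(2s)), the
# vertex-centroid distance of the unit-edge regular simplex: the
# maximal-separation configuration (all sources pairwise non-overlapping,
# equal weights) then scores exactly 1, while identical sources score 0.

#' Jensen-Shannon distance between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`,
#' logarithms base 2 and `0 log 0 = 0`; the returned value is
#' `sqrt(JSD)`, a metric bounded in \[0, 1\] that reaches 1 exactly for
#' disjoint supports.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing
#'   to 1 (within 1e-9).
#' @return the Jensen-Shannon distance, a scalar in \[0, 1\].
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q))
    stop_msvdq("probability vectors differ in length", "msvdq_metric_error")
  if (any(p < 0) || any(q < 0))
    stop_msvdq("negative probability mass", "msvdq_metric_error")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop_msvdq("probability vectors must sum to 1", "msvdq_metric_error")
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  jsd <- (kl(p) + kl(q)) / 2
  sqrt(min(max(jsd, 0), 1))
}

#' Pairwise Jensen-Shannon distance matrix of aligned densities
#'
#' @param d an [align_densities()] result, or a named list of probability
#'   vectors on a common grid.
#' @return symmetric s x s matrix of class `"dist_matrix"` with zero
#'   diagonal and source labels.
#' @export
pairwise_distances <- function(d) {
  dens <- if (inherits(d, "aligned_density")) d$densities else d
  s <- length(dens)
  if (s < 2L)
    stop_msvdq("need >= 2 sources", "msvdq_metric_error")
  labels <- names(dens) %||% paste0("source", seq_len(s))
  D <- matrix(0, s, s, dimnames = list(labels, labels))
  for (i in seq_len(s - 1L))
    for (j in (i + 1L):s)
      D[i, j] <- D[j, i] <- js_distance(dens[[i]], dens[[j]])
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Simplex embedding of a distance matrix (classical scaling)
#'
#' Torgerson scaling: `B = -J D^2 J / 2` with `J` the centering matrix;
#' `B` is eigen-decomposed and vertex coordinates are
#' `eigenvectors * sqrt(eigenvalues)` over the non-negative spectrum.
#' Numerically negative eigenvalues above `-1e-10 * max` are clipped to
#' zero; a larger negative eigenvalue (beyond `1e-6 * max` in magnitude)
#' raises an error, since Jensen-Shannon distance matrices are Euclidean-
#' embeddable and a strong violation signals corrupted input. The
#' centroid is the case-weighted mean of the vertex coordinates -- the
#' informed average distribution of the sources.
#'
#' @param dm s x s symmetric distance matrix (zero diagonal).
#' @param weights positive per-source case counts (default equal).
#' @return object of class `"simplex_embedding"`: `coords` (s x (s-1)),
#'   `weights`, `centroid`, `eigenvalues` and source `labels`.
#' @export
embed_simplex <- function(dm, weights = NULL) {
  D <- unclass(as.matrix(dm))
  s <- nrow(D)
  if (s < 2L || ncol(D) != s)
    stop_msvdq("distance matrix must be square with >= 2 sources",
               "msvdq_metric_error")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop_msvdq("distance matrix must be symmetric with zero diagonal",
               "msvdq_metric_error")
  weights <- weights %||% rep(1, s)
  if (length(weights) != s || any(weights <= 0))
    stop_msvdq("weights must be positive, one per source",
               "msvdq_metric_error")
  J <- diag(s) - 1 / s
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  emax <- max(ev, 0)
  if (emax > 0 && min(ev) < -1e-6 * emax)
    stop_msvdq(
      "distance matrix is strongly non-Euclidean; input may be corrupted",
      "msvdq_metric_error")
  ev[ev < 0] <- 0
  ax <- seq_len(s - 1L)
  coords <- eg$vectors[, ax, drop = FALSE] %*% diag(sqrt(ev[ax]), s - 1L)
  # deterministic sign: largest-magnitude coordinate positive per axis
  for (a in ax) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  labels <- rownames(D) %||% paste0("source", seq_len(s))
  rownames(coords) <- labels
  centroid <- drop(weights %*% coords) / sum(weights)
  structure(list(coords = coords, weights = weights, centroid = centroid,
                 eigenvalues = ev, labels = labels),
            class = "simplex_embedding")
}

# Vertex-centroid distance of the unit-edge regular s-simplex: the
# normalizer mapping the all-disjoint equal-weight configuration to 1.
simplex_norm_const <- function(s) sqrt((s - 1) / (2 * s))

#' GPD and SPO from a simplex embedding
#'
#' With `d_i` the Euclidean distance from vertex `i` to the weighted
#' centroid and `c_s = sqrt((s-1)/(2s))`, `SPO_i = min(1, d_i / c_s)` and
#' `GPD = min(1, weighted.mean(d) / c_s)` (the clip guards the
#' unequal-weight corner where a light source can sit beyond `c_s`).
#'
#' @param e a [embed_simplex()] result.
#' @return list with `gpd`, named `spo`, the vertex-centroid `dists` and
#'   the normalizer `c_s`.
#' @export
compute_msv <- function(e) {
  stopifnot(inherits(e, "simplex_embedding"))
  s <- nrow(e$coords)
  if (s < 2L) stop_msvdq("need >= 2 sources", "msvdq_metric_error")
  d <- sqrt(rowSums(sweep(e$coords, 2, e$centroid)^2))
  cs <- simplex_norm_const(s)
  spo <- pmin(1, d / cs)
  names(spo) <- e$labels
  gpd <- min(1, sum(e$weights * d) / sum(e$weights) / cs)
  list(gpd = gpd, spo = spo, dists = d, c_s = cs)
}

#' MSV plot coordinates
#'
#' Projects the sources on the `dims` highest-eigenvalue axes of the
#' embedding; each source's plot radius is proportional to its case
#' count (`r_max * w_i / max(w)`).
#'
#' @param e a [embed_simplex()] result.
#' @param dims 2 or 3 (if more than available, the available axes are
#'   used with a warning).
#' @param r_max radius of the largest source (default 1).
#' @return list with `coords` (s x dims) and `radii`.
#' @export
msv_plot_coords <- function(e, dims = 2L, r_max = 1) {
  stopifnot(inherits(e, "simplex_embedding"))
  avail <- ncol(e$coords)
  if (dims > avail) {
    warning(sprintf("only %d embedding axes available", avail))
    dims <- avail
  }
  coords <- e$coords[, seq_len(dims), drop = FALSE]
  list(coords = coords, radii = r_max * e$weights / max(e$weights))
}

#' Multisource variability of a set of aligned densities
#'
#' The package's core estimator: computes pairwise Jensen-Shannon
#' distances between the sources' probability vectors, embeds them as a
#' simplex conserving the inter-source dissimilarities, and derives the
#' bounded variability metrics GPD (global) and SPO (per source), plus
#' MSV plot coordinates.
#'
#' @param x an [align_densities()] result, a named list of probability
#'   vectors on a common grid, or a precomputed `"dist_matrix"`.
#' @param weights per-source case counts used for the informed centroid
#'   and the plot radii; defaults to the densities' retained case counts
#'   (equal weights for a bare list or distance matrix).
#' @return object of class `"msv"` with elements `gpd`, `spo`,
#'   `distances`, `embedding`, `plot_coords`, `radii`, `weights`,
#'   `n_sources`.
#' @export
msv <- function(x, weights = NULL) {
  if (inherits(x, "dist_matrix") ||
      (is.matrix(x) && nrow(x) == ncol(x) && all(diag(x) == 0))) {
    dm <- x
  } else {
    dm <- pairwise_distances(x)
    if (is.null(weights) && inherits(x, "aligned_density"))
      weights <- x$n_cases
  }
  e <- embed_simplex(dm, weights)
  met <- compute_msv(e)
  pc <- msv_plot_coords(e, dims = min(2L, ncol(e$coords)))
  structure(list(gpd = met$gpd, spo = met$spo, distances = dm,
                 embedding = e, plot_coords = pc$coords, radii = pc$radii,
                 weights = e$weights, n_sources = length(met$spo)),
            class = "msv")
}

#' @export
print.msv <- function(x, digits = 3, ...) {
  cat(sprintf("Multisource variability over %d sources\n", x$n_sources))
  cat(sprintf("  GPD: %.*f\n", digits, x$gpd))
  cat("  SPO:", paste(sprintf("%s=%.*f", names(x$spo), digits, x$spo),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.msv <- function(object, ...) {
  cat(sprintf(
    "Multisource variability (GPD = %.4f; 0 = identical distributions, 1 = non-overlapping)\n",
    object$gpd))
  tab <- data.frame(source = names(object$spo), spo = unname(object$spo),
                    weight = object$weights,
                    dist_to_centroid = unname(
                      sqrt(rowSums(sweep(object$embedding$coords, 2,
                                         object$embedding$centroid)^2))))
  print(tab, row.names = FALSE, digits = 4)
  cat("\nPairwise Jensen-Shannon distances:\n")
  print(round(unclass(object$distances), 4))
  invisible(object)
}

#' @export
coef.msv <- function(object, ...) {
  c(gpd = object$gpd, stats::setNames(object$spo,
                                      paste0("spo.", names(object$spo))))
}

#' MSV plot: sources as circles in the top embedding axes
#'
#' Distances between circle centres reflect the Jensen-Shannon distances
#' between the sources' distributions; radii are proportional to case
#' counts.
#'
#' @param x an `"msv"` object.
#' @param r_scale radius of the largest source in plot units (default
#'   scaled to 1/8 of the coordinate span).
#' @param ... passed to [graphics::plot()].
#' @export
plot.msv <- function(x, r_scale = NULL, ...) {
  pc <- x$plot_coords
  if (ncol(pc) < 2L) pc <- cbind(pc, 0)
  span <- max(apply(pc, 2, function(v) diff(range(v))), 1e-6)
  r_scale <- r_scale %||% (span / 8)
  radii <- r_scale * x$weights / max(x$weights)
  lim <- function(v, r) range(v - r, v + r)
  graphics::plot(pc[, 1], pc[, 2], type = "n",
                 xlim = lim(pc[, 1], max(radii)),
                 ylim = lim(pc[, 2], max(radii)),
                 xlab = "Axis 1", ylab = "Axis 2",
                 main = sprintf("MSV plot (GPD = %.3f)", x$gpd), ...)
  graphics::symbols(pc[, 1], pc[, 2], circles = radii, inches = FALSE,
                    add = TRUE, fg = "grey30",
                    bg = grDevices::adjustcolor(
                      seq_len(nrow(pc)) + 1, alpha.f = 0.4))
  graphics::text(pc[, 1], pc[, 2], labels = rownames(pc), cex = 0.8)
  cen <- x$embedding$centroid
  graphics::points(cen[1], if (length(cen) > 1) cen[2] else 0, pch = 3)
  invisible(x)
}
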