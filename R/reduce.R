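# Dimensionality reduction: correlation PCA for the imputed values branch,
# indicator-matrix MCA for the categorical missingness branch, and the
# contribution-based top-variable ranking shared by both.

new_reduced_scores <- function(scores, loadings, explained, contributions,
                               site, method, dropped = character()) {
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, contributions = contributions,
                 site = site, method = method, dropped = dropped),
            class = "reduced_scores")
}

#' @export
print.reduced_scores <- function(x, ...) {
  cat(sprintf("%s reduction: %d rows -> %d axes (%.1f%% of %s)\n",
              toupper(x$method), nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained),
              if (x$method == "pca") "variance" else "inertia"))
  if (length(x$dropped))
    cat("  dropped constant column(s):", paste(x$dropped, collapse = ", "),
        "\n")
  invisible(x)
}

# Deterministic sign convention: on each axis the largest-magnitude
# loading (or category coordinate) is made positive.
fix_signs <- function(loadings, scores) {
  for (a in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of a complete encoded matrix
#'
#' Columns are centered and, by default, scaled to unit variance before
#' the decomposition (questionnaire items have heterogeneous encodings, so
#' correlation PCA is the default; switchable). Scores are the projections
#' on the top-`k` right singular directions; loadings are orthonormal.
#' Zero-variance columns are dropped with a warning. A deterministic sign
#' convention (largest-magnitude loading positive per component) makes the
#' output byte-stable.
#'
#' @param m a complete [encode()]d matrix (no masked cells).
#' @param k number of components (default 3).
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return a `"reduced_scores"` object; `explained` holds each retained
#'   axis's fraction of the total variance; `contributions` holds, per
#'   variable, the explained-weighted squared loading summed over the
#'   retained axes.
#' @export
pca_reduce <- function(m, k = 3L, standardize = TRUE) {
  stopifnot(inherits(m, "encoded_matrix"))
  if (any(m$mask))
    stop_msvdq("PCA input still has missing cells; impute first",
               "msvdq_reduce_error")
  V <- m$values
  sds <- apply(V, 2, stats::sd)
  dropped <- colnames(V)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")))
    V <- V[, sds > 0, drop = FALSE]
  }
  if (nrow(V) <= k)
    stop_msvdq("PCA needs n > k rows", "msvdq_reduce_error")
  k <- min(k, ncol(V))
  pc <- stats::prcomp(V, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  explained_all <- ev / sum(ev)
  sgn <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                   pc$x[, seq_len(k), drop = FALSE])
  contrib <- drop(sgn$loadings^2 %*% explained_all[seq_len(k)])
  names(contrib) <- colnames(V)
  # dropped columns contribute zero but keep their slot in the ranking
  if (length(dropped)) {
    z <- stats::setNames(rep(0, length(dropped)), dropped)
    contrib <- c(contrib, z)[colnames(m$values)]
  }
  new_reduced_scores(sgn$scores, sgn$loadings,
                     explained_all[seq_len(k)], contrib,
                     m$site, "pca", dropped)
}

#' Multiple correspondence analysis of a categorical matrix
#'
#' Implemented as correspondence analysis of the complete disjunctive
#' (indicator) matrix: build the indicator matrix Z, the correspondence
#' matrix P = Z / sum(Z), standardized residuals
#' S = Dr^(-1/2) (P - r c') Dc^(-1/2), and take the SVD of S. Row scores
#' are principal coordinates on the top-`k` axes; explained inertia
#' fractions are the squared singular values over their total. Constant
#' columns (a single observed level) are dropped with a warning.
#'
#' @param cat data.frame (or matrix) of categorical columns, no missing
#'   entries.
#' @param k number of axes (default 3).
#' @param site optional per-row site labels carried through.
#' @return a `"reduced_scores"` object; `loadings` is the category
#'   principal-coordinate table (rows = category levels), and
#'   `contributions` aggregates category contributions to their parent
#'   variable, weighted by explained inertia.
#' @export
mca_reduce <- function(cat, k = 3L, site = NULL) {
  cat <- as.data.frame(cat, stringsAsFactors = FALSE)
  cat[] <- lapply(cat, as.character)
  nlev <- vapply(cat, function(x) length(unique(x)), 0L)
  dropped <- names(cat)[nlev < 2L]
  if (length(dropped)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(dropped, collapse = ", ")))
    cat <- cat[, nlev >= 2L, drop = FALSE]
  }
  if (!ncol(cat))
    stop_msvdq("MCA needs at least one non-constant column",
               "msvdq_reduce_error")
  if (anyNA(cat))
    stop_msvdq("MCA input must be complete", "msvdq_reduce_error")
  n <- nrow(cat)
  # indicator (complete disjunctive) matrix
  blocks <- lapply(names(cat), function(nm) {
    f <- factor(cat[[nm]])
    Z <- matrix(0L, n, nlevels(f),
                dimnames = list(NULL, paste(nm, levels(f), sep = ":")))
    Z[cbind(seq_len(n), as.integer(f))] <- 1L
    Z
  })
  Z <- do.call(cbind, blocks)
  var_of_cat <- rep(names(cat), vapply(blocks, ncol, 0L))
  P <- Z / sum(Z)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > max(sv$d, 1e-300) * 1e-10
  d <- sv$d[pos]
  if (!length(d)) {
    # perfectly independent columns: P = r c' exactly, no structure
    warning("no non-trivial MCA axes (columns are independent)")
    out <- new_reduced_scores(
      matrix(0, n, 0), matrix(0, 0, 0), numeric(0),
      stats::setNames(rep(0, ncol(cat)), names(cat)), site, "mca", dropped)
    out$sv_all <- sv$d
    return(out)
  }
  explained_all <- d^2 / sum(d^2)
  k_eff <- min(k, length(d))
  if (k_eff < k)
    warning(sprintf("only %d non-trivial MCA axes available", k_eff))
  idx <- seq_len(k_eff)
  # principal coordinates
  row_sc <- sweep(sv$u[, pos, drop = FALSE][, idx, drop = FALSE] %*%
                    diag(d[idx], k_eff), 1, sqrt(r), "/")
  col_sc <- sweep(sv$v[, pos, drop = FALSE][, idx, drop = FALSE] %*%
                    diag(d[idx], k_eff), 1, sqrt(cc), "/")
  rownames(col_sc) <- colnames(Z)
  colnames(row_sc) <- colnames(col_sc) <- paste0("Axis", idx)
  sgn <- fix_signs(col_sc, row_sc)
  col_sc <- sgn$loadings; row_sc <- sgn$scores
  # category contribution on axis a: mass * coord^2 / inertia of the axis;
  # aggregated to the parent variable, weighted by explained inertia
  ctr <- sapply(idx, function(a) cc * col_sc[, a]^2 / d[a]^2)
  ctr <- matrix(ctr, ncol = k_eff)
  var_ctr <- rowsum(ctr, var_of_cat, reorder = FALSE)
  contrib <- drop(var_ctr %*% explained_all[idx])
  names(contrib) <- rownames(var_ctr)
  if (length(dropped)) {
    z <- stats::setNames(rep(0, length(dropped)), dropped)
    all_names <- c(names(contrib), dropped)
    contrib <- c(contrib, z)
  }
  out <- new_reduced_scores(row_sc, col_sc, explained_all[idx], contrib,
                            site, "mca", dropped)
  out$sv_all <- sv$d
  out
}

#' Rank variables by their contribution to the retained axes
#'
#' The contribution of a variable is the sum over retained axes of the
#' axis's explained variance (inertia) fraction times the variable's
#' squared loading on it (for MCA, its categories' summed contributions).
#' This is the standard contribution measure used to read off the most
#' influential questionnaire items from a PCA or MCA.
#'
#' @param r a `"reduced_scores"` object.
#' @param k_vars how many variables to return (default 20).
#' @return data.frame with columns `id` and `contribution`, in descending
#'   contribution order; ties keep the earlier codebook order. If `k_vars`
#'   exceeds the number of variables, all are returned with a warning.
#' @export
top_contributors <- function(r, k_vars = 20L) {
  stopifnot(inherits(r, "reduced_scores"))
  ctr <- r$contributions
  if (k_vars > length(ctr)) {
    warning(sprintf("k_vars = %d exceeds the %d available variables",
                    k_vars, length(ctr)))
    k_vars <- length(ctr)
  }
  ord <- order(-ctr, seq_along(ctr))
  data.frame(id = names(ctr)[ord][seq_len(k_vars)],
             contribution = unname(ctr[ord][seq_len(k_vars)]),
             stringsAsFactors = FALSE)
}
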