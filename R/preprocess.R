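# Values-branch preprocessing: variable exclusion, numeric encoding and
# chained-equations imputation.

#' Select analyzable variables
#'
#' Text and multiple-choice questions are excluded from the values
#' analysis; categorical, ordinal and continuous variables are retained in
#' codebook order.
#'
#' @param cb a [codebook()].
#' @return character vector of variable ids.
#' @export
select_analyzable <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  keep <- vapply(cb, function(v)
    v$vtype %in% c("categorical", "ordinal", "continuous"), TRUE)
  names(cb)[keep]
}

#' Encode a dataset as a numeric matrix with a missingness mask
#'
#' Categorical/ordinal cells map to the 0-based index of their label in
#' the declared category order; continuous cells are parsed as numbers;
#' blanks get mask `TRUE` and a placeholder value of `NA` that is never
#' used in computation.
#'
#' @param ds an [msv_dataset()].
#' @param cb a [codebook()]; defaults to the dataset's own.
#' @param ids variables to encode; defaults to [select_analyzable()] ids
#'   present in the dataset.
#' @return object of class `"encoded_matrix"`: list with `values` (n x p
#'   numeric), `mask` (n x p logical), `columns` (data.frame of id, vtype,
#'   n_levels, section), `site` (per-row site label) and `levels` (the
#'   category order per encoded column).
#' @export
encode <- function(ds, cb = attr(ds, "codebook"), ids = NULL) {
  stopifnot(inherits(ds, "msv_dataset"))
  if (is.null(ids))
    ids <- intersect(select_analyzable(cb), setdiff(names(ds),
                                                    attr(ds, "site_col")))
  if (!length(ids))
    stop_msvdq("no analyzable variables to encode", "msvdq_encode_error")
  n <- nrow(ds)
  values <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    v <- cb[[ids[j]]]
    cell <- ds[[ids[j]]]
    if (v$vtype == "continuous") {
      num <- suppressWarnings(as.numeric(cell))
      bad <- which(!is.na(cell) & is.na(num))
      if (length(bad))
        stop_msvdq(sprintf(
          "unparseable numeric '%s' at (row %d, column %s)",
          cell[bad[1L]], bad[1L], ids[j]), "msvdq_encode_error")
      values[, j] <- num
    } else {
      values[, j] <- match(cell, v$categories) - 1
    }
  }
  columns <- data.frame(
    id = ids,
    vtype = vapply(ids, function(i) cb[[i]]$vtype, ""),
    n_levels = vapply(ids, function(i) length(cb[[i]]$categories), 0L),
    section = vapply(ids, function(i) cb[[i]]$section, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(values = values, mask = is.na(values), columns = columns,
                 site = dataset_sites(ds),
                 levels = lapply(ids, function(i) cb[[i]]$categories)),
            class = "encoded_matrix")
}

# One ridge regression: y ~ intercept + X with L2 penalty on the slopes
# only. Returns the fitted coefficient vector c(intercept, slopes).
ridge_fit <- function(X, y, lambda) {
  Xa <- cbind(1, X)
  G <- crossprod(Xa) + diag(c(0, rep(lambda, ncol(X))))
  b <- tryCatch(solve(G, crossprod(Xa, y)),
                error = function(e) stop_msvdq(
                  "singular design in chained imputation; use ridge_lambda > 0",
                  "msvdq_impute_error"))
  drop(b)
}

#' Chained-equations imputation with ridge regressions
#'
#' Iterative multivariate imputation: missing cells are initialized with
#' the column mean over observed cells; then, sweeping incomplete columns
#' in ascending order of missing count (ties broken by column order), each
#' incomplete column is regressed on all the others (current imputations
#' filled in) with an L2-shrinkage linear fit on the rows where it is
#' observed, and its missing cells are overwritten with the predictions.
#' Sweeps stop when the largest absolute change of any imputed cell falls
#' below `tol` times its column's observed-cell SD, or at `max_iter`. The
#' fit pools the rows of all sites. The algorithm is deterministic; `seed`
#' is accepted for run-manifest compatibility only. Categorical/ordinal
#' columns are finally rounded to the nearest valid code.
#'
#' @param m an [encode()]d matrix.
#' @param max_iter maximum number of sweeps (default 10).
#' @param tol relative convergence tolerance (default 1e-3).
#' @param ridge_lambda L2 penalty on regression slopes (default 1e-3).
#' @param seed unused; recorded for manifests.
#' @return an `"encoded_matrix"` with no missing cells and an attribute
#'   `trace`: per-sweep maximum scaled change of imputed cells.
#' @export
impute_chained <- function(m, max_iter = 10L, tol = 1e-3,
                           ridge_lambda = 1e-3, seed = NULL) {
  stopifnot(inherits(m, "encoded_matrix"))
  V <- m$values
  M <- m$mask
  n <- nrow(V); p <- ncol(V)
  if (n < 2L)
    stop_msvdq("imputation needs n >= 2 rows", "msvdq_impute_error")
  n_miss <- colSums(M)
  if (any(n_miss == n))
    stop_msvdq(sprintf("column(s) entirely missing: %s",
                       paste(colnames(V)[n_miss == n], collapse = ", ")),
               "msvdq_impute_error")
  trace <- numeric(0)
  if (any(M)) {
    # mean initialization
    mu <- vapply(seq_len(p), function(j) mean(V[!M[, j], j]), 0)
    for (j in seq_len(p)) V[M[, j], j] <- mu[j]
    csd <- vapply(seq_len(p), function(j) {
      s <- stats::sd(m$values[!M[, j], j])
      if (!is.finite(s) || s == 0) 1 else s
    }, 0)
    order_j <- order(n_miss, seq_len(p))
    order_j <- order_j[n_miss[order_j] > 0L]
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in order_j) {
        obs <- !M[, j]
        b <- ridge_fit(V[obs, -j, drop = FALSE], V[obs, j], ridge_lambda)
        pred <- drop(cbind(1, V[!obs, -j, drop = FALSE]) %*% b)
        delta <- max(delta, max(abs(pred - V[!obs, j]) / csd[j]))
        V[!obs, j] <- pred
      }
      trace <- c(trace, delta)
      if (delta < tol) break
    }
    # snap categorical/ordinal imputations back onto valid codes
    for (j in seq_len(p)) {
      if (m$columns$vtype[j] == "continuous" || !any(M[, j])) next
      L <- m$columns$n_levels[j]
      V[M[, j], j] <- pmin(pmax(round(V[M[, j], j]), 0), L - 1)
    }
  }
  out <- m
  out$values <- V
  out$mask <- matrix(FALSE, n, p, dimnames = dimnames(M))
  attr(out, "trace") <- trace
  out
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("Encoded matrix: %d x %d (%.1f%% masked)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}
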