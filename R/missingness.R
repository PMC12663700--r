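# Completeness branch front end: classify every cell as ordinary missing
# (0), dependent / not-applicable missing (1) or non-missing (2), and
# summarize completeness overall, per site, per section and per variable.

MISSING_LABELS <- c(`0` = "ordinary", `1` = "not_applicable", `2` = "observed")

#' Categorize cells into ordinary / not-applicable / observed
#'
#' Non-blank cells get code 2. A blank cell in a branch-gated column whose
#' parent is observed gets code 1 when the parent's value is outside the
#' activating set (the question did not apply) and code 0 otherwise. When
#' the parent is itself blank, the child inherits code 1 if the parent's
#' own code is 1 (a definitely-not-applicable chain cascades); any other
#' blank-parent child is code 0 under the default cascade -- its
#' applicability is unknowable and coding it ordinary never understates a
#' data-collection fault. `cascade = "ordinary"` instead codes every
#' blank-parent child 0.
#'
#' @param ds an [msv_dataset()].
#' @param cb a [codebook()]; defaults to the dataset's own.
#' @param cascade `"inherit"` (default) or `"ordinary"` (see above).
#' @return object of class `"missing_matrix"`: n x p integer matrix of
#'   codes in \{0, 1, 2\} with variable-id columns, plus attributes
#'   `site` and `codebook`.
#' @export
categorize <- function(ds, cb = attr(ds, "codebook"),
                       cascade = c("inherit", "ordinary")) {
  stopifnot(inherits(ds, "msv_dataset"))
  cascade <- match.arg(cascade)
  ids <- setdiff(names(ds), attr(ds, "site_col"))
  n <- nrow(ds)
  codes <- matrix(2L, n, length(ids), dimnames = list(NULL, ids))
  cache <- new.env(parent = emptyenv())
  col_codes <- function(id, depth = 0L) {
    if (depth > 10L)
      stop_msvdq(sprintf("branch chain deeper than 10 at '%s'; suspected cycle",
                         id), "msvdq_missing_error")
    if (!is.null(cache[[id]])) return(cache[[id]])
    cell <- ds[[id]]
    out <- rep(2L, n)
    blank <- is.na(cell)
    br <- cb[[id]]$branch
    if (is.null(br)) {
      out[blank] <- 0L
    } else {
      pcell <- ds[[br$parent]]
      pcode <- col_codes(br$parent, depth + 1L)
      not_applicable <- (!is.na(pcell) & !pcell %in% br$values) |
        (cascade == "inherit" & is.na(pcell) & pcode == 1L)
      out[blank & not_applicable] <- 1L
      out[blank & !not_applicable] <- 0L
    }
    cache[[id]] <- out
    out
  }
  for (id in ids) codes[, id] <- col_codes(id)
  structure(codes, site = dataset_sites(ds), codebook = cb,
            class = c("missing_matrix", "matrix"))
}

pct1 <- function(count, total) round_half_away(100 * count / total, 1)

#' Completeness summary of a missing-category matrix
#'
#' Counts and percentage shares of each code (0 = ordinary missing,
#' 1 = not-applicable missing, 2 = observed), overall and sliced per
#' site, per section, per variable and per site-by-section cell. Shares
#' are reported to 1 decimal (rounding half away from zero); the overall
#' observed share is additionally given in whole-percent style.
#'
#' @param m a [categorize()] result.
#' @return object of class `"completeness_summary"`: list of data.frames
#'   `overall`, `by_site`, `by_section`, `by_variable`,
#'   `by_site_section`.
#' @export
completeness_summary <- function(m) {
  stopifnot(inherits(m, "missing_matrix"))
  site <- attr(m, "site")
  cb <- attr(m, "codebook")
  section <- vapply(colnames(m), function(id) cb[[id]]$section, "")
  slice <- function(rows, cols) {
    sub <- m[rows, cols, drop = FALSE]
    tot <- length(sub)
    cnt <- vapply(0:2, function(k) sum(sub == k), 0L)
    data.frame(total = tot,
               n_ordinary = cnt[1L], n_not_applicable = cnt[2L],
               n_observed = cnt[3L],
               pct_ordinary = pct1(cnt[1L], tot),
               pct_not_applicable = pct1(cnt[2L], tot),
               pct_observed = pct1(cnt[3L], tot))
  }
  all_rows <- seq_len(nrow(m)); all_cols <- seq_len(ncol(m))
  overall <- slice(all_rows, all_cols)
  overall$pct_observed_whole <- round_half_away(
    100 * overall$n_observed / overall$total, 0)
  by_site <- do.call(rbind, lapply(unique(site), function(s)
    cbind(site = s, slice(site == s, all_cols))))
  by_section <- do.call(rbind, lapply(unique(section), function(sec)
    cbind(section = sec, slice(all_rows, section == sec))))
  by_variable <- do.call(rbind, lapply(colnames(m), function(id)
    cbind(id = id, section = section[[id]], slice(all_rows, id))))
  by_site_section <- do.call(rbind, lapply(unique(site), function(s)
    do.call(rbind, lapply(unique(section), function(sec)
      cbind(site = s, section = sec, slice(site == s, section == sec))))))
  rownames(by_site) <- rownames(by_section) <- rownames(by_variable) <-
    rownames(by_site_section) <- NULL
  structure(list(overall = overall, by_site = by_site,
                 by_section = by_section, by_variable = by_variable,
                 by_site_section = by_site_section),
            class = "completeness_summary")
}

#' @export
print.completeness_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Completeness: %d cells; %d (%.0f%%) observed, %d (%.1f%%) not applicable, %d (%.1f%%) ordinary missing\n",
    o$total, o$n_observed, o$pct_observed_whole,
    o$n_not_applicable, o$pct_not_applicable,
    o$n_ordinary, o$pct_ordinary))
  cat("\nPer site:\n")
  print(x$by_site, row.names = FALSE)
  invisible(x)
}

#' Missing-category matrix as a categorical table for MCA
#'
#' Codes become the three-level categorical values `"ordinary"`,
#' `"not_applicable"`, `"observed"`. Columns with a single observed level
#' are flagged (attribute `constant`) for MCA's constant-column drop.
#'
#' @param m a [categorize()] result.
#' @return data.frame of character columns with attributes `constant`
#'   (named logical) and `site`.
#' @export
to_categorical_table <- function(m) {
  stopifnot(inherits(m, "missing_matrix"))
  df <- as.data.frame(matrix(MISSING_LABELS[as.character(m)], nrow(m),
                             dimnames = dimnames(m)),
                      stringsAsFactors = FALSE)
  constant <- vapply(df, function(x) length(unique(x)) < 2L, TRUE)
  structure(df, constant = constant, site = attr(m, "site"))
}
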