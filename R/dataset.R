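# Multi-site participant table: one row per participant, a site label,
# one column per question, blanks preserved as NA.

#' Construct a validated multi-site dataset
#'
#' @param data data.frame of character columns, one per codebook variable
#'   (blanks as `NA`), plus the site column.
#' @param cb a [codebook()].
#' @param site_col name of the site column (default `"site"`).
#' @return object of class `"msv_dataset"`: the data.frame with attributes
#'   `site_col` and `codebook`.
#' @export
msv_dataset <- function(data, cb, site_col = "site") {
  stopifnot(is.data.frame(data), inherits(cb, "codebook"))
  if (!site_col %in% names(data))
    stop_msvdq(sprintf("site column '%s' not found", site_col),
               "msvdq_dataset_error")
  if (nrow(data) == 0L)
    stop_msvdq("no records", "msvdq_dataset_error")
  qcols <- setdiff(names(data), site_col)
  unknown <- setdiff(qcols, names(cb))
  if (length(unknown))
    stop_msvdq(sprintf("column(s) not in codebook: %s",
                       paste(unknown, collapse = ", ")),
               "msvdq_dataset_error")
  if (anyNA(data[[site_col]]))
    stop_msvdq("missing site labels", "msvdq_dataset_error")
  data[qcols] <- lapply(data[qcols], as.character)
  # categorical/ordinal cells must be declared categories
  for (id in qcols) {
    v <- cb[[id]]
    if (!v$vtype %in% c("categorical", "ordinal")) next
    cell <- data[[id]]
    bad <- which(!is.na(cell) & !cell %in% v$categories)
    if (length(bad))
      stop_msvdq(sprintf(
        "invalid category '%s' at (row %d, column %s)",
        cell[bad[1L]], bad[1L], id), "msvdq_dataset_error")
  }
  structure(data, site_col = site_col, codebook = cb,
            class = c("msv_dataset", "data.frame"))
}

#' Read a multi-site dataset from CSV
#'
#' The CSV must have a header row, one row per participant and a site
#' column. Cells equal to one of `na_values` (default empty string and
#' `"NA"`; the blank encoding of questionnaire exports varies, so the
#' sentinel list is configurable) are treated as missing. All cells are
#' read as text; numeric parsing of continuous variables happens at
#' [encode()] time.
#'
#' @param path CSV file path (UTF-8).
#' @param cb a [codebook()].
#' @param site_col name of the site column (default `"site"`).
#' @param na_values character vector of cell values mapped to missing.
#' @return an [msv_dataset()].
#' @export
load_dataset <- function(path, cb, site_col = "site",
                         na_values = c("", "NA")) {
  if (!file.exists(path))
    stop_msvdq(sprintf("dataset file not found: %s", path), "msvdq_io_error")
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8"),
    error = function(e) stop_msvdq(
      sprintf("could not parse CSV: %s", conditionMessage(e)),
      "msvdq_io_error"))
  if (nrow(df) == 0L)
    stop_msvdq("no records", "msvdq_dataset_error")
  qcols <- setdiff(names(df), site_col)
  df[qcols] <- lapply(df[qcols], function(x) {
    x[x %in% na_values] <- NA_character_
    x
  })
  msv_dataset(df, cb, site_col = site_col)
}

#' Write a multi-site dataset to CSV
#'
#' Blanks are written as empty cells, so
#' `load_dataset(write_dataset(ds, f), ...)` round-trips cell values and
#' blank positions exactly.
#'
#' @param ds an [msv_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "msv_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Site labels of a dataset
#' @param ds an [msv_dataset()].
#' @return character vector, one entry per row.
#' @export
dataset_sites <- function(ds) {
  as.character(ds[[attr(ds, "site_col")]])
}

#' @export
print.msv_dataset <- function(x, ...) {
  sites <- table(dataset_sites(x))
  cat(sprintf("Multi-site dataset: %d participants, %d question(s), %d site(s)\n",
              nrow(x), ncol(x) - 1L, length(sites)))
  cat(" ", paste(sprintf("%s (n=%d)", names(sites), sites), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-site demographic summary
#'
#' Reproduces the usual multicenter cohort table: per-site n with its
#' percentage share of the total, age mean and SD (sample, n-1
#' denominator), and counts/shares per sex category. Shares are shown to 1
#' decimal, rounding half away from zero. A site with no non-missing ages
#' gets `NA` age fields rather than an error.
#'
#' @param ds an [msv_dataset()].
#' @param age_var id of a continuous age variable.
#' @param sex_var id of a categorical sex variable.
#' @return data.frame with one row per site plus a `"Total"` row.
#' @export
summarize_demographics <- function(ds, age_var, sex_var) {
  stopifnot(inherits(ds, "msv_dataset"))
  cb <- attr(ds, "codebook")
  if (!age_var %in% names(cb) || cb[[age_var]]$vtype != "continuous")
    stop_msvdq(sprintf("'%s' is not a continuous codebook variable", age_var),
               "msvdq_dataset_error")
  if (!sex_var %in% names(cb) || cb[[sex_var]]$vtype != "categorical")
    stop_msvdq(sprintf("'%s' is not a categorical codebook variable", sex_var),
               "msvdq_dataset_error")
  site <- dataset_sites(ds)
  sites <- unique(site)
  age <- suppressWarnings(as.numeric(ds[[age_var]]))
  sex <- ds[[sex_var]]
  cats <- cb[[sex_var]]$categories
  n_total <- nrow(ds)
  one <- function(keep, label) {
    n <- sum(keep)
    a <- age[keep]
    a <- a[!is.na(a)]
    row <- data.frame(
      site = label, n = n,
      share = round_half_away(100 * n / n_total, 1),
      age_mean = if (length(a)) mean(a) else NA_real_,
      age_sd = if (length(a) > 1L) stats::sd(a) else NA_real_,
      stringsAsFactors = FALSE)
    for (ct in cats) {
      cnt <- sum(sex[keep] == ct, na.rm = TRUE)
      row[[paste0(ct, "_n")]] <- cnt
      row[[paste0(ct, "_pct")]] <- round_half_away(100 * cnt / n, 1)
    }
    row
  }
  out <- do.call(rbind, lapply(sites, function(s) one(site == s, s)))
  out <- rbind(out, one(rep(TRUE, n_total), "Total"))
  rownames(out) <- NULL
  out
}
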