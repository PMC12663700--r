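# Orchestration of the two analysis branches (values, completeness),
# globally and per questionnaire section.

#' Analysis configuration
#'
#' Resolved parameter snapshot for the pipeline; all defaults follow the
#' package's documented conventions.
#'
#' @param impute_max_iter,impute_tol,impute_ridge_lambda chained
#'   imputation controls (see [impute_chained()]).
#' @param reduce_k retained reduction axes (default 3).
#' @param reduce_top_vars contributor list length (default 20).
#' @param reduce_standardize correlation (vs covariance) PCA flag.
#' @param lof_k,lof_threshold,lof_max_removed_frac outlier filtering
#'   controls (see [filter_per_site()]).
#' @param hist_bins_per_dim histogram bins per dimension (default 10).
#' @param seed integer recorded in the run manifest.
#' @return a named list of class `"msvdq_config"`.
#' @export
msvdq_config <- function(impute_max_iter = 10L, impute_tol = 1e-3,
                         impute_ridge_lambda = 1e-3,
                         reduce_k = 3L, reduce_top_vars = 20L,
                         reduce_standardize = TRUE,
                         lof_k = 20L, lof_threshold = 1.5,
                         lof_max_removed_frac = 0.10,
                         hist_bins_per_dim = 10L, seed = 1L) {
  structure(list(
    impute_max_iter = impute_max_iter, impute_tol = impute_tol,
    impute_ridge_lambda = impute_ridge_lambda,
    reduce_k = reduce_k, reduce_top_vars = reduce_top_vars,
    reduce_standardize = reduce_standardize,
    lof_k = lof_k, lof_threshold = lof_threshold,
    lof_max_removed_frac = lof_max_removed_frac,
    hist_bins_per_dim = hist_bins_per_dim, seed = as.integer(seed)),
    class = "msvdq_config")
}

# Collect warnings raised by expr into the character vector named by
# `store` in the caller's environment, without aborting.
with_warnings <- function(expr, warnings_env) {
  withCallingHandlers(expr, warning = function(w) {
    warnings_env$log <- c(warnings_env$log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

# Shared tail of both branches: per-site filtering in the reduced space,
# shared-edge histograms, and the MSV metrics.
metric_tail <- function(red, config, bins_per_dim, wenv) {
  flt <- with_warnings(
    filter_per_site(red, k_neighbors = config$lof_k,
                    threshold = config$lof_threshold,
                    max_removed_frac = config$lof_max_removed_frac),
    wenv)
  kept <- flt$scores
  pts <- split.data.frame(kept$scores, kept$site)
  dens <- with_warnings(align_densities(pts, bins_per_dim), wenv)
  list(msv = msv(dens), densities = dens, outliers = flt$report)
}

# Bins per dimension capped so the total grid stays at <= 1000 cells when
# low-dimensional sections are binned directly.
bins_for_dims <- function(bins_per_dim, n_dims) {
  min(bins_per_dim, max(2L, floor(1000^(1 / n_dims))))
}

#' Values-branch analysis of one scope
#'
#' Stage order: analyzable-variable selection, numeric encoding, chained
#' imputation (always on the full analyzable matrix, pooled across sites,
#' so every section sees the same completed data), restriction to the
#' scoped section, PCA to `reduce_k` dimensions, per-site LOF filtering,
#' shared-edge histograms and the MSV metrics. A section with 3 or fewer
#' analyzable variables skips the reduction and is binned directly on its
#' encoded variables (bins per dimension capped to keep the grid at 1000
#' cells or fewer).
#'
#' @param ds an [msv_dataset()].
#' @param cb a [codebook()]; defaults to the dataset's own.
#' @param section section name or `"all"`.
#' @param config an [msvdq_config()].
#' @param imputed optional precomputed [impute_chained()] result for the
#'   full analyzable matrix (lets [run_hierarchical()] impute once).
#' @return list of class `"msv_scope"`: `branch`, `section`, `msv`,
#'   `contributors`, `biplot` (scores and loading arrows of the top
#'   contributors), `outliers`, `warnings`, `skipped`/`reason`.
#' @export
run_values_analysis <- function(ds, cb = attr(ds, "codebook"),
                                section = "all",
                                config = msvdq_config(),
                                imputed = NULL) {
  wenv <- new.env(); wenv$log <- character()
  ids_all <- intersect(select_analyzable(cb),
                       setdiff(names(ds), attr(ds, "site_col")))
  ids <- if (identical(section, "all")) ids_all
         else intersect(ids_all, codebook_ids(cb, section))
  if (!length(ids))
    return(scope_skipped("values", section, "no analyzable variables"))
  if (is.null(imputed)) {
    enc <- encode(ds, cb, ids = ids_all)
    imputed <- impute_chained(enc, max_iter = config$impute_max_iter,
                              tol = config$impute_tol,
                              ridge_lambda = config$impute_ridge_lambda)
  }
  sub <- imputed
  keep <- match(ids, sub$columns$id)
  sub$values <- sub$values[, keep, drop = FALSE]
  sub$mask <- sub$mask[, keep, drop = FALSE]
  sub$columns <- sub$columns[keep, , drop = FALSE]
  sub$levels <- sub$levels[keep]
  if (length(ids) > 3L) {
    red <- with_warnings(
      pca_reduce(sub, k = config$reduce_k,
                 standardize = config$reduce_standardize), wenv)
    bins <- config$hist_bins_per_dim
    contributors <- with_warnings(
      top_contributors(red, config$reduce_top_vars), wenv)
    biplot <- list(scores = red$scores[, 1:min(2L, ncol(red$scores)),
                                       drop = FALSE],
                   arrows = red$loadings[
                     intersect(contributors$id, rownames(red$loadings)),
                     1:min(2L, ncol(red$loadings)), drop = FALSE],
                   site = red$site)
  } else {
    # direct binning of the encoded variables, no reduction
    red <- new_reduced_scores(sub$values, NULL, numeric(), NULL,
                              sub$site, "none")
    bins <- bins_for_dims(config$hist_bins_per_dim, ncol(sub$values))
    contributors <- NULL
    biplot <- NULL
  }
  tail <- metric_tail(red, config, bins, wenv)
  structure(list(branch = "values", section = section, skipped = FALSE,
                 msv = tail$msv, contributors = contributors,
                 biplot = biplot, outliers = tail$outliers,
                 densities = tail$densities, flags = character(),
                 warnings = wenv$log),
            class = "msv_scope")
}

scope_skipped <- function(branch, section, reason) {
  structure(list(branch = branch, section = section, skipped = TRUE,
                 reason = reason, msv = NULL, contributors = NULL,
                 warnings = character(), flags = character()),
            class = "msv_scope")
}

#' Completeness-branch analysis of one scope
#'
#' Stage order: three-category missing classification, categorical table,
#' MCA to `reduce_k` axes, per-site LOF filtering, shared-edge histograms
#' and the MSV metrics. A scope whose category table is entirely constant
#' (no missingness anywhere) yields GPD = 0 with all SPO = 0 and the
#' `"no-missingness"` flag.
#'
#' @param ds an [msv_dataset()].
#' @param cb a [codebook()]; defaults to the dataset's own.
#' @param section section name or `"all"`.
#' @param config an [msvdq_config()].
#' @param mm optional precomputed [categorize()] matrix.
#' @return an `"msv_scope"` (see [run_values_analysis()]).
#' @export
run_completeness_analysis <- function(ds, cb = attr(ds, "codebook"),
                                      section = "all",
                                      config = msvdq_config(),
                                      mm = NULL) {
  wenv <- new.env(); wenv$log <- character()
  if (is.null(mm)) mm <- categorize(ds, cb)
  ids <- if (identical(section, "all")) colnames(mm)
         else intersect(colnames(mm), codebook_ids(cb, section))
  if (!length(ids))
    return(scope_skipped("completeness", section, "no variables in scope"))
  sub <- mm[, ids, drop = FALSE]
  attr(sub, "site") <- attr(mm, "site")
  attr(sub, "codebook") <- attr(mm, "codebook")
  class(sub) <- class(mm)
  tab <- to_categorical_table(sub)
  site <- attr(tab, "site")
  if (all(attr(tab, "constant"))) {
    sites <- unique(site)
    zero <- structure(list(
      gpd = 0, spo = stats::setNames(rep(0, length(sites)), sites),
      distances = NULL, embedding = NULL, plot_coords = NULL,
      radii = NULL, weights = as.vector(table(site)[sites]),
      n_sources = length(sites)), class = "msv")
    return(structure(list(branch = "completeness", section = section,
                          skipped = FALSE, msv = zero, contributors = NULL,
                          outliers = NULL, flags = "no-missingness",
                          warnings = wenv$log),
                     class = "msv_scope"))
  }
  red <- with_warnings(mca_reduce(tab, k = config$reduce_k, site = site),
                       wenv)
  contributors <- with_warnings(
    top_contributors(red, min(config$reduce_top_vars,
                              length(red$contributions))), wenv)
  bins <- if (ncol(red$scores) < 3L)
    bins_for_dims(config$hist_bins_per_dim, ncol(red$scores))
  else config$hist_bins_per_dim
  tail <- metric_tail(red, config, bins, wenv)
  structure(list(branch = "completeness", section = section, skipped = FALSE,
                 msv = tail$msv, contributors = contributors,
                 biplot = list(scores = red$scores[, 1:min(2L, ncol(red$scores)),
                                                   drop = FALSE], site = site),
                 outliers = tail$outliers, densities = tail$densities,
                 flags = character(), warnings = wenv$log),
            class = "msv_scope")
}

#' @export
print.msv_scope <- function(x, ...) {
  cat(sprintf("[%s | %s] ", x$branch, x$section))
  if (x$skipped) {
    cat("skipped:", x$reason, "\n")
  } else {
    cat(sprintf("GPD = %.3f%s\n", x$msv$gpd,
                if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

#' Hierarchical top-down analysis: both branches, global and per section
#'
#' Runs the values and completeness branches for the whole questionnaire
#' and for every section, imputing once on the full analyzable matrix and
#' classifying missingness once. Scope failures are recorded and do not
#' abort the run.
#'
#' @param ds an [msv_dataset()].
#' @param cb a [codebook()]; defaults to the dataset's own.
#' @param config an [msvdq_config()].
#' @return object of class `"msvdq_report"`: list of `"msv_scope"`
#'   results keyed `"<branch>:<section>"`, plus a `manifest` (package
#'   version, parameters, seed, accumulated warnings) sufficient to
#'   reproduce the run.
#' @export
run_hierarchical <- function(ds, cb = attr(ds, "codebook"),
                             config = msvdq_config()) {
  enc <- encode(ds, cb)
  imputed <- impute_chained(enc, max_iter = config$impute_max_iter,
                            tol = config$impute_tol,
                            ridge_lambda = config$impute_ridge_lambda)
  mm <- categorize(ds, cb)
  scopes <- list()
  secs <- c("all", codebook_sections(cb))
  for (sec in secs) {
    scopes[[paste0("values:", sec)]] <- tryCatch(
      run_values_analysis(ds, cb, sec, config, imputed = imputed),
      error = function(e) scope_skipped("values", sec, conditionMessage(e)))
  }
  for (sec in secs) {
    scopes[[paste0("completeness:", sec)]] <- tryCatch(
      run_completeness_analysis(ds, cb, sec, config, mm = mm),
      error = function(e) scope_skipped("completeness", sec,
                                        conditionMessage(e)))
  }
  manifest <- list(
    package = "msvdq",
    version = as.character(utils::packageVersion("msvdq")),
    parameters = unclass(config),
    seed = config$seed,
    sections = codebook_sections(cb),
    n_rows = nrow(ds),
    n_variables = length(cb),
    warnings = stats::setNames(
      lapply(scopes, function(s) s$warnings),
      names(scopes)))
  structure(list(scopes = scopes, manifest = manifest,
                 completeness = completeness_summary(mm)),
            class = "msvdq_report")
}

#' @export
print.msvdq_report <- function(x, ...) {
  cat("Multisource data-quality report\n")
  for (s in x$scopes) print(s)
  invisible(x)
}

#' Export a report bundle as JSON/CSV files
#'
#' Writes `metrics.json` (per-scope GPD/SPO/distances/plot data),
#' `completeness.json`, `contributors.csv` and `manifest.json` under
#' `dir`.
#'
#' @param report an [run_hierarchical()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "msvdq_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- lapply(report$scopes, function(s) {
    if (s$skipped)
      return(list(branch = s$branch, section = s$section, skipped = TRUE,
                  reason = s$reason))
    out <- list(branch = s$branch, section = s$section, skipped = FALSE,
                gpd = s$msv$gpd, spo = as.list(s$msv$spo),
                flags = s$flags)
    if (!is.null(s$msv$distances)) {
      out$distances <- unclass(s$msv$distances)
      out$plot <- list(coords = s$msv$plot_coords, radii = s$msv$radii)
    }
    out
  })
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(report$completeness),
                       file.path(dir, "completeness.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  ctr <- do.call(rbind, Filter(Negate(is.null),
    lapply(report$scopes, function(s) {
      if (s$skipped || is.null(s$contributors)) return(NULL)
      cbind(branch = s$branch, section = s$section, s$contributors)
    })))
  if (!is.null(ctr))
    utils::write.csv(ctr, file.path(dir, "contributors.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
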