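# Synthetic multi-site questionnaire generator. Emulates the statistical
# structure the analysis pipeline assumes: site-specific distribution
# shifts, branch-gated (skip-logic) questions producing structurally
# not-applicable blanks, and ordinary missingness (MCAR or MNAR) on top.

#' Configure a synthetic multi-site questionnaire study
#'
#' @param sites data.frame with columns `label` and `n` (participants per
#'   site), all `n >= 1`.
#' @param sections list of section descriptors, each a list with `name`,
#'   `n_vars` (total variables in the section) and optionally `n_gated`
#'   (number of parent/child skip-logic pairs; each pair consumes two of
#'   `n_vars`) and `type_mix` (character vector of types cycled over the
#'   non-gated variables; default `c("categorical","ordinal","continuous")`).
#' @param missing_rate default per-cell ordinary-missingness probability,
#'   applied to every (site, section) unless overridden.
#' @param missing_overrides optional data.frame with columns `site`,
#'   `section`, `rate` overriding the default for specific cells of the
#'   site-by-section grid.
#' @param shifts optional list of shift descriptors, each a list with
#'   `site`, and either `sections` or `variables` naming what is affected,
#'   plus `delta` (continuous/ordinal latent mean shift in SD units, >= 0)
#'   and/or `alpha` (Dirichlet concentration for per-site categorical
#'   probability perturbation, > 0; larger alpha = smaller perturbation).
#' @param gate_activation probability that a gate parent answers its
#'   activating value (so a fraction `1 - gate_activation` of gated child
#'   cells is structurally not applicable).
#' @param mnar_strength coefficient linking the log-odds of ordinary
#'   missingness to the standardized (unobserved) cell value; 0 = MCAR.
#' @param seed master integer seed. Every (site, variable, channel) triple
#'   gets its own stream derived from it by counter-based splitting, so
#'   adding a variable never perturbs the draws of the others.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(sites, sections,
                       missing_rate = 0,
                       missing_overrides = NULL,
                       shifts = list(),
                       gate_activation = 0.63,
                       mnar_strength = 0,
                       seed = 1L) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("label", "n") %in% names(sites)))
  if (any(sites$n < 1))
    stop_msvdq("every site needs n >= 1", "msvdq_config_error")
  sec_names <- vapply(sections, `[[`, "", "name")
  if (anyDuplicated(sec_names))
    stop_msvdq("duplicated section names", "msvdq_config_error")
  rates <- c(missing_rate,
             if (!is.null(missing_overrides)) missing_overrides$rate)
  if (any(rates < 0 | rates > 1))
    stop_msvdq("missingness rates must lie in [0, 1]", "msvdq_config_error")
  if (gate_activation < 0 || gate_activation > 1)
    stop_msvdq("gate_activation must lie in [0, 1]", "msvdq_config_error")
  for (sh in shifts) {
    if (!sh$site %in% sites$label)
      stop_msvdq(sprintf("shift configured for unknown site '%s'", sh$site),
                 "msvdq_config_error")
    if (!is.null(sh$delta) && sh$delta < 0)
      stop_msvdq("shift delta must be >= 0", "msvdq_config_error")
    if (!is.null(sh$alpha) && sh$alpha <= 0)
      stop_msvdq("shift alpha must be > 0", "msvdq_config_error")
    if (!is.null(sh$sections)) {
      bad <- setdiff(sh$sections, sec_names)
      if (length(bad))
        stop_msvdq(sprintf("shift references unknown section(s): %s",
                           paste(bad, collapse = ", ")), "msvdq_config_error")
    }
  }
  if (!is.null(missing_overrides)) {
    bad <- setdiff(missing_overrides$site, sites$label)
    if (length(bad))
      stop_msvdq(sprintf("missing_overrides references unknown site(s): %s",
                         paste(bad, collapse = ", ")), "msvdq_config_error")
  }
  structure(list(sites = sites, sections = sections,
                 missing_rate = missing_rate,
                 missing_overrides = missing_overrides,
                 shifts = shifts, gate_activation = gate_activation,
                 mnar_strength = mnar_strength, seed = as.integer(seed)),
            class = "sim_config")
}

# Build the codebook implied by a sim_config. Variables are Q1, Q2, ...
# in section order; each gated pair is a binary yes/no parent immediately
# followed by its child (branch on parent == "yes").
sim_codebook <- function(config) {
  specs <- list()
  q <- 0L
  for (sec in config$sections) {
    n_gated <- sec$n_gated %||% 0L
    mix <- sec$type_mix %||% c("categorical", "ordinal", "continuous")
    n_free <- sec$n_vars - 2L * n_gated
    if (n_free < 0L)
      stop_msvdq(sprintf("section '%s': n_gated pairs exceed n_vars", sec$name),
                 "msvdq_config_error")
    child_types <- rep_len(c("ordinal", "continuous", "categorical"),
                           max(n_gated, 1L))
    for (g in seq_len(n_gated)) {
      q <- q + 1L
      parent_id <- paste0("Q", q)
      specs[[length(specs) + 1L]] <- variable_spec(
        parent_id, sec$name, "categorical", categories = c("no", "yes"))
      q <- q + 1L
      ct <- child_types[g]
      specs[[length(specs) + 1L]] <- variable_spec(
        paste0("Q", q), sec$name, ct,
        categories = if (ct == "continuous") character()
                     else paste0(substr(ct, 1, 1), 1:4),
        branch = list(parent = parent_id, values = "yes"))
    }
    for (j in seq_len(n_free)) {
      q <- q + 1L
      ty <- rep_len(mix, n_free)[j]
      L <- c(categorical = 3L, ordinal = 5L)[ty]
      specs[[length(specs) + 1L]] <- variable_spec(
        paste0("Q", q), sec$name, ty,
        categories = if (ty %in% c("categorical", "ordinal"))
          paste0(substr(ty, 1, 1), seq_len(L)) else character())
    }
  }
  codebook(specs)
}

# Base category probabilities: mildly skewed (proportional to L..1) so the
# distribution is not flat; gate parents use (1 - gate_activation,
# gate_activation) on (no, yes).
sim_base_probs <- function(v, config) {
  L <- length(v$categories)
  if (identical(v$categories, c("no", "yes")))
    return(c(1 - config$gate_activation, config$gate_activation))
  p <- rev(seq_len(L)) + 1
  p / sum(p)
}

sim_rate <- function(config, site, section) {
  ov <- config$missing_overrides
  if (!is.null(ov)) {
    hit <- which(ov$site == site & ov$section == section)
    if (length(hit)) return(ov$rate[hit[1L]])
  }
  config$missing_rate
}

sim_shift <- function(config, site, var_id, section) {
  delta <- 0; alpha <- Inf
  for (sh in config$shifts) {
    if (sh$site != site) next
    hit <- (!is.null(sh$variables) && var_id %in% sh$variables) ||
           (!is.null(sh$sections) && section %in% sh$sections)
    if (!hit) next
    if (!is.null(sh$delta)) delta <- delta + sh$delta
    if (!is.null(sh$alpha)) alpha <- min(alpha, sh$alpha)
  }
  list(delta = delta, alpha = alpha)
}

#' Generate a synthetic multi-site dataset
#'
#' Deterministic given the config seed. Continuous variables are drawn from
#' a standard normal with the site mean shifted by `delta` SD units where a
#' shift is configured; ordinal variables threshold a latent normal at the
#' base distribution's quantile cut points (so `delta` shifts ordinals
#' too); categorical site probabilities are drawn once per (site,
#' variable) from `Dirichlet(alpha * base)` where `alpha` is configured.
#' Branch-gated children are blank whenever the parent's drawn value is
#' outside the activating set (structurally not-applicable blanks);
#' ordinary missingness is applied afterwards to the remaining cells,
#' MCAR or MNAR per `mnar_strength`.
#'
#' @param config a [sim_config()].
#' @return list of class `"msv_simulation"` with elements `dataset` (an
#'   [msv_dataset()]), `codebook`, `truth` (ground-truth record: logical
#'   matrices `structural` and `ordinary` marking injected blanks, plus a
#'   data.frame `shifts` of every injected effect) and `config`.
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cb <- sim_codebook(config)
  ids <- names(cb)
  sections <- vapply(cb, `[[`, "", "section")
  n_tot <- sum(config$sites$n)
  site_of_row <- rep(config$sites$label, config$sites$n)
  raw <- matrix(NA_character_, n_tot, length(ids),
                dimnames = list(NULL, ids))
  structural <- matrix(FALSE, n_tot, length(ids), dimnames = list(NULL, ids))
  ordinary <- matrix(FALSE, n_tot, length(ids), dimnames = list(NULL, ids))
  shift_log <- list()
  # standardized numeric view of the drawn values, for the MNAR mechanism
  zval <- matrix(0, n_tot, length(ids))

  for (s in seq_len(nrow(config$sites))) {
    site <- config$sites$label[s]
    n <- config$sites$n[s]
    rows <- which(site_of_row == site)
    for (j in seq_along(ids)) {
      v <- cb[[j]]
      sh <- sim_shift(config, site, v$id, v$section)
      if (sh$delta > 0 || is.finite(sh$alpha))
        shift_log[[length(shift_log) + 1L]] <- data.frame(
          site = site, variable = v$id, section = v$section,
          delta = sh$delta, alpha = sh$alpha)
      set.seed(stream_seed(config$seed, site, v$id, 1L))
      if (v$vtype == "continuous") {
        x <- stats::rnorm(n, mean = sh$delta, sd = 1)
        raw[rows, j] <- sprintf("%.6f", x)
        zval[rows, j] <- x - sh$delta
      } else if (v$vtype == "ordinal") {
        base <- sim_base_probs(v, config)
        cuts <- stats::qnorm(cumsum(base)[-length(base)])
        z <- stats::rnorm(n, mean = sh$delta, sd = 1)
        code <- findInterval(z, cuts) + 1L
        raw[rows, j] <- v$categories[code]
        zval[rows, j] <- scale(code)[, 1]
      } else if (v$vtype %in% c("categorical")) {
        base <- sim_base_probs(v, config)
        p <- base
        if (is.finite(sh$alpha)) {
          set.seed(stream_seed(config$seed, site, v$id, 3L))
          g <- stats::rgamma(length(base), shape = sh$alpha * base)
          p <- g / sum(g)
        }
        set.seed(stream_seed(config$seed, site, v$id, 1L))
        code <- sample.int(length(base), n, replace = TRUE, prob = p)
        raw[rows, j] <- v$categories[code]
        zs <- scale(code)[, 1]
        zval[rows, j] <- ifelse(is.nan(zs), 0, zs)
      } else if (v$vtype == "text") {
        raw[rows, j] <- paste0("free text ",
                               sample.int(.Machine$integer.max, n))
      } else { # multichoice
        opts <- c("optA", "optB", "optC", "optD")
        raw[rows, j] <- vapply(seq_len(n), function(i)
          paste(sample(opts, sample(1:3, 1)), collapse = ";"), "")
      }
    }
  }
  zval[is.na(zval) | is.nan(zval)] <- 0

  # structural (not-applicable) blanks from the drawn parent values,
  # resolved in codebook order so chains cascade
  for (j in seq_along(ids)) {
    br <- cb[[j]]$branch
    if (is.null(br)) next
    pj <- match(br$parent, ids)
    na_parent <- structural[, pj] |
      (!is.na(raw[, pj]) & !raw[, pj] %in% br$values)
    structural[na_parent, j] <- TRUE
    raw[na_parent, j] <- NA_character_
  }

  # ordinary missingness on the remaining cells
  for (s in seq_len(nrow(config$sites))) {
    site <- config$sites$label[s]
    rows <- which(site_of_row == site)
    for (j in seq_along(ids)) {
      rate <- sim_rate(config, site, sections[j])
      if (rate <= 0) next
      set.seed(stream_seed(config$seed, site, ids[j], 2L))
      u <- stats::runif(length(rows))
      pmiss <- if (config$mnar_strength == 0) rate else
        stats::plogis(stats::qlogis(rate) +
                        config$mnar_strength * zval[rows, j])
      hit <- u < pmiss & !structural[rows, j]
      ordinary[rows[hit], j] <- TRUE
      raw[rows[hit], j] <- NA_character_
    }
  }

  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  df$site <- site_of_row
  ds <- msv_dataset(df, cb, site_col = "site")
  truth <- list(
    structural = structural, ordinary = ordinary,
    shifts = if (length(shift_log)) do.call(rbind, shift_log) else
      data.frame(site = character(), variable = character(),
                 section = character(), delta = numeric(), alpha = numeric()))
  structure(list(dataset = ds, codebook = cb, truth = truth, config = config),
            class = "msv_simulation")
}

#' @export
print.msv_simulation <- function(x, ...) {
  cat("Synthetic multi-site questionnaire study\n")
  print(x$dataset)
  cat(sprintf("  structural blanks: %.1f%%, ordinary blanks: %.1f%%\n",
              100 * mean(x$truth$structural), 100 * mean(x$truth$ordinary)))
  invisible(x)
}

#' Reference multicenter scenario
#'
#' A fixed four-site scenario mirroring a European multicenter cohort:
#' sites of 142, 158, 197 and 155 participants (652 in total), 130
#' variables in 9 questionnaire sections (652 x 130 = 84,760 cells), 26
#' skip-logic gated questions yielding roughly 7.4% structurally
#' not-applicable cells, and ordinary missingness calibrated to roughly
#' 9.6% of cells overall. Four sections (health data, health literacy,
#' psychological distress, health care empowerment) have no missingness at
#' all; site C carries concentrated missingness (rate 0.35) in quality of
#' life and use of health care services, so its completeness profile
#' diverges from the other sites, and a moderate response-distribution
#' shift in quality of life and interpersonal communication.
#'
#' @param seed master seed (default 1234).
#' @return an `"msv_simulation"` (see [generate()]).
#' @export
reference_cohort <- function(seed = 1234L) {
  generate(reference_config(seed))
}

#' Configuration of the reference multicenter scenario
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
reference_config <- function(seed = 1234L) {
  sections <- list(
    list(name = "sociodemographic data", n_vars = 18L, n_gated = 3L),
    list(name = "health data", n_vars = 8L),
    list(name = "health literacy", n_vars = 12L),
    list(name = "risk behaviors and healthy lifestyles", n_vars = 16L,
         n_gated = 8L),
    list(name = "psychological distress", n_vars = 18L),
    list(name = "quality of life", n_vars = 10L),
    list(name = "health care empowerment", n_vars = 10L),
    list(name = "interpersonal communication", n_vars = 14L, n_gated = 5L),
    list(name = "use of health care services", n_vars = 24L, n_gated = 10L))
  miss_secs <- c("sociodemographic data",
                 "risk behaviors and healthy lifestyles",
                 "quality of life", "interpersonal communication",
                 "use of health care services")
  sites <- data.frame(label = c("site A", "site B", "site C", "site D"),
                      n = c(142L, 158L, 197L, 155L))
  ov <- expand.grid(site = sites$label, section = miss_secs,
                    stringsAsFactors = FALSE)
  ov$rate <- 0.147
  conc <- ov$site == "site C" &
    ov$section %in% c("quality of life", "use of health care services")
  ov$rate[conc] <- 0.35
  sim_config(
    sites = sites, sections = sections,
    missing_rate = 0, missing_overrides = ov,
    shifts = list(list(site = "site C",
                       sections = c("quality of life",
                                    "interpersonal communication"),
                       delta = 0.5, alpha = 20)),
    gate_activation = 0.63, mnar_strength = 0, seed = seed)
}
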