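# Codebook: variable semantics and branching (skip-logic) rules for a
# multi-site questionnaire.

VTYPES <- c("categorical", "ordinal", "continuous", "text", "multichoice")

#' Declare a questionnaire variable
#'
#' A variable spec carries the question id, the questionnaire section it
#' belongs to, its measurement type, the ordered category labels (for
#' categorical/ordinal types) and an optional branching rule stating that
#' the question only applies when a parent question took one of a set of
#' activating values.
#'
#' @param id question identifier, e.g. `"Q88"`. Any non-empty string.
#' @param section section (sub-questionnaire) name.
#' @param vtype one of `"categorical"`, `"ordinal"`, `"continuous"`,
#'   `"text"`, `"multichoice"`.
#' @param categories ordered character vector of category labels; required
#'   (length >= 2) for categorical/ordinal, must be empty otherwise.
#' @param branch optional list `list(parent = <id>, values = <labels>)`:
#'   the question applies only when `parent` took one of `values`.
#' @return an object of class `"variable_spec"`.
#' @export
variable_spec <- function(id, section, vtype,
                          categories = character(), branch = NULL) {
  vtype <- match.arg(vtype, VTYPES)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_msvdq("variable id must be a non-empty string", "msvdq_codebook_error")
  categories <- as.character(categories)
  if (vtype %in% c("categorical", "ordinal")) {
    if (length(unique(categories)) < 2L)
      stop_msvdq(sprintf(
        "variable '%s': %s variables need >= 2 distinct categories", id, vtype),
        "msvdq_codebook_error")
    if (anyDuplicated(categories))
      stop_msvdq(sprintf("variable '%s': duplicated category labels", id),
                 "msvdq_codebook_error")
  } else if (length(categories) > 0L) {
    stop_msvdq(sprintf(
      "variable '%s': %s variables must not declare categories", id, vtype),
      "msvdq_codebook_error")
  }
  if (!is.null(branch)) {
    if (is.null(branch$parent) || is.null(branch$values) ||
        length(branch$values) < 1L)
      stop_msvdq(sprintf(
        "variable '%s': branch rule needs a parent and >= 1 activating value", id),
        "msvdq_codebook_error")
    branch <- list(parent = as.character(branch$parent)[1L],
                   values = as.character(unlist(branch$values)))
  }
  structure(list(id = id, section = as.character(section), vtype = vtype,
                 categories = categories, branch = branch),
            class = "variable_spec")
}

#' Assemble and validate a codebook
#'
#' @param variables list of [variable_spec()] objects.
#' @return an object of class `"codebook"`: a named list of variable specs,
#'   in declaration order, with all cross-variable invariants checked
#'   (unique ids; branch parents exist, are categorical/ordinal, differ from
#'   the child, and parent chains are acyclic; activating values are
#'   declared parent categories).
#' @export
codebook <- function(variables) {
  if (!length(variables))
    stop_msvdq("codebook has no variables", "msvdq_codebook_error")
  variables <- lapply(variables, function(v) {
    if (!inherits(v, "variable_spec"))
      v <- do.call(variable_spec, v)
    v
  })
  ids <- vapply(variables, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_msvdq(sprintf("duplicate variable id(s): %s",
                       paste(unique(dup), collapse = ", ")),
               "msvdq_codebook_error")
  names(variables) <- ids
  # branch-rule referential checks
  for (v in variables) {
    br <- v$branch
    if (is.null(br)) next
    if (br$parent == v$id)
      stop_msvdq(sprintf("variable '%s': branch parent is itself", v$id),
                 "msvdq_codebook_error")
    if (!br$parent %in% ids)
      stop_msvdq(sprintf(
        "variable '%s': branch parent '%s' not in codebook", v$id, br$parent),
        "msvdq_codebook_error")
    p <- variables[[br$parent]]
    if (!p$vtype %in% c("categorical", "ordinal"))
      stop_msvdq(sprintf(
        "variable '%s': branch parent '%s' is %s, not categorical/ordinal",
        v$id, p$id, p$vtype), "msvdq_codebook_error")
    bad <- setdiff(br$values, p$categories)
    if (length(bad))
      stop_msvdq(sprintf(
        "variable '%s': activating value(s) %s not among parent '%s' categories",
        v$id, paste(shQuote(bad), collapse = ", "), p$id),
        "msvdq_codebook_error")
  }
  # cycle detection over parent chains
  for (start in ids) {
    seen <- character()
    cur <- start
    repeat {
      br <- variables[[cur]]$branch
      if (is.null(br)) break
      if (br$parent %in% c(seen, start))
        stop_msvdq(sprintf("cyclic branch chain involving '%s'", start),
                   "msvdq_codebook_error")
      seen <- c(seen, cur)
      cur <- br$parent
    }
  }
  structure(variables, class = "codebook")
}

#' Read a codebook from JSON or YAML
#'
#' The on-disk schema is
#' `{"variables": [{"id", "section", "vtype", "categories"?, "branch"?:
#' {"parent", "values"}}]}`; files ending in `.yaml`/`.yml` are parsed as
#' YAML, everything else as JSON.
#'
#' @param path file path.
#' @return a validated [codebook()].
#' @export
load_codebook <- function(path) {
  if (!file.exists(path))
    stop_msvdq(sprintf("codebook file not found: %s", path), "msvdq_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$variables))
    stop_msvdq("codebook file has no 'variables' entry", "msvdq_codebook_error")
  specs <- lapply(raw$variables, function(v)
    variable_spec(id = v$id, section = v$section, vtype = v$vtype,
                  categories = unlist(v$categories) %||% character(),
                  branch = v$branch))
  codebook(specs)
}

#' Write a codebook to JSON
#'
#' @param cb a [codebook()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  vars <- lapply(unclass(cb), function(v) {
    out <- list(id = v$id, section = v$section, vtype = v$vtype)
    if (length(v$categories)) out$categories <- v$categories
    if (!is.null(v$branch))
      out$branch <- list(parent = v$branch$parent, values = v$branch$values)
    out
  })
  jsonlite::write_json(list(variables = unname(vars)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.codebook <- function(x, ...) {
  secs <- codebook_sections(x)
  cat(sprintf("Questionnaire codebook: %d variables in %d section(s)\n",
              length(x), length(secs)))
  tab <- table(vapply(x, `[[`, "", "vtype"))
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  nbr <- sum(vapply(x, function(v) !is.null(v$branch), TRUE))
  cat(sprintf("  branch-gated variables: %d\n", nbr))
  invisible(x)
}

#' Section names of a codebook, in first-appearance order
#' @param cb a [codebook()].
#' @return character vector of section names.
#' @export
codebook_sections <- function(cb) {
  unique(vapply(cb, `[[`, "", "section"))
}

#' Variable ids of a codebook (optionally restricted to one section)
#' @param cb a [codebook()].
#' @param section a section name, or `"all"`.
#' @return character vector of ids in declaration order.
#' @export
codebook_ids <- function(cb, section = "all") {
  ids <- names(cb)
  if (identical(section, "all")) return(ids)
  if (!section %in% codebook_sections(cb))
    stop_msvdq(sprintf("unknown section '%s'", section), "msvdq_codebook_error")
  ids[vapply(cb, `[[`, "", "section") == section]
}
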