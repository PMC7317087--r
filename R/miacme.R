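# MIACME (Minimum Information About a Cell Migration Experiment) metadata:
# structured JSON documents spanning three conceptual domains -- experimental
# set-up, imaging condition, and data -- validated against a declarative
# requirement table (field path -> MUST/SHOULD/MAY) shipped as YAML, and
# embeddable into a package descriptor. Validation is purely offline: term
# annotations are shape-checked (label/source/accession), never resolved
# against a live ontology service.

MIACME_VERSIONS <- "1.1"

#' Load a MIACME requirement table
#'
#' The table is data, not code: a YAML document listing field paths (dot
#' notation into the metadata document) with a requirement level, `MUST`
#' (missing is an error), `SHOULD` (missing is a warning) or `MAY`. The
#' shipped default covers MIACME 1.1 with MUST for the assay type, cell
#' model, imaging modality and raw-data summary.
#'
#' @param path YAML file; `NULL` for the table shipped with the package.
#' @return list with `miacme_version` and `fields`.
#' @export
miacme_requirements <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "miacme-requirements.yaml", package = "biotracksr")
  }
  yaml::read_yaml(path)
}

#' Read a MIACME document from JSON
#'
#' @param path JSON file.
#' @return The parsed document (nested list, arrays kept as lists).
#' @export
read_miacme <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Path to the shipped example MIACME document
#'
#' A complete synthetic example document describing a Ba/F3-style single-cell
#' migration study, annotated with illustrative controlled-vocabulary terms.
#' @return File path of `miacme-example.json`.
#' @export
miacme_example <- function() {
  system.file("extdata", "miacme-example.json", package = "biotracksr")
}

# walk a dot-notation path; NULL when any step is absent
get_path <- function(doc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- doc
  for (p in parts) {
    if (!is.list(cur) || is.null(cur[[p]])) return(NULL)
    cur <- cur[[p]]
  }
  cur
}

is_present <- function(v) {
  if (is.null(v)) return(FALSE)
  if (length(v) == 0) return(FALSE)
  if (is.character(v) && all(!nzchar(v))) return(FALSE)
  TRUE
}

# recursive shape check of term annotations: any mapping with a label key
check_terms <- function(node, where, push) {
  if (!is.list(node)) return(invisible())
  nm <- names(node)
  if (!is.null(nm) && "label" %in% nm) {
    lab <- node[["label"]]
    if (!is_present(lab) || !is.character(unlist(lab))) {
      push(bt_issue("error", "invalid_term_annotation",
                    sprintf("term annotation at %s has an empty label", where),
                    "miacme"))
    }
    if (is_present(node[["accession"]]) && !is_present(node[["source"]])) {
      push(bt_issue("error", "term_accession_without_source",
                    sprintf("term annotation at %s has an accession but no source", where),
                    "miacme"))
    }
  }
  for (i in seq_along(node)) {
    child_name <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    check_terms(node[[i]], paste(where, child_name, sep = "."), push)
  }
}

#' Validate a MIACME metadata document
#'
#' Structural, offline validation: the document's `miacme_version` selects
#' the requirement table (unknown versions are an error); every missing
#' MUST-level field yields one error, every missing SHOULD-level field one
#' warning; term annotations are checked for shape (non-empty label, no
#' accession without a source); replicate and image counts must be positive
#' integers when given. Unknown extra fields are preserved and never flagged
#' (open-world validation), and field order is irrelevant.
#'
#' @param doc a parsed MIACME document (nested list).
#' @param requirements a requirement table from [miacme_requirements()].
#' @return A [bt_report()].
#' @export
validate_miacme <- function(doc, requirements = miacme_requirements()) {
  iss <- list()
  push <- function(x) iss[[length(iss) + 1]] <<- x

  ver <- doc[["miacme_version"]]
  if (is.null(ver)) {
    push(bt_issue("warning", "missing_version",
                  sprintf("document declares no miacme_version; assuming %s",
                          requirements$miacme_version), "miacme"))
  } else if (!as.character(ver) %in% MIACME_VERSIONS) {
    push(bt_issue("error", "unknown_miacme_version",
                  sprintf("miacme_version %s is not supported", ver), "miacme"))
    return(bt_report(do.call(rbind, iss)))
  }

  for (f in requirements$fields) {
    lvl <- toupper(f$level)
    if (lvl == "MAY") next
    if (!is_present(get_path(doc, f$path))) {
      if (lvl == "MUST") {
        push(bt_issue("error", "missing_required_field",
                      sprintf("MUST-level field %s is absent or empty", f$path),
                      "miacme"))
      } else {
        push(bt_issue("warning", "missing_recommended_field",
                      sprintf("SHOULD-level field %s is absent or empty", f$path),
                      "miacme"))
      }
    }
  }

  for (cp in c("data.number_of_replicates", "data.raw_data_summary.number_of_images")) {
    v <- get_path(doc, cp)
    if (!is.null(v)) {
      vv <- suppressWarnings(as.numeric(v))
      if (is.na(vv) || vv != round(vv) || vv <= 0) {
        push(bt_issue("error", "invalid_count",
                      sprintf("%s must be a positive integer", cp), "miacme"))
      }
    }
  }

  check_terms(doc, "document", push)
  bt_report(if (length(iss)) do.call(rbind, iss) else empty_issues())
}

#' Embed a MIACME document into a package descriptor
#'
#' The document is validated first; documents with MUST-level errors are
#' refused. The descriptor gains a `miacme` block carrying the document
#' verbatim plus its schema version, which round-trips unchanged through
#' [write_biotracks()] / [read_biotracks()]. Embedding over an existing
#' block replaces it with a warning (last write wins).
#'
#' @param pkg a [bt_package()].
#' @param doc a MIACME document (nested list, e.g. from [read_miacme()]).
#' @param requirements requirement table used for validation.
#' @return The package with the metadata attached.
#' @export
embed_miacme <- function(pkg, doc, requirements = miacme_requirements()) {
  stopifnot(inherits(pkg, "bt_package"))
  rep <- validate_miacme(doc, requirements)
  if (!rep$ok) stop_invalid(rep, "MIACME document")
  if (is.null(pkg$descriptor)) pkg$descriptor <- default_descriptor(pkg)
  if (!is.null(pkg$descriptor$miacme)) {
    warning("replacing an existing miacme block (last write wins)")
  }
  if (is.null(doc[["miacme_version"]])) {
    doc$miacme_version <- requirements$miacme_version
  }
  pkg$descriptor$miacme <- doc
  pkg
}
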