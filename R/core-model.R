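#' biotracksr: cell tracking data packages
#'
#' Read, write, validate, convert and simulate cell-migration tracking data
#' stored as a Tabular Data Package: an `objects` table (one detection per
#' frame), a `links` table (linear chains of objects across frames) and a
#' `tracks` table (sets of links forming one lineage), plus a JSON descriptor.
#'
#' @section Main entry points:
#' * [bt_package()], [validate_package()] -- in-memory model and integrity checks
#' * [read_biotracks()], [write_biotracks()] -- package directory I/O
#' * [infer_tracks()], [detect_events()], [package_stats()] -- lineage topology
#' * [read_trackmate()], [read_cellprofiler()], [read_generic_csv()] -- converters
#' * [validate_miacme()], [embed_miacme()] -- experiment metadata
#' * [simulate_tracks()] -- synthetic tracking data with ground truth
#' * [bt_cli()] -- command-line surface
#'
#' @name biotracksr-package
#' @keywords internal
"_PACKAGE"

# Reserved column names used on disk; feature columns must not collide.
CMSO_COLS <- c(
  object_id = "cmso_object_id", frame = "cmso_frame_id",
  x = "cmso_x_coord", y = "cmso_y_coord", z = "cmso_z_coord",
  link_id = "cmso_link_id", track_id = "cmso_track_id"
)

BT_FORMAT_VERSION <- "0.1"
BT_PROFILE <- "tabular-data-package"

#' Assemble an in-memory tracking data package
#'
#' A package bundles three tables. `objects` has one row per detection with
#' integer columns `object_id` and `frame`, numeric coordinates `x`, `y`
#' (optionally `z`), and any further numeric columns, which are treated as
#' features (area, intensity, ...). `links` is in long form with columns
#' `link_id` and `object_id`; row order within a link gives the order of the
#' chain, whose frames must strictly increase (gaps are allowed). `tracks`,
#' also long form (`track_id`, `link_id`), partitions the links into weakly
#' connected lineage components; it may be omitted and inferred later with
#' [infer_tracks()].
#'
#' @param objects data.frame of detections.
#' @param links data.frame with columns `link_id`, `object_id` (long form).
#'   May have zero rows for an objects-only package.
#' @param tracks optional data.frame with columns `track_id`, `link_id`.
#' @param descriptor optional descriptor list (see [default_descriptor()]);
#'   built on demand by [write_biotracks()] when absent.
#' @return An object of class `bt_package`.
#' @seealso [validate_package()]
#' @examples
#' obj <- data.frame(object_id = 0:1, frame = 0:1, x = c(0, 3), y = c(0, 4))
#' lnk <- data.frame(link_id = c(0L, 0L), object_id = 0:1)
#' pkg <- bt_package(obj, lnk)
#' validate_package(pkg)$ok
#' @export
bt_package <- function(objects, links = NULL, tracks = NULL, descriptor = NULL) {
  objects <- as.data.frame(objects)
  if (is.null(links)) {
    links <- data.frame(link_id = integer(0), object_id = integer(0))
  }
  links <- as.data.frame(links)
  if (!is.null(tracks)) tracks <- as.data.frame(tracks)
  for (col in c("object_id", "frame")) {
    if (col %in% names(objects) && is.numeric(objects[[col]])) {
      if (all(is.finite(objects[[col]]) & objects[[col]] == round(objects[[col]]))) {
        objects[[col]] <- as.integer(objects[[col]])
      }
    }
  }
  for (col in c("link_id", "object_id")) {
    if (col %in% names(links) && is.numeric(links[[col]])) {
      links[[col]] <- as.integer(links[[col]])
    }
  }
  if (!is.null(tracks)) {
    for (col in c("track_id", "link_id")) {
      if (col %in% names(tracks) && is.numeric(tracks[[col]])) {
        tracks[[col]] <- as.integer(tracks[[col]])
      }
    }
  }
  structure(
    list(objects = objects, links = links, tracks = tracks, descriptor = descriptor),
    class = "bt_package"
  )
}

#' @export
print.bt_package <- function(x, ...) {
  nl <- if (nrow(x$links)) length(unique(x$links$link_id)) else 0L
  nt <- if (!is.null(x$tracks) && nrow(x$tracks)) length(unique(x$tracks$track_id)) else NA_integer_
  cat(sprintf(
    "<bt_package> %d objects, %d links, %s tracks%s\n",
    nrow(x$objects), nl,
    if (is.na(nt)) "(uninferred)" else as.character(nt),
    if (!is.null(x$descriptor$miacme)) ", MIACME metadata attached" else ""
  ))
  feats <- feature_columns(x$objects)
  if (length(feats)) cat("  features:", paste(feats, collapse = ", "), "\n")
  invisible(x)
}

#' Names of the feature columns of an objects table
#'
#' Everything that is not an identifier, frame or coordinate column.
#' @param objects an objects data.frame.
#' @return character vector of column names (possibly empty).
#' @export
feature_columns <- function(objects) {
  setdiff(names(objects), c("object_id", "frame", "x", "y", "z"))
}

# ---- validation reports ------------------------------------------------------

empty_issues <- function() {
  data.frame(
    severity = character(0), code = character(0), message = character(0),
    table = character(0), row = integer(0), stringsAsFactors = FALSE
  )
}

bt_issue <- function(severity, code, message, table = NA_character_, row = NA_integer_) {
  data.frame(
    severity = severity, code = code, message = message,
    table = table, row = as.integer(row), stringsAsFactors = FALSE
  )
}

#' Build a validation report
#'
#' Reports carry a logical `ok` (true iff no error-severity issues) and an
#' `issues` data.frame with columns `severity` (`"error"` or `"warning"`),
#' `code`, `message`, `table` and `row`.
#'
#' @param issues an issues data.frame (zero rows for a clean report).
#' @return An object of class `bt_report`.
#' @export
bt_report <- function(issues = empty_issues()) {
  rownames(issues) <- NULL
  structure(
    list(ok = !any(issues$severity == "error"), issues = issues),
    class = "bt_report"
  )
}

#' @export
print.bt_report <- function(x, ...) {
  cat(sprintf(
    "<bt_report> %s: %d error(s), %d warning(s)\n",
    if (x$ok) "OK" else "INVALID",
    sum(x$issues$severity == "error"), sum(x$issues$severity == "warning")
  ))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      loc <- if (is.na(x$issues$table[i])) "" else {
        sprintf(" [%s%s]", x$issues$table[i],
                if (is.na(x$issues$row[i])) "" else paste0(":", x$issues$row[i]))
      }
      cat(sprintf("  %s %s%s: %s\n", toupper(x$issues$severity[i]),
                  x$issues$code[i], loc, x$issues$message[i]))
    }
  }
  invisible(x)
}

combine_reports <- function(...) {
  bt_report(do.call(rbind, lapply(list(...), function(r) r$issues)))
}

report_codes <- function(report, severity = NULL) {
  iss <- report$issues
  if (!is.null(severity)) iss <- iss[iss$severity == severity, , drop = FALSE]
  iss$code
}

stop_invalid <- function(report, what) {
  msg <- paste0(
    what, " failed validation: ",
    paste(utils::head(unique(report_codes(report, "error")), 5), collapse = ", ")
  )
  cond <- structure(
    class = c("bt_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), report = report)
  )
  stop(cond)
}

# ---- objects -----------------------------------------------------------------

#' Validate an objects table
#'
#' Checks identifier uniqueness and non-negativity, frame indices, coordinate
#' finiteness and feature integrity. Malformed input yields error issues in
#' the report, never an exception.
#'
#' @param objects an objects data.frame (see [bt_package()]).
#' @return A [bt_report()].
#' @export
validate_objects <- function(objects) {
  iss <- list()
  push <- function(x) iss[[length(iss) + 1]] <<- x

  missing_cols <- setdiff(c("object_id", "frame", "x", "y"), names(objects))
  if (length(missing_cols)) {
    push(bt_issue("error", "missing_column",
                  paste("objects table lacks column(s):", paste(missing_cols, collapse = ", ")),
                  "objects"))
    return(bt_report(do.call(rbind, iss)))
  }

  id <- objects$object_id
  if (!is.numeric(id) || any(!is.finite(id)) || any(id != round(id))) {
    push(bt_issue("error", "bad_object_id", "object_id must be integer-valued and finite", "objects"))
  } else {
    if (any(id < 0)) {
      for (r in which(id < 0)) {
        push(bt_issue("error", "negative_object_id",
                      sprintf("object_id %s is negative", id[r]), "objects", r))
      }
    }
    dup <- duplicated(id)
    for (r in which(dup)) {
      push(bt_issue("error", "duplicate_object_id",
                    sprintf("object_id %s occurs more than once", id[r]), "objects", r))
    }
  }

  fr <- objects$frame
  if (!is.numeric(fr) || any(!is.finite(fr)) || any(fr != round(fr))) {
    push(bt_issue("error", "bad_frame", "frame must be integer-valued and finite", "objects"))
  } else {
    for (r in which(fr < 0)) {
      push(bt_issue("error", "negative_frame",
                    sprintf("frame %s is negative", fr[r]), "objects", r))
    }
  }

  coord_cols <- intersect(c("x", "y", "z"), names(objects))
  for (cc in coord_cols) {
    v <- objects[[cc]]
    if (!is.numeric(v)) {
      push(bt_issue("error", "nonfinite_coordinate",
                    sprintf("coordinate column %s is not numeric", cc), "objects"))
      next
    }
    for (r in which(!is.finite(v))) {
      push(bt_issue("error", "nonfinite_coordinate",
                    sprintf("non-finite %s at objects row %d", cc, r), "objects", r))
    }
  }

  for (fc in feature_columns(objects)) {
    if (!nzchar(fc)) {
      push(bt_issue("error", "empty_feature_name", "feature column has an empty name", "objects"))
      next
    }
    v <- objects[[fc]]
    if (!is.numeric(v)) {
      push(bt_issue("error", "nonnumeric_feature",
                    sprintf("feature column %s is not numeric", fc), "objects"))
      next
    }
    for (r in which(!is.finite(v))) {
      push(bt_issue("error", "nonfinite_feature",
                    sprintf("non-finite value of feature %s at objects row %d", fc, r),
                    "objects", r))
    }
  }

  bt_report(if (length(iss)) do.call(rbind, iss) else empty_issues())
}

# ---- links -------------------------------------------------------------------

# split long-form link table into ordered object-id vectors, named by link_id
link_sequences <- function(links) {
  if (!nrow(links)) return(structure(list(), names = character(0)))
  split(links$object_id, factor(links$link_id, levels = unique(links$link_id)))
}

#' Validate a links table against its objects
#'
#' Links must linearly connect existing objects across strictly increasing
#' frames: dangling references, non-increasing frame sequences, repeated
#' objects within a link, and links shorter than two objects are all flagged.
#'
#' @param objects an objects data.frame, assumed already validated.
#' @param links a long-form links data.frame (`link_id`, `object_id`).
#' @return A [bt_report()].
#' @export
validate_links <- function(objects, links) {
  iss <- list()
  push <- function(x) iss[[length(iss) + 1]] <<- x

  missing_cols <- setdiff(c("link_id", "object_id"), names(links))
  if (length(missing_cols)) {
    push(bt_issue("error", "missing_column",
                  paste("links table lacks column(s):", paste(missing_cols, collapse = ", ")),
                  "links"))
    return(bt_report(do.call(rbind, iss)))
  }

  frame_of <- stats::setNames(objects$frame, objects$object_id)
  seqs <- link_sequences(links)
  for (lid in names(seqs)) {
    ids <- seqs[[lid]]
    if (length(ids) < 2) {
      push(bt_issue("error", "link_too_short",
                    sprintf("link %s has %d object(s); at least 2 required", lid, length(ids)),
                    "links"))
    }
    known <- as.character(ids) %in% names(frame_of)
    for (i in which(!known)) {
      push(bt_issue("error", "dangling_reference",
                    sprintf("link %s references unknown object %s", lid, ids[i]), "links"))
    }
    if (anyDuplicated(ids)) {
      for (v in unique(ids[duplicated(ids)])) {
        push(bt_issue("error", "duplicate_object_in_link",
                      sprintf("object %s repeats within link %s", v, lid), "links"))
      }
    }
    if (all(known) && length(ids) >= 2) {
      fr <- unname(frame_of[as.character(ids)])
      if (any(diff(fr) <= 0)) {
        push(bt_issue("error", "frame_order",
                      sprintf("frames along link %s are not strictly increasing", lid),
                      "links"))
      }
    }
  }

  bt_report(if (length(iss)) do.call(rbind, iss) else empty_issues())
}

# ---- tracks ------------------------------------------------------------------

#' Validate a tracks table: partition and connectivity
#'
#' Tracks must partition the links (every link assigned to exactly one track,
#' no unknown links) and each track's links, viewed as nodes joined whenever
#' they share an object, must form a single connected component.
#'
#' @param links a long-form links data.frame.
#' @param tracks a long-form tracks data.frame (`track_id`, `link_id`).
#' @return A [bt_report()].
#' @export
validate_tracks <- function(links, tracks) {
  iss <- list()
  push <- function(x) iss[[length(iss) + 1]] <<- x

  missing_cols <- setdiff(c("track_id", "link_id"), names(tracks))
  if (length(missing_cols)) {
    push(bt_issue("error", "missing_column",
                  paste("tracks table lacks column(s):", paste(missing_cols, collapse = ", ")),
                  "tracks"))
    return(bt_report(do.call(rbind, iss)))
  }

  link_ids <- unique(links$link_id)
  assigned <- tracks$link_id
  for (v in setdiff(link_ids, assigned)) {
    push(bt_issue("error", "unassigned_link",
                  sprintf("link %s is not assigned to any track", v), "tracks"))
  }
  for (v in setdiff(assigned, link_ids)) {
    push(bt_issue("error", "dangling_link_reference",
                  sprintf("tracks table references unknown link %s", v), "tracks"))
  }
  for (v in unique(assigned[duplicated(assigned)])) {
    push(bt_issue("error", "multiply_assigned_link",
                  sprintf("link %s is assigned to more than one track", v), "tracks"))
  }

  seqs <- link_sequences(links)
  for (tid in unique(tracks$track_id)) {
    members <- as.character(tracks$link_id[tracks$track_id == tid])
    members <- members[members %in% names(seqs)]
    if (length(members) <= 1) next
    comp <- link_components(seqs[members])
    if (length(unique(comp)) > 1) {
      push(bt_issue("error", "track_disconnected",
                    sprintf("track %s is not connected through shared objects", tid),
                    "tracks"))
    }
  }

  bt_report(if (length(iss)) do.call(rbind, iss) else empty_issues())
}

# component id per link, via the bipartite link--object incidence (igraph)
link_components <- function(seqs) {
  if (!length(seqs)) return(integer(0))
  link_names <- paste0("L", names(seqs))
  edges <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    cbind(link_names[i], paste0("O", seqs[[i]]))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  unname(memb[link_names])
}

#' Validate a whole tracking package
#'
#' Runs the object, link and (when present) track checks and aggregates all
#' issues into one report. An absent tracks table is legal (it is derivable
#' with [infer_tracks()]); an empty links table yields a `no_links` warning.
#'
#' @param pkg a [bt_package()].
#' @return A [bt_report()].
#' @export
validate_package <- function(pkg) {
  stopifnot(inherits(pkg, "bt_package"))
  rep_o <- validate_objects(pkg$objects)
  rep_l <- validate_links(pkg$objects, pkg$links)
  reps <- list(rep_o, rep_l)
  if (!nrow(pkg$links)) {
    reps <- c(reps, list(bt_report(bt_issue(
      "warning", "no_links", "package has objects but no links", "links"
    ))))
  }
  if (!is.null(pkg$tracks)) {
    reps <- c(reps, list(validate_tracks(pkg$links, pkg$tracks)))
  }
  do.call(combine_reports, reps)
}
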