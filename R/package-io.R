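# Serialization of tracking packages as a Tabular Data Package:
# <dir>/datapackage.json + objects.csv + links.csv [+ tracks.csv].
#
# Writing is byte-stable by construction: fixed column order, descriptor keys
# sorted recursively, LF line endings, RFC 4180 quoting, integers printed
# without a decimal point and reals via R's shortest up-to-15-significant-digit
# representation. Reading goes through utils::read.csv with column classes
# taken from the descriptor schemas.

# ---- number / CSV formatting -------------------------------------------------

fmt_value <- function(v) {
  if (is.integer(v)) return(ifelse(is.na(v), "", as.character(v)))
  if (is.numeric(v)) return(ifelse(is.na(v), "", vapply(v, as.character, "")))
  s <- ifelse(is.na(v), "", as.character(v))
  needs_quote <- grepl('[",\n\r]', s)
  s[needs_quote] <- paste0('"', gsub('"', '""', s[needs_quote]), '"')
  s
}

write_csv_stable <- function(df, path) {
  header <- fmt_value(names(df))
  body <- if (nrow(df)) {
    cols <- lapply(df, fmt_value)
    do.call(paste, c(cols, sep = ","))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

schema_type <- function(v) {
  if (is.integer(v)) "integer" else if (is.numeric(v)) "number" else "string"
}

csv_colclass <- c(integer = "integer", number = "numeric", string = "character")

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else {
    x
  }
}

write_json_stable <- function(x, path) {
  txt <- jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, pretty = 2,
                          digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- descriptor --------------------------------------------------------------

#' Default descriptor for a tracking package
#'
#' The descriptor is the `datapackage.json` document: general metadata plus
#' one resource entry per CSV table with its column schema, and a `biotracks`
#' block carrying the format version, the bindings from canonical roles
#' (object id, frame, coordinates) to on-disk column names, the spatial unit
#' and the frame interval. On-disk columns use the `cmso_` namespace
#' (`cmso_object_id`, `cmso_frame_id`, `cmso_x_coord`, ...); feature columns
#' keep their own names.
#'
#' @param pkg a [bt_package()]; its tables define the resource schemas.
#' @param name package name recorded in the descriptor.
#' @param spatial_unit label for the coordinate unit (e.g. `"pixel"`,
#'   `"micron"`); stored verbatim, never used for rescaling.
#' @param frame_interval physical time per frame, in arbitrary but stated
#'   units; > 0.
#' @return A descriptor list.
#' @export
default_descriptor <- function(pkg, name = "tracking-data",
                               spatial_unit = "pixel", frame_interval = 1) {
  has_z <- "z" %in% names(pkg$objects)
  bindings <- list(
    object_id = unname(CMSO_COLS["object_id"]),
    frame = unname(CMSO_COLS["frame"]),
    x = unname(CMSO_COLS["x"]),
    y = unname(CMSO_COLS["y"])
  )
  if (has_z) bindings$z <- unname(CMSO_COLS["z"])

  obj_fields <- c(
    list(
      list(name = unname(CMSO_COLS["object_id"]), type = "integer"),
      list(name = unname(CMSO_COLS["frame"]), type = "integer"),
      list(name = unname(CMSO_COLS["x"]), type = "number"),
      list(name = unname(CMSO_COLS["y"]), type = "number")
    ),
    if (has_z) list(list(name = unname(CMSO_COLS["z"]), type = "number")),
    lapply(feature_columns(pkg$objects), function(fc) {
      list(name = fc, type = schema_type(pkg$objects[[fc]]))
    })
  )
  resources <- list(
    list(name = "objects", path = "objects.csv",
         schema = list(fields = obj_fields)),
    list(name = "links", path = "links.csv",
         schema = list(fields = list(
           list(name = unname(CMSO_COLS["link_id"]), type = "integer"),
           list(name = unname(CMSO_COLS["object_id"]), type = "integer")
         )))
  )
  if (!is.null(pkg$tracks)) {
    resources <- c(resources, list(
      list(name = "tracks", path = "tracks.csv",
           schema = list(fields = list(
             list(name = unname(CMSO_COLS["track_id"]), type = "integer"),
             list(name = unname(CMSO_COLS["link_id"]), type = "integer")
           )))
    ))
  }
  list(
    name = name,
    profile = BT_PROFILE,
    biotracks = list(
      format_version = BT_FORMAT_VERSION,
      bindings = bindings,
      spatial_unit = spatial_unit,
      frame_interval = frame_interval
    ),
    resources = resources
  )
}

descriptor_resource <- function(descriptor, name) {
  for (r in descriptor$resources) if (identical(r$name, name)) return(r)
  NULL
}

schema_field_names <- function(resource) {
  vapply(resource$schema$fields, function(f) f$name %||% "", "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structurally validate a package descriptor
#'
#' Checks the shape of a `datapackage.json` document: known profile, presence
#' of the `biotracks` block and of exactly one objects and one links resource
#' (tracks optional), and that every column binding points at a column
#' declared in the objects schema.
#'
#' @param descriptor a descriptor list (e.g. parsed from JSON).
#' @return A [bt_report()].
#' @export
validate_descriptor <- function(descriptor) {
  iss <- list()
  push <- function(x) iss[[length(iss) + 1]] <<- x

  profile <- descriptor$profile
  if (is.null(profile) || !identical(as.character(profile), BT_PROFILE)) {
    push(bt_issue("warning", "unknown_profile",
                  sprintf("profile is %s, expected %s",
                          profile %||% "<missing>", BT_PROFILE), "descriptor"))
  }
  bt <- descriptor$biotracks
  if (is.null(bt)) {
    push(bt_issue("error", "missing_biotracks_block",
                  "descriptor lacks the biotracks block", "descriptor"))
  } else if (is.null(bt$format_version)) {
    push(bt_issue("error", "missing_format_version",
                  "biotracks block lacks format_version", "descriptor"))
  }

  obj_res <- descriptor_resource(descriptor, "objects")
  if (is.null(obj_res)) {
    push(bt_issue("error", "missing_objects_resource",
                  "descriptor declares no objects resource", "descriptor"))
  }
  if (is.null(descriptor_resource(descriptor, "links"))) {
    push(bt_issue("error", "missing_links_resource",
                  "descriptor declares no links resource", "descriptor"))
  }

  if (!is.null(bt) && !is.null(bt$bindings) && !is.null(obj_res)) {
    declared <- schema_field_names(obj_res)
    for (role in names(bt$bindings)) {
      col <- bt$bindings[[role]]
      if (!col %in% declared) {
        push(bt_issue("error", "dangling_binding",
                      sprintf("binding %s -> %s names a column absent from the objects schema",
                              role, col), "descriptor"))
      }
    }
    for (role in c("object_id", "frame", "x", "y")) {
      if (is.null(bt$bindings[[role]])) {
        push(bt_issue("error", "missing_binding",
                      sprintf("biotracks bindings lack the %s role", role), "descriptor"))
      }
    }
  }

  bt_report(if (length(iss)) do.call(rbind, iss) else empty_issues())
}

# ---- write -------------------------------------------------------------------

#' Write a tracking package to a directory
#'
#' Produces `datapackage.json`, `objects.csv`, `links.csv` and, when the
#' package has a tracks table, `tracks.csv`. Link and track tables are
#' written in long form, one row per (link, object) / (track, link), in
#' sequence order. The package is validated first and an invalid package is
#' refused with the report attached to the error condition. Writing the same
#' package twice yields byte-identical files.
#'
#' @param pkg a valid [bt_package()].
#' @param dir output directory, created if needed.
#' @param name,spatial_unit,frame_interval passed to [default_descriptor()]
#'   when the package carries no descriptor yet.
#' @return Invisibly, the character vector of files written.
#' @export
write_biotracks <- function(pkg, dir, name = "tracking-data",
                            spatial_unit = "pixel", frame_interval = 1) {
  stopifnot(inherits(pkg, "bt_package"))
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "package to write")

  desc <- pkg$descriptor
  if (is.null(desc)) {
    desc <- default_descriptor(pkg, name = name, spatial_unit = spatial_unit,
                               frame_interval = frame_interval)
  }
  # resources and bindings must mirror the canonical tables actually written
  canonical <- default_descriptor(pkg, name = name)
  desc$resources <- canonical$resources
  desc$biotracks$bindings <- canonical$biotracks$bindings
  if (is.null(desc$biotracks$format_version)) {
    desc$biotracks$format_version <- BT_FORMAT_VERSION
  }
  drep <- validate_descriptor(desc)
  if (!drep$ok) stop_invalid(drep, "descriptor to write")

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  obj <- pkg$objects
  obj_out <- data.frame(a = obj$object_id, b = obj$frame, check.names = FALSE)
  names(obj_out) <- unname(CMSO_COLS[c("object_id", "frame")])
  obj_out[[unname(CMSO_COLS["x"])]] <- obj$x
  obj_out[[unname(CMSO_COLS["y"])]] <- obj$y
  if ("z" %in% names(obj)) obj_out[[unname(CMSO_COLS["z"])]] <- obj$z
  for (fc in feature_columns(obj)) obj_out[[fc]] <- obj[[fc]]
  obj_out <- obj_out[order(obj_out[[1]]), , drop = FALSE]

  links_out <- data.frame(a = pkg$links$link_id, b = pkg$links$object_id)
  names(links_out) <- unname(CMSO_COLS[c("link_id", "object_id")])

  files <- c(
    write_json_stable(desc, file.path(dir, "datapackage.json")),
    write_csv_stable(obj_out, file.path(dir, "objects.csv")),
    write_csv_stable(links_out, file.path(dir, "links.csv"))
  )
  if (!is.null(pkg$tracks)) {
    tr <- pkg$tracks[order(pkg$tracks$track_id, pkg$tracks$link_id), , drop = FALSE]
    tr_out <- data.frame(a = tr$track_id, b = tr$link_id)
    names(tr_out) <- unname(CMSO_COLS[c("track_id", "link_id")])
    files <- c(files, write_csv_stable(tr_out, file.path(dir, "tracks.csv")))
  }
  invisible(files)
}

# ---- read --------------------------------------------------------------------

read_resource_csv <- function(dir, resource) {
  path <- file.path(dir, resource$path)
  if (!file.exists(path)) {
    return(list(error = bt_issue(
      "error", "missing_resource",
      sprintf("resource %s: file %s not found", resource$name, resource$path),
      resource$name
    )))
  }
  fields <- schema_field_names(resource)
  types <- vapply(resource$schema$fields, function(f) f$type %||% "string", "")
  classes <- unname(csv_colclass[types])
  classes[is.na(classes)] <- "character"
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) e
  )
  if (inherits(df, "error")) {
    return(list(error = bt_issue(
      "error", "unreadable_resource",
      sprintf("resource %s (%s): %s", resource$name, path, conditionMessage(df)),
      resource$name
    )))
  }
  missing <- setdiff(fields, names(df))
  if (length(missing)) {
    return(list(error = bt_issue(
      "error", "schema_mismatch",
      sprintf("resource %s lacks declared column(s): %s",
              resource$name, paste(missing, collapse = ", ")),
      resource$name
    )))
  }
  for (i in seq_along(fields)) {
    v <- df[[fields[i]]]
    conv <- switch(classes[i],
                   integer = suppressWarnings(as.integer(v)),
                   numeric = suppressWarnings(as.numeric(v)),
                   as.character(v))
    if (classes[i] != "character" && any(is.na(conv) & !is.na(v))) {
      return(list(error = bt_issue(
        "error", "type_mismatch",
        sprintf("resource %s column %s does not parse as %s",
                resource$name, fields[i], types[i]),
        resource$name
      )))
    }
    df[[fields[i]]] <- conv
  }
  list(table = df)
}

#' Read a tracking package from a directory
#'
#' Parses `datapackage.json`, loads each declared CSV resource with the
#' column types of its schema, applies the `biotracks` column bindings to
#' recover the canonical `object_id`/`frame`/`x`/`y`/`z` columns (all other
#' objects columns are kept verbatim as features) and validates the result.
#' A package that fails validation is refused with the report attached to
#' the error condition.
#'
#' @param dir directory containing `datapackage.json`.
#' @param materialize_tracks when `TRUE` and the package has no tracks
#'   resource on disk, infer the tracks table with [infer_tracks()]; the
#'   default `FALSE` leaves it absent.
#' @return A valid [bt_package()] whose `descriptor` is the parsed document.
#' @export
read_biotracks <- function(dir, materialize_tracks = FALSE) {
  desc_path <- file.path(dir, "datapackage.json")
  if (!file.exists(desc_path)) {
    stop_invalid(bt_report(bt_issue(
      "error", "missing_descriptor",
      sprintf("no datapackage.json in %s", dir), "descriptor"
    )), "package directory")
  }
  desc <- jsonlite::fromJSON(desc_path, simplifyVector = FALSE)
  drep <- validate_descriptor(desc)
  if (!drep$ok) stop_invalid(drep, "descriptor")

  issues <- list()
  load_res <- function(name) {
    r <- descriptor_resource(desc, name)
    if (is.null(r)) return(NULL)
    got <- read_resource_csv(dir, r)
    if (!is.null(got$error)) {
      issues[[length(issues) + 1]] <<- got$error
      return(NULL)
    }
    got$table
  }
  obj_raw <- load_res("objects")
  links_raw <- load_res("links")
  tracks_raw <- load_res("tracks")
  if (length(issues)) stop_invalid(bt_report(do.call(rbind, issues)), "package resources")

  bind <- desc$biotracks$bindings
  objects <- data.frame(object_id = as.integer(obj_raw[[bind$object_id]]),
                        frame = as.integer(obj_raw[[bind$frame]]))
  objects$x <- as.numeric(obj_raw[[bind$x]])
  objects$y <- as.numeric(obj_raw[[bind$y]])
  bound <- c(bind$object_id, bind$frame, bind$x, bind$y)
  if (!is.null(bind$z) && bind$z %in% names(obj_raw)) {
    objects$z <- as.numeric(obj_raw[[bind$z]])
    bound <- c(bound, bind$z)
  }
  for (fc in setdiff(names(obj_raw), bound)) objects[[fc]] <- obj_raw[[fc]]

  links <- data.frame(
    link_id = as.integer(links_raw[[CMSO_COLS["link_id"]]] %||% links_raw[[1]]),
    object_id = as.integer(links_raw[[CMSO_COLS["object_id"]]] %||% links_raw[[2]])
  )
  tracks <- NULL
  if (!is.null(tracks_raw)) {
    tracks <- data.frame(
      track_id = as.integer(tracks_raw[[CMSO_COLS["track_id"]]] %||% tracks_raw[[1]]),
      link_id = as.integer(tracks_raw[[CMSO_COLS["link_id"]]] %||% tracks_raw[[2]])
    )
  }

  pkg <- bt_package(objects, links, tracks, descriptor = desc)
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "package content")
  if (is.null(pkg$tracks) && materialize_tracks) {
    pkg$tracks <- infer_tracks(pkg$objects, pkg$links, validate = FALSE)
  }
  pkg
}
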