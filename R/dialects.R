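# Converters from tracking-tool native outputs to validated tracking
# packages. Edge-list sources (TrackMate-style XML) are decomposed into
# maximal linear chains; label-column sources (CellProfiler-style or generic
# CSV) are segmented into per-label runs. All converters normalize frames to
# 0-based and remap source ids to dense non-negative integers in sorted
# source-id order, recording the mapping in the descriptor.

#' Describe how a tracking CSV maps onto the data model
#'
#' @param frame source column holding the time index (required).
#' @param x,y,z source coordinate columns (`z` optional).
#' @param object_id optional source column with a unique per-object id; when
#'   `NULL`, ids are synthesized in (frame, row) order.
#' @param label optional column whose value groups objects into one linear
#'   trajectory (e.g. CellProfiler's `TrackObjects_Label`); when `NULL`, the
#'   result has no links.
#' @param object_number optional per-frame object counter column, used only
#'   to detect duplicate (frame, object-number) rows; never a feature.
#' @param frame_base first frame index used by the source tool, 0 or 1.
#' @param features character vector of passthrough feature columns; `NULL`
#'   (default) takes every remaining numeric column. Non-numeric columns are
#'   dropped with a warning.
#' @return An object of class `bt_column_mapping`.
#' @export
column_mapping <- function(frame, x, y, z = NULL, object_id = NULL,
                           label = NULL, object_number = NULL,
                           frame_base = 0, features = NULL) {
  stopifnot(frame_base %in% c(0, 1))
  mapped <- c(frame, x, y, z, object_id, label, object_number)
  if (anyDuplicated(mapped)) stop("mapped source column names must be distinct")
  structure(
    list(frame = frame, x = x, y = y, z = z, object_id = object_id,
         label = label, object_number = object_number,
         frame_base = as.integer(frame_base), features = features),
    class = "bt_column_mapping"
  )
}

#' Default column mapping for CellProfiler-style tracking CSV
#'
#' @param label name of the tracking label column (the `TrackObjects_Label_*`
#'   column name varies with the configured tracker settings).
#' @return A [column_mapping()] with 1-based `ImageNumber` frames,
#'   `Location_Center_X`/`_Y` coordinates and `ObjectNumber` duplicate checks.
#' @export
cellprofiler_mapping <- function(label = "TrackObjects_Label") {
  column_mapping(
    frame = "ImageNumber", x = "Location_Center_X", y = "Location_Center_Y",
    label = label, object_number = "ObjectNumber", frame_base = 1
  )
}

#' Read a column mapping from a YAML or JSON file
#'
#' The file holds the arguments of [column_mapping()] as a flat mapping.
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [column_mapping()].
#' @export
read_column_mapping <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  # YAML 1.1 reads the bare keys y/n as booleans; map them back
  names(cfg)[names(cfg) == "TRUE"] <- "y"
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  do.call(column_mapping, cfg)
}

# dense remap of (possibly non-contiguous) numeric source ids, sorted order
remap_ids <- function(source_ids) {
  u <- sort(unique(source_ids))
  list(new = match(source_ids, u) - 1L,
       map = stats::setNames(seq_along(u) - 1L, as.character(u)))
}

dialect_descriptor <- function(pkg, dialect, source_id_map = NULL) {
  desc <- default_descriptor(pkg, name = paste0(dialect, "-import"))
  desc$biotracks$source_dialect <- dialect
  if (!is.null(source_id_map)) {
    desc$biotracks$source_id_map <- as.list(source_id_map)
  }
  desc
}

# ---- generic / CellProfiler CSV ---------------------------------------------

#' Convert a generic per-object tracking CSV
#'
#' Each row becomes one object; rows sharing a value of the mapping's label
#' column are sorted by frame and connected into linear links. A gap in the
#' frame sequence of a label either closes the current link and opens a new
#' one (`gap = "split"`, the default, since gap semantics differ across
#' tracker configurations) or is kept inside one gap-closed link
#' (`gap = "bridge"`). Without a label column the result is an objects-only
#' package and a `no_linking_column` warning is emitted.
#'
#' @param path CSV file (or a data.frame already in memory).
#' @param mapping a [column_mapping()] resolving at least frame, x and y.
#' @param gap gap policy for label runs, `"split"` or `"bridge"`.
#' @return A validated [bt_package()].
#' @export
read_generic_csv <- function(path, mapping, gap = c("split", "bridge")) {
  gap <- match.arg(gap)
  stopifnot(inherits(mapping, "bt_column_mapping"))
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  needed <- c(mapping$frame, mapping$x, mapping$y, mapping$z, mapping$object_id,
              mapping$label, mapping$object_number)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop("mapping names column(s) absent from the table: ",
         paste(absent, collapse = ", "))
  }

  frame <- as.integer(df[[mapping$frame]]) - mapping$frame_base
  if (any(is.na(frame)) || any(frame < 0)) {
    stop("frame column does not normalize to non-negative 0-based integers; ",
         "check frame_base")
  }
  if (!is.null(mapping$object_number)) {
    key <- paste(frame, df[[mapping$object_number]])
    if (anyDuplicated(key)) stop("duplicate (frame, object-number) rows in input")
  }

  ord <- order(frame, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  frame <- frame[ord]

  source_id_map <- NULL
  if (!is.null(mapping$object_id)) {
    rm <- remap_ids(as.numeric(df[[mapping$object_id]]))
    object_id <- rm$new
    source_id_map <- rm$map
  } else {
    object_id <- seq_len(nrow(df)) - 1L
  }

  objects <- data.frame(object_id = object_id, frame = frame)
  objects$x <- as.numeric(df[[mapping$x]])
  objects$y <- as.numeric(df[[mapping$y]])
  if (!is.null(mapping$z)) objects$z <- as.numeric(df[[mapping$z]])

  used <- c(mapping$frame, mapping$x, mapping$y, mapping$z, mapping$object_id,
            mapping$label, mapping$object_number)
  feats <- mapping$features %||% setdiff(names(df), used)
  for (fc in feats) {
    if (!is.numeric(df[[fc]])) {
      warning(sprintf("dropping non-numeric source column %s (features must be numeric)", fc))
      next
    }
    objects[[fc]] <- df[[fc]]
  }

  links <- data.frame(link_id = integer(0), object_id = integer(0))
  if (is.null(mapping$label)) {
    warning("no_linking_column: mapping has no label column; package has no links")
  } else {
    lab <- df[[mapping$label]]
    keep <- !is.na(lab) & nzchar(as.character(lab))
    runs <- list()
    for (lv in unique(as.character(lab[keep]))) {
      sel <- which(keep & as.character(lab) == lv)
      sel <- sel[order(frame[sel])]
      fr <- frame[sel]
      if (anyDuplicated(fr)) {
        stop(sprintf("label %s occurs more than once in a frame; cannot form a linear link", lv))
      }
      seg_starts <- if (gap == "split") c(1L, which(diff(fr) > 1L) + 1L) else 1L
      seg_id <- findInterval(seq_along(sel), seg_starts)
      for (s in unique(seg_id)) {
        ids <- object_id[sel[seg_id == s]]
        if (length(ids) >= 2) runs[[length(runs) + 1]] <- ids
      }
    }
    if (length(runs)) {
      # deterministic link numbering by (first frame, first object id)
      firsts <- vapply(runs, function(r) r[1], integer(1))
      runs <- runs[order(objects$frame[match(firsts, objects$object_id)], firsts)]
      links <- data.frame(
        link_id = rep(seq_along(runs) - 1L, lengths(runs)),
        object_id = unlist(runs, use.names = FALSE)
      )
    }
  }

  pkg <- bt_package(objects, links)
  pkg$descriptor <- dialect_descriptor(pkg, "generic-csv", source_id_map)
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "converted package")
  pkg
}

#' Convert a CellProfiler-style tracking CSV
#'
#' Thin wrapper around [read_generic_csv()] with the CellProfiler defaults:
#' 1-based `ImageNumber` frames, `Location_Center_X`/`_Y` coordinates,
#' duplicate detection on `(ImageNumber, ObjectNumber)` and linking by the
#' `TrackObjects_Label` column.
#'
#' @inheritParams read_generic_csv
#' @param mapping a [column_mapping()]; defaults to [cellprofiler_mapping()].
#' @return A validated [bt_package()].
#' @export
read_cellprofiler <- function(path, mapping = cellprofiler_mapping(),
                              gap = c("split", "bridge")) {
  pkg <- read_generic_csv(path, mapping, gap = match.arg(gap))
  pkg$descriptor$biotracks$source_dialect <- "cellprofiler"
  pkg$descriptor$name <- "cellprofiler-import"
  pkg
}

# ---- TrackMate-style XML -----------------------------------------------------

# maximal linear chains of a directed edge list: interior nodes have
# in-degree = out-degree = 1; junction/terminal nodes end chains
chain_decompose <- function(edges) {
  if (!nrow(edges)) return(list())
  outdeg <- table(factor(edges$from, levels = unique(c(edges$from, edges$to))))
  indeg <- table(factor(edges$to, levels = unique(c(edges$from, edges$to))))
  deg_in <- function(v) as.integer(indeg[as.character(v)])
  deg_out <- function(v) as.integer(outdeg[as.character(v)])
  is_junction <- function(v) deg_in(v) != 1L || deg_out(v) != 1L
  nxt <- split(edges$to, edges$from)

  chains <- list()
  starts <- unique(edges$from[vapply(edges$from, is_junction, logical(1))])
  for (u in starts) {
    for (v in sort(as.integer(nxt[[as.character(u)]]))) {
      chain <- c(u, v)
      while (!is_junction(chain[length(chain)])) {
        chain <- c(chain, nxt[[as.character(chain[length(chain)])]])
      }
      chains[[length(chains) + 1]] <- as.integer(chain)
    }
  }
  chains
}

#' Convert a TrackMate-style XML tracking document
#'
#' Spots become objects: the `FRAME`, `POSITION_X`, `POSITION_Y` (and
#' optional `POSITION_Z`) attributes map to frame and coordinates, and every
#' other numeric spot attribute becomes a feature. Spot ids are remapped to
#' dense non-negative integers in sorted source order. The edge graph is
#' decomposed into maximal linear chains (a link is a maximal path whose
#' interior nodes have in-degree = out-degree = 1), so branch nodes end
#' chains and splits/merges surface as objects shared between links. When
#' the source groups edges into tracks, components are recomputed and a
#' warning is emitted if the grouping disagrees.
#'
#' @param path an XML file, literal XML string or `xml2` document.
#' @return A validated [bt_package()] with an inferred tracks table.
#' @export
read_trackmate <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (!length(spots)) stop("empty model: document contains no spots")

  attr_mat <- lapply(spots, xml2::xml_attrs)
  source_ids <- as.numeric(vapply(attr_mat, function(a) a[["ID"]], ""))
  if (any(is.na(source_ids))) stop("spot without a numeric ID attribute")
  rm <- remap_ids(source_ids)

  get_attr <- function(name) {
    vapply(attr_mat, function(a) if (name %in% names(a)) a[[name]] else NA_character_, "")
  }
  frame <- as.integer(get_attr("FRAME"))
  if (any(is.na(frame))) stop("spot without a FRAME attribute")
  objects <- data.frame(object_id = rm$new, frame = frame)
  objects$x <- as.numeric(get_attr("POSITION_X"))
  objects$y <- as.numeric(get_attr("POSITION_Y"))
  zv <- get_attr("POSITION_Z")
  if (!all(is.na(zv))) objects$z <- as.numeric(zv)

  reserved <- c("ID", "name", "FRAME", "POSITION_X", "POSITION_Y", "POSITION_Z")
  extra <- setdiff(unique(unlist(lapply(attr_mat, names))), reserved)
  for (at in extra) {
    v <- suppressWarnings(as.numeric(get_attr(at)))
    if (all(is.na(v))) {
      warning(sprintf("dropping non-numeric spot attribute %s", at))
    } else {
      objects[[at]] <- v
    }
  }
  objects <- objects[order(objects$object_id), , drop = FALSE]
  rownames(objects) <- NULL

  edge_nodes <- xml2::xml_find_all(doc, ".//AllTracks//Edge")
  src <- as.numeric(xml2::xml_attr(edge_nodes, "SPOT_SOURCE_ID"))
  tgt <- as.numeric(xml2::xml_attr(edge_nodes, "SPOT_TARGET_ID"))
  if (length(src) && (any(is.na(src)) || any(is.na(tgt)))) {
    stop("edge without numeric SPOT_SOURCE_ID/SPOT_TARGET_ID")
  }
  unknown <- setdiff(c(src, tgt), source_ids)
  if (length(unknown)) {
    stop("edge references unknown spot id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  from <- unname(rm$map[as.character(src)])
  to <- unname(rm$map[as.character(tgt)])
  # orient every edge forward in time
  ff <- objects$frame[match(from, objects$object_id)]
  tf <- objects$frame[match(to, objects$object_id)]
  if (any(ff == tf)) stop("edge connects two spots in the same frame")
  swap <- ff > tf
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  edges <- unique(data.frame(from = from, to = to))

  chains <- chain_decompose(edges)
  links <- data.frame(link_id = integer(0), object_id = integer(0))
  if (length(chains)) {
    firsts <- vapply(chains, function(ch) ch[1], integer(1))
    first_frames <- objects$frame[match(firsts, objects$object_id)]
    chains <- chains[order(first_frames, firsts,
                           vapply(chains, function(ch) ch[2], integer(1)))]
    links <- data.frame(
      link_id = rep(seq_along(chains) - 1L, lengths(chains)),
      object_id = unlist(chains, use.names = FALSE)
    )
  }

  tracks <- infer_tracks(objects, links, validate = FALSE)
  n_source_tracks <- length(xml2::xml_find_all(doc, ".//AllTracks/Track"))
  n_components <- if (nrow(tracks)) length(unique(tracks$track_id)) else 0L
  if (n_source_tracks > 0 && nrow(links) && n_source_tracks != n_components) {
    warning(sprintf(
      "source groups edges into %d track(s) but the edge graph has %d component(s); using recomputed components",
      n_source_tracks, n_components
    ))
  }

  pkg <- bt_package(objects, links, tracks)
  pkg$descriptor <- dialect_descriptor(pkg, "trackmate", rm$map)
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "converted package")
  pkg
}
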