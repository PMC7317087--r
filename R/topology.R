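# Lineage topology: the directed graph induced by the links, its weakly
# connected components (= tracks), split/merge events, and per-track motility
# statistics.

#' Build the directed lineage graph of a set of links
#'
#' Nodes are the objects referenced by at least one link; each consecutive
#' pair within a link contributes a directed parent-to-child edge. Duplicate
#' edges contributed by several links are collapsed into one edge whose
#' `link_ids` label lists every contributing link.
#'
#' @param objects,links validated objects / long-form links tables.
#' @param validate run [validate_objects()] / [validate_links()] first and
#'   refuse invalid input (default `TRUE`).
#' @return A `bt_lineage_graph`: list with `nodes` (integer object ids) and
#'   `edges`, a data.frame with columns `from`, `to` and list-column
#'   `link_ids`.
#' @export
build_lineage_graph <- function(objects, links, validate = TRUE) {
  if (validate) {
    rep <- combine_reports(validate_objects(objects), validate_links(objects, links))
    if (!rep$ok) stop_invalid(rep, "lineage graph input")
  }
  seqs <- link_sequences(links)
  pairs <- lapply(names(seqs), function(lid) {
    ids <- seqs[[lid]]
    if (length(ids) < 2) return(NULL)
    data.frame(from = ids[-length(ids)], to = ids[-1],
               link_id = as.integer(lid), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) {
    edges <- data.frame(from = integer(0), to = integer(0))
    edges$link_ids <- list()
    return(structure(list(nodes = integer(0), edges = edges),
                     class = "bt_lineage_graph"))
  }
  key <- paste(pairs$from, pairs$to)
  first <- !duplicated(key)
  edges <- pairs[first, c("from", "to")]
  edges$link_ids <- unname(lapply(split(pairs$link_id, key)[key[first]], sort))
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  nodes <- sort(unique(unlist(seqs, use.names = FALSE)))
  structure(list(nodes = nodes, edges = edges), class = "bt_lineage_graph")
}

#' @export
print.bt_lineage_graph <- function(x, ...) {
  cat(sprintf("<bt_lineage_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Infer the tracks table from objects and links
#'
#' A track is one weakly connected component of the lineage graph (edge
#' direction ignored), so splits and merges join links into a single lineage.
#' Components are mapped back to the links they contain, sorted by their
#' minimum contained `link_id`, and numbered from 0 -- deterministic and
#' independent of input order.
#'
#' @inheritParams build_lineage_graph
#' @return A long-form tracks data.frame (`track_id`, `link_id`), ordered by
#'   track then link id, that partitions the links.
#' @export
infer_tracks <- function(objects, links, validate = TRUE) {
  if (validate) {
    rep <- combine_reports(validate_objects(objects), validate_links(objects, links))
    if (!rep$ok) stop_invalid(rep, "track inference input")
  }
  seqs <- link_sequences(links)
  if (!length(seqs)) {
    return(data.frame(track_id = integer(0), link_id = integer(0)))
  }
  comp <- link_components(seqs)
  link_ids <- as.integer(names(seqs))
  min_per_comp <- tapply(link_ids, comp, min)
  ord <- rank(min_per_comp)  # component -> 1-based rank by smallest link id
  track_id <- as.integer(ord[as.character(comp)]) - 1L
  out <- data.frame(track_id = track_id, link_id = link_ids)
  out <- out[order(out$track_id, out$link_id), ]
  rownames(out) <- NULL
  out
}

#' Detect split and merge lineage events
#'
#' In the lineage graph, a split is a node with out-degree at least 2 (a
#' parent with more than one child) and a merge a node with in-degree at
#' least 2. Events are sorted by pivot frame, then pivot object id.
#'
#' @inheritParams build_lineage_graph
#' @return A data.frame with columns `kind` (`"split"`/`"merge"`),
#'   `pivot_object_id`, `frame`, and list-columns `upstream` and `downstream`
#'   holding the predecessor and successor object ids of the pivot. Zero rows
#'   when the lineage is branch-free.
#' @export
detect_events <- function(objects, links, validate = TRUE) {
  g <- build_lineage_graph(objects, links, validate = validate)
  empty <- data.frame(kind = character(0), pivot_object_id = integer(0),
                      frame = integer(0))
  empty$upstream <- list(); empty$downstream <- list()
  if (!nrow(g$edges)) return(empty)

  succ <- split(g$edges$to, g$edges$from)
  pred <- split(g$edges$from, g$edges$to)
  frame_of <- stats::setNames(objects$frame, objects$object_id)

  mk <- function(kind, pivots, nbr) {
    if (!length(pivots)) return(NULL)
    data.frame(kind = kind, pivot_object_id = as.integer(pivots),
               frame = as.integer(unname(frame_of[pivots])),
               stringsAsFactors = FALSE)
  }
  split_pivots <- names(succ)[lengths(succ) >= 2]
  merge_pivots <- names(pred)[lengths(pred) >= 2]
  ev <- rbind(mk("split", split_pivots), mk("merge", merge_pivots))
  if (is.null(ev)) return(empty)

  get_ids <- function(tbl, pivot) {
    v <- tbl[[as.character(pivot)]]
    if (is.null(v)) integer(0) else sort(unique(as.integer(v)))
  }
  ev$upstream <- lapply(ev$pivot_object_id, function(p) get_ids(pred, p))
  ev$downstream <- lapply(ev$pivot_object_id, function(p) get_ids(succ, p))
  ev <- ev[order(ev$frame, ev$pivot_object_id), ]
  rownames(ev) <- NULL
  ev
}

# ---- per-track statistics ----------------------------------------------------

# Principal path of a track: the root-to-leaf directed path with the largest
# frame span; ties broken by the smaller terminal object id, then smaller
# predecessor ids while backtracking. Returns the object ids along the path.
principal_path <- function(graph, objects) {
  nodes <- graph$nodes
  if (length(nodes) == 0) return(integer(0))
  frame_of <- stats::setNames(objects$frame, objects$object_id)
  node_frames <- unname(frame_of[as.character(nodes)])
  ord <- order(node_frames, nodes)
  nodes <- nodes[ord]
  pred <- split(graph$edges$from, graph$edges$to)

  # earliest reachable start frame, walking predecessors in frame order
  start_frame <- stats::setNames(unname(frame_of[as.character(nodes)]), nodes)
  best_pred <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (v in nodes) {
    ps <- pred[[as.character(v)]]
    if (is.null(ps)) next
    sf <- start_frame[as.character(ps)]
    m <- min(sf)
    if (m <= start_frame[as.character(v)]) {
      start_frame[as.character(v)] <- m
      cand <- sort(as.integer(ps[sf == m]))
      best_pred[as.character(v)] <- cand[1]
    }
  }
  span <- unname(frame_of[as.character(nodes)]) - unname(start_frame[as.character(nodes)])
  terminal <- nodes[order(-span, nodes)][1]
  path <- terminal
  while (!is.na(best_pred[as.character(path[1])])) {
    path <- c(best_pred[[as.character(path[1])]], path)
  }
  as.integer(path)
}

#' Motility statistics of one track
#'
#' Statistics are computed along the track's principal path: the directed
#' root-to-leaf path with the largest frame span (ties broken towards the
#' smaller terminal object id), since a branching lineage has no single
#' trajectory. `path_length` sums Euclidean step distances along that path,
#' `net_displacement` is the start-to-end distance,
#' `mean_speed = path_length / (duration_frames * frame_interval)` and the
#' confinement ratio is `net_displacement / path_length` (1 for straight
#' motion, 0 for a closed loop). Elapsed time uses the frame span, so
#' gap-closed links are timed correctly.
#'
#' @param track_links integer link ids belonging to the track.
#' @param objects,links validated tables of the enclosing package.
#' @param frame_interval physical time per frame (same for all frames), > 0.
#' @param track_id id recorded in the output row.
#' @return One-row data.frame with columns `track_id`, `n_objects`,
#'   `duration_frames`, `path_length`, `net_displacement`, `mean_speed`,
#'   `confinement_ratio`.
#' @export
track_stats <- function(track_links, objects, links, frame_interval = 1,
                        track_id = NA_integer_) {
  stopifnot(frame_interval > 0)
  sub <- links[links$link_id %in% track_links, , drop = FALSE]
  g <- build_lineage_graph(objects, sub, validate = FALSE)
  n_objects <- length(g$nodes)
  zero <- data.frame(track_id = as.integer(track_id), n_objects = n_objects,
                     duration_frames = 0L, path_length = 0, net_displacement = 0,
                     mean_speed = 0, confinement_ratio = 0)
  if (n_objects <= 1) {
    warning("track has fewer than two objects; statistics are zero")
    return(zero)
  }
  path <- principal_path(g, objects)
  rows <- objects[match(path, objects$object_id), , drop = FALSE]
  coord_cols <- intersect(c("x", "y", "z"), names(objects))
  xyz <- as.matrix(rows[, coord_cols, drop = FALSE])
  steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  path_length <- sum(steps)
  net <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  duration <- rows$frame[nrow(rows)] - rows$frame[1]
  data.frame(
    track_id = as.integer(track_id),
    n_objects = n_objects,
    duration_frames = as.integer(duration),
    path_length = path_length,
    net_displacement = net,
    mean_speed = if (duration > 0) path_length / (duration * frame_interval) else 0,
    confinement_ratio = if (path_length > 0) net / path_length else 0
  )
}

#' Motility statistics for every track of a package
#'
#' Applies [track_stats()] to each track (inferring the tracks table first
#' when the package lacks one) and returns one row per track, ordered by
#' `track_id`.
#'
#' @param pkg a valid [bt_package()].
#' @param frame_interval physical time per frame; defaults to the value
#'   recorded in the package descriptor, else 1.
#' @return data.frame of per-track statistics (zero rows if no links).
#' @export
package_stats <- function(pkg, frame_interval = NULL) {
  stopifnot(inherits(pkg, "bt_package"))
  if (is.null(frame_interval)) {
    frame_interval <- pkg$descriptor$biotracks$frame_interval
    if (is.null(frame_interval)) frame_interval <- 1
  }
  tracks <- pkg$tracks
  if (is.null(tracks)) tracks <- infer_tracks(pkg$objects, pkg$links)
  if (!nrow(tracks)) {
    out <- track_stats(integer(0), pkg$objects, pkg$links)[0, ]
    return(out)
  }
  rows <- lapply(sort(unique(tracks$track_id)), function(tid) {
    track_stats(tracks$link_id[tracks$track_id == tid], pkg$objects, pkg$links,
                frame_interval = frame_interval, track_id = tid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
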