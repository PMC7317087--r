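# Synthetic time-lapse tracking data with a ground-truth lineage ledger.
#
# Cells perform a biased 2D/3D random walk (isotropic Gaussian steps plus an
# optional drift). At a split the parent stream ends and two daughter streams
# start from the parent's last object, which they share; at a merge two
# streams end on one shared merged object from which a new stream starts.
# Each stream becomes one link, so splits and merges surface exactly as the
# shared-object branch points the topology module detects. Detection dropout
# removes interior objects of a stream, producing within-link frame gaps.
#
# Representational constraint of this encoding: a split pivot or merged
# object must have at least one frame before and after it, so events are
# only drawn at frames 1 .. n_frames-2; probabilities supplied for the
# boundary frames are ignored.

#' Configuration of the tracking-data simulator
#'
#' Defaults describe a desk-scale but realistic time-lapse experiment:
#' a handful of cells followed for tens of frames, step sizes of a couple of
#' spatial units per frame, rare divisions, rarer collisions-as-merges and a
#' few percent detection dropout.
#'
#' @param n_initial_cells cells present in frame 0.
#' @param n_frames number of frames (>= 2).
#' @param sigma isotropic Gaussian step s.d. per coordinate, units/frame.
#' @param drift drift vector per frame (length `ndim`).
#' @param p_split per-cell per-frame split probability; scalar or a vector
#'   indexed by pivot frame (length `n_frames`).
#' @param p_merge per-pair per-frame merge probability; scalar or a vector
#'   indexed by the merged object's frame (length `n_frames`).
#' @param p_dropout probability that an interior detection of a stream is
#'   missed, creating a frame gap inside the link.
#' @param merge_radius only pairs closer than this merge; default `3 * sigma`
#'   (unbounded when `sigma = 0`, so drift-only configs can still merge).
#' @param ndim 2 or 3 spatial dimensions.
#' @param arena side length of the square/cubic region seeding initial
#'   positions.
#' @param features named list of per-object feature generators; each entry is
#'   `list(dist = "lognormal", meanlog =, sdlog =)` or
#'   `list(dist = "normal", mean =, sd =)`.
#' @param seed RNG seed; identical configs and seeds give byte-identical
#'   packages.
#' @return An object of class `bt_sim_config`.
#' @export
simulation_config <- function(n_initial_cells = 10, n_frames = 40, sigma = 2,
                              drift = c(0, 0), p_split = 0.01, p_merge = 0.005,
                              p_dropout = 0.05, merge_radius = NULL, ndim = 2,
                              arena = 100,
                              features = list(area = list(dist = "lognormal",
                                                          meanlog = log(100),
                                                          sdlog = 0.25)),
                              seed = 1) {
  stopifnot(n_initial_cells >= 1, n_frames >= 2, sigma >= 0, ndim %in% c(2, 3))
  stopifnot(all(p_split >= 0 & p_split <= 1), all(p_merge >= 0 & p_merge <= 1))
  stopifnot(length(p_dropout) == 1, p_dropout >= 0, p_dropout <= 1)
  if (length(drift) == 1) drift <- rep(drift, ndim)
  stopifnot(length(drift) == ndim)
  if (is.null(merge_radius)) merge_radius <- if (sigma > 0) 3 * sigma else Inf
  expand <- function(p, what) {
    if (length(p) == 1) return(rep(p, n_frames))
    if (length(p) != n_frames) {
      stop(sprintf("%s must be a scalar or have length n_frames (%d)", what, n_frames))
    }
    p
  }
  structure(
    list(n_initial_cells = as.integer(n_initial_cells),
         n_frames = as.integer(n_frames), sigma = sigma, drift = drift,
         p_split = expand(p_split, "p_split"),
         p_merge = expand(p_merge, "p_merge"),
         p_dropout = p_dropout, merge_radius = merge_radius,
         ndim = as.integer(ndim), arena = arena, features = features,
         seed = as.integer(seed)),
    class = "bt_sim_config"
  )
}

#' Read a simulator configuration from YAML or JSON
#'
#' @param path file holding [simulation_config()] arguments.
#' @return A `bt_sim_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$drift)) cfg$drift <- as.numeric(unlist(cfg$drift))
  if (!is.null(cfg$p_split)) cfg$p_split <- as.numeric(unlist(cfg$p_split))
  if (!is.null(cfg$p_merge)) cfg$p_merge <- as.numeric(unlist(cfg$p_merge))
  do.call(simulation_config, cfg)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# minimal union-find over stream indices
uf_new <- function() new.env(parent = emptyenv())
uf_find <- function(uf, i) {
  key <- as.character(i)
  p <- uf[[key]]
  if (is.null(p) || p == i) return(i)
  r <- uf_find(uf, p)
  uf[[key]] <- r
  r
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[as.character(max(ra, rb))]] <- min(ra, rb)
  invisible()
}

#' Simulate a tracking dataset with known ground truth
#'
#' Runs the biased-random-walk lineage model of [simulation_config()] and
#' returns both the resulting tracking package and a ground-truth ledger:
#' the true split/merge events (kind, pivot object, frame), the true track
#' partition of the links, and the per-link object paths. By construction
#' the package passes [validate_package()], the ledger partition equals
#' [infer_tracks()] on the package, and [detect_events()] recovers exactly
#' the ledger's events.
#'
#' @param config a [simulation_config()].
#' @return list with elements `package` (a [bt_package()] with tracks table)
#'   and `ledger` (list `events`, `tracks`, `paths`, `n_splits`, `n_merges`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "bt_sim_config"))
  with_seed(config$seed, {
    ndim <- config$ndim
    nf <- config$n_frames

    oid <- integer(0); ofr <- integer(0)
    opos <- matrix(numeric(0), ncol = ndim)
    ofeat <- lapply(config$features, function(f) numeric(0))
    next_id <- 0L

    gen_features <- function() {
      vapply(config$features, function(f) {
        switch(f$dist %||% "lognormal",
               lognormal = stats::rlnorm(1, f$meanlog %||% 0, f$sdlog %||% 1),
               normal = stats::rnorm(1, f$mean %||% 0, f$sd %||% 1),
               stop("unknown feature distribution: ", f$dist))
      }, numeric(1))
    }
    new_object <- function(frame, pos) {
      id <- next_id; next_id <<- next_id + 1L
      oid <<- c(oid, id); ofr <<- c(ofr, as.integer(frame))
      opos <<- rbind(opos, pos)
      fv <- gen_features()
      for (nm in names(ofeat)) ofeat[[nm]] <<- c(ofeat[[nm]], fv[[nm]])
      id
    }

    streams <- list()  # each: objects (id vector), pos, alive
    uf <- uf_new()
    new_stream <- function(first_object, pos) {
      streams[[length(streams) + 1]] <<- list(objects = first_object, pos = pos,
                                              alive = TRUE)
      length(streams)
    }
    events <- list()

    for (i in seq_len(config$n_initial_cells)) {
      pos <- stats::runif(ndim, 0, config$arena)
      new_stream(new_object(0L, pos), pos)
    }

    step <- function(pos) {
      pos + config$drift + stats::rnorm(ndim, 0, config$sigma)
    }

    for (t in 0:(nf - 2L)) {
      # splits with pivot at frame t (needs a preceding frame in the parent)
      if (t >= 1 && config$p_split[t + 1L] > 0) {
        for (si in seq_along(streams)) {
          st <- streams[[si]]
          if (!st$alive || length(st$objects) < 2) next
          if (stats::runif(1) < config$p_split[t + 1L]) {
            pivot <- st$objects[length(st$objects)]
            streams[[si]]$alive <- FALSE
            d1 <- new_stream(pivot, st$pos)
            d2 <- new_stream(pivot, st$pos)
            uf_union(uf, si, d1); uf_union(uf, si, d2)
            events[[length(events) + 1]] <- list(kind = "split",
                                                 pivot = pivot, frame = t)
          }
        }
      }
      # merges into frame t+1 (merged object needs a following frame)
      if (t + 1L <= nf - 2L && config$p_merge[t + 2L] > 0) {
        alive_idx <- which(vapply(streams, function(s) s$alive, logical(1)))
        consumed <- integer(0)
        if (length(alive_idx) >= 2) {
          pairs <- utils::combn(alive_idx, 2)
          for (k in seq_len(ncol(pairs))) {
            a <- pairs[1, k]; b <- pairs[2, k]
            if (a %in% consumed || b %in% consumed) next
            sa <- streams[[a]]; sb <- streams[[b]]
            last_a <- sa$objects[length(sa$objects)]
            last_b <- sb$objects[length(sb$objects)]
            if (last_a == last_b) next  # sibling daughters share their pivot
            if (sqrt(sum((sa$pos - sb$pos)^2)) > config$merge_radius) next
            if (stats::runif(1) < config$p_merge[t + 2L]) {
              mid <- step((sa$pos + sb$pos) / 2)
              m <- new_object(t + 1L, mid)
              streams[[a]]$objects <- c(sa$objects, m)
              streams[[b]]$objects <- c(sb$objects, m)
              streams[[a]]$alive <- FALSE
              streams[[b]]$alive <- FALSE
              mi <- new_stream(m, mid)
              uf_union(uf, a, b); uf_union(uf, a, mi)
              consumed <- c(consumed, a, b)
              events[[length(events) + 1]] <- list(kind = "merge",
                                                   pivot = m, frame = t + 1L)
            }
          }
        }
      }
      # plain moves for every stream still lacking a frame t+1 object
      for (si in seq_along(streams)) {
        st <- streams[[si]]
        if (!st$alive) next
        if (ofr[match(st$objects[length(st$objects)], oid)] == t) {
          pos <- step(st$pos)
          streams[[si]]$objects <- c(st$objects, new_object(t + 1L, pos))
          streams[[si]]$pos <- pos
        }
      }
    }

    # dropout: interior detections only, so shared boundary objects survive
    dropped <- integer(0)
    if (config$p_dropout > 0) {
      for (si in seq_along(streams)) {
        objs <- streams[[si]]$objects
        if (length(objs) <= 2) next
        interior <- objs[-c(1, length(objs))]
        out <- interior[stats::runif(length(interior)) < config$p_dropout]
        if (length(out)) {
          streams[[si]]$objects <- setdiff(objs, out)
          dropped <- c(dropped, out)
        }
      }
    }

    objects <- data.frame(object_id = oid, frame = ofr)
    objects$x <- opos[, 1]
    objects$y <- opos[, 2]
    if (ndim == 3) objects$z <- opos[, 3]
    for (nm in names(ofeat)) objects[[nm]] <- ofeat[[nm]]
    paths <- lapply(streams, function(s) s$objects)
    ev_pivots <- vapply(events, `[[`, 0L, "pivot")
    if (length(dropped)) {
      # compact ids so the emitted package uses dense 0-based identifiers
      objects <- objects[!objects$object_id %in% dropped, , drop = FALSE]
      rownames(objects) <- NULL
      remap <- stats::setNames(seq_len(nrow(objects)) - 1L,
                               as.character(objects$object_id))
      objects$object_id <- unname(remap[as.character(objects$object_id)])
      paths <- lapply(paths, function(p) unname(remap[as.character(p)]))
      ev_pivots <- unname(remap[as.character(ev_pivots)])
    }
    links <- data.frame(
      link_id = rep(seq_along(paths) - 1L, lengths(paths)),
      object_id = unlist(paths, use.names = FALSE)
    )

    comp <- vapply(seq_along(streams), function(i) uf_find(uf, i), integer(1))
    min_link <- tapply(seq_along(streams) - 1L, comp, min)
    track_id <- as.integer(rank(min_link)[as.character(comp)]) - 1L
    tracks <- data.frame(track_id = track_id, link_id = seq_along(streams) - 1L)
    tracks <- tracks[order(tracks$track_id, tracks$link_id), , drop = FALSE]
    rownames(tracks) <- NULL

    ev <- if (length(events)) {
      data.frame(kind = vapply(events, `[[`, "", "kind"),
                 pivot_object_id = as.integer(ev_pivots),
                 frame = vapply(events, `[[`, 0L, "frame"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(kind = character(0), pivot_object_id = integer(0),
                 frame = integer(0))
    }
    ev <- ev[order(ev$frame, ev$pivot_object_id), , drop = FALSE]
    rownames(ev) <- NULL

    pkg <- bt_package(objects, links, tracks)
    pkg$descriptor <- default_descriptor(pkg, name = "simulated-tracking")
    pkg$descriptor$biotracks$simulation_seed <- config$seed
    rep <- validate_package(pkg)
    if (!rep$ok) stop_invalid(rep, "simulated package")  # generator contract

    list(package = pkg,
         ledger = list(events = ev, tracks = tracks,
                       paths = stats::setNames(paths, seq_along(paths) - 1L),
                       n_splits = sum(ev$kind == "split"),
                       n_merges = sum(ev$kind == "merge")))
  })
}

# ---- dialect fixture emitters ------------------------------------------------

#' Emit a package as a TrackMate-style XML document
#'
#' Spots carry `ID`, `FRAME`, `POSITION_X/Y[/Z]` and one attribute per
#' feature column; the deduplicated lineage-graph edges are grouped into one
#' `Track` element per track. [read_trackmate()] on the result reproduces
#' the lineage graph (node and edge sets by id) of `pkg`.
#'
#' @param pkg a valid [bt_package()].
#' @param path optional output file.
#' @return The `xml2` document (invisibly when `path` is given).
#' @export
emit_trackmate <- function(pkg, path = NULL) {
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "package to emit")
  obj <- pkg$objects
  g <- build_lineage_graph(obj, pkg$links, validate = FALSE)
  tracks <- pkg$tracks
  if (is.null(tracks)) tracks <- infer_tracks(obj, pkg$links, validate = FALSE)

  doc <- xml2::xml_new_root("TrackMate", version = "7.0")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel",
                               timeunits = "frame")
  all_spots <- xml2::xml_add_child(model, "AllSpots",
                                   nspots = as.character(nrow(obj)))
  feats <- feature_columns(obj)
  for (fr in sort(unique(obj$frame))) {
    sif <- xml2::xml_add_child(all_spots, "SpotsInFrame", frame = as.character(fr))
    rows <- obj[obj$frame == fr, , drop = FALSE]
    rows <- rows[order(rows$object_id), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      attrs <- c(
        ID = as.character(rows$object_id[i]),
        name = paste0("ID", rows$object_id[i]),
        FRAME = as.character(rows$frame[i]),
        POSITION_X = as.character(rows$x[i]),
        POSITION_Y = as.character(rows$y[i])
      )
      if ("z" %in% names(rows)) attrs <- c(attrs, POSITION_Z = as.character(rows$z[i]))
      for (fc in feats) attrs[[fc]] <- as.character(rows[[fc]][i])
      do.call(xml2::xml_add_child, c(list(sif, "Spot"), as.list(attrs)))
    }
  }

  all_tracks <- xml2::xml_add_child(model, "AllTracks")
  link_track <- stats::setNames(tracks$track_id, tracks$link_id)
  edge_track <- vapply(seq_len(nrow(g$edges)), function(i) {
    unname(link_track[as.character(g$edges$link_ids[[i]][1])])
  }, integer(1))
  for (tid in sort(unique(tracks$track_id))) {
    tr <- xml2::xml_add_child(all_tracks, "Track", TRACK_ID = as.character(tid),
                              name = paste0("Track_", tid))
    sel <- which(edge_track == tid)
    for (i in sel) {
      xml2::xml_add_child(tr, "Edge",
                          SPOT_SOURCE_ID = as.character(g$edges$from[i]),
                          SPOT_TARGET_ID = as.character(g$edges$to[i]))
    }
  }
  filtered <- xml2::xml_add_child(model, "FilteredTracks")
  for (tid in sort(unique(tracks$track_id))) {
    xml2::xml_add_child(filtered, "TrackID", TRACK_ID = as.character(tid))
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Emit a branch-free package as a CellProfiler-style tracking CSV
#'
#' The label-column dialect can only express one linear trajectory per label,
#' so packages in which any object is shared between links (splits or merges)
#' are refused with an `unexpressible_topology` error. Frames are written
#' 1-based as `ImageNumber` with a per-frame `ObjectNumber`, coordinates as
#' `Location_Center_X/_Y[/Z]`, the link id + 1 as `TrackObjects_Label`, and
#' features verbatim. Reading the result back with [read_cellprofiler()]
#' (gap policy `"bridge"` when links contain frame gaps) reproduces the
#' objects and links exactly.
#'
#' @param pkg a valid, branch-free [bt_package()].
#' @param path optional output CSV file.
#' @return The emitted data.frame (invisibly when `path` is given).
#' @export
emit_cellprofiler <- function(pkg, path = NULL) {
  rep <- validate_package(pkg)
  if (!rep$ok) stop_invalid(rep, "package to emit")
  if (anyDuplicated(pkg$links$object_id)) {
    cond <- structure(
      class = c("unexpressible_topology", "error", "condition"),
      list(message = paste(
        "unexpressible_topology: package contains split/merge events",
        "(objects shared between links); the label-column dialect cannot express them"
      ), call = sys.call(-1))
    )
    stop(cond)
  }
  obj <- pkg$objects[order(pkg$objects$frame, pkg$objects$object_id), , drop = FALSE]
  label_of <- stats::setNames(pkg$links$link_id + 1L, pkg$links$object_id)
  lab <- label_of[as.character(obj$object_id)]
  out <- data.frame(
    ImageNumber = obj$frame + 1L,
    ObjectNumber = stats::ave(obj$object_id, obj$frame,
                              FUN = function(v) seq_along(v)),
    Location_Center_X = obj$x,
    Location_Center_Y = obj$y
  )
  if ("z" %in% names(obj)) out$Location_Center_Z <- obj$z
  out$TrackObjects_Label <- ifelse(is.na(lab), "", as.character(lab))
  for (fc in feature_columns(pkg$objects)) out[[fc]] <- obj[[fc]]
  if (!is.null(path)) {
    write_csv_stable(out, path)
    return(invisible(out))
  }
  out
}
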