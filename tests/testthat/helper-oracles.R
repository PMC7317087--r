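# Independent brute-force oracles. These deliberately avoid the package's
# own graph machinery (igraph) so they can cross-check it.

# connected components of links over shared objects, by naive depth-first
# search; returns a partition as a list of sorted link-id vectors, itself
# sorted by smallest member
dfs_link_components <- function(links) {
  seqs <- split(links$object_id, links$link_id)
  lids <- names(seqs)
  n <- length(lids)
  if (!n) return(list())
  shares <- function(i, j) length(intersect(seqs[[i]], seqs[[j]])) > 0
  visited <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- s
    comp <- integer(0)
    visited[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in seq_len(n)) {
        if (!visited[w] && shares(v, w)) {
          visited[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(as.integer(lids[comp]))
  }
  comps[order(vapply(comps, min, 0L))]
}

# tracks data.frame -> the same canonical partition representation
tracks_to_partition <- function(tracks) {
  comps <- lapply(split(tracks$link_id, tracks$track_id), function(v) sort(as.integer(v)))
  comps <- unname(comps)
  comps[order(vapply(comps, min, 0L))]
}

# all consecutive object pairs over all links, deduplicated
enumerate_edges <- function(links) {
  seqs <- split(links$object_id, factor(links$link_id, levels = unique(links$link_id)))
  pairs <- do.call(rbind, lapply(seqs, function(ids) {
    if (length(ids) < 2) return(NULL)
    cbind(ids[-length(ids)], ids[-1])
  }))
  if (is.null(pairs)) return(character(0))
  sort(unique(paste(pairs[, 1], pairs[, 2])))
}

# random linear links over a pool of objects: each link picks a sorted
# subset of frames; some links are forced to share endpoints to create
# junctions
random_link_instance <- function(n_objects = 60, n_links = 25, share_prob = 0.3) {
  resample <- function(x, k = 1) x[sample.int(length(x), k)]
  frames <- sample(0:29, n_objects, replace = TRUE)
  objects <- data.frame(object_id = 0:(n_objects - 1), frame = frames,
                        x = runif(n_objects, 0, 50), y = runif(n_objects, 0, 50))
  links <- list()
  for (l in seq_len(n_links)) {
    if (length(links) && runif(1) < share_prob) {
      # branch off an existing link at one of its objects
      base <- links[[sample.int(length(links), 1)]]
      anchor <- resample(base)
      pool <- setdiff(which(objects$frame > objects$frame[anchor + 1]) - 1L, anchor)
      if (length(pool) >= 1) {
        k <- sample.int(min(3, length(pool)), 1)
        ids <- resample(pool, k)
        ids <- ids[order(objects$frame[ids + 1], ids)]
        ids <- ids[!duplicated(objects$frame[ids + 1])]
        if (length(ids) >= 1) {
          links[[length(links) + 1]] <- c(anchor, ids)
          next
        }
      }
    }
    k <- sample(2:5, 1)
    ids <- resample(0:(n_objects - 1), k)
    ids <- ids[order(objects$frame[ids + 1], ids)]
    ids <- ids[!duplicated(objects$frame[ids + 1])]
    if (length(ids) >= 2) links[[length(links) + 1]] <- ids
  }
  links_df <- data.frame(
    link_id = rep(seq_along(links) - 1L, lengths(links)),
    object_id = as.integer(unlist(links))
  )
  list(objects = objects, links = links_df)
}

expect_package_equal <- function(a, b, tol = 1e-12) {
  expect_identical(a$objects$object_id, b$objects$object_id)
  expect_identical(a$objects$frame, b$objects$frame)
  for (cc in intersect(c("x", "y", "z"), names(a$objects))) {
    expect_equal(a$objects[[cc]], b$objects[[cc]], tolerance = tol)
  }
  expect_setequal(feature_columns(a$objects), feature_columns(b$objects))
  for (fc in feature_columns(a$objects)) {
    expect_equal(a$objects[[fc]], b$objects[[fc]], tolerance = tol)
  }
  expect_identical(a$links, b$links)
  if (!is.null(a$tracks) && !is.null(b$tracks)) {
    expect_identical(a$tracks, b$tracks)
  }
}

lineage_graph_equal <- function(pkg_a, pkg_b) {
  ga <- build_lineage_graph(pkg_a$objects, pkg_a$links, validate = FALSE)
  gb <- build_lineage_graph(pkg_b$objects, pkg_b$links, validate = FALSE)
  identical(ga$nodes, gb$nodes) &&
    identical(ga$edges[c("from", "to")], gb$edges[c("from", "to")])
}
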