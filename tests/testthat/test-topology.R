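test_that("lineage graph edges follow link adjacency and collapse duplicates", {
  pkg <- fixture_split()
  g <- build_lineage_graph(pkg$objects, pkg$links)
  expect_identical(g$nodes, 0:3)
  expect_identical(paste(g$edges$from, g$edges$to), c("0 1", "1 2", "1 3"))
  expect_identical(sum(g$edges$from == 1L), 2L)  # out-degree 2 at the pivot

  # two links sharing an edge: collapsed with both labels retained
  obj <- data.frame(object_id = 0:2, frame = 0:2, x = 0:2, y = 0:2)
  lnk <- data.frame(link_id = c(0L, 0L, 1L, 1L), object_id = c(0L, 1L, 0L, 1L))
  g2 <- build_lineage_graph(obj, lnk)
  expect_identical(nrow(g2$edges), 1L)
  expect_identical(g2$edges$link_ids[[1]], c(0L, 1L))
})

test_that("lineage graph edge census matches brute-force pair enumeration", {
  set.seed(202)
  for (trial in 1:10) {
    inst <- random_link_instance(n_objects = 80, n_links = 40)
    g <- build_lineage_graph(inst$objects, inst$links)
    expect_identical(sort(paste(g$edges$from, g$edges$to)),
                     enumerate_edges(inst$links))
  }
})

test_that("invalid input is rejected by the topology layer", {
  obj <- data.frame(object_id = 0:1, frame = 0:1, x = c(0, 1), y = c(0, 1))
  bad <- data.frame(link_id = 0L, object_id = c(0L, 99L))
  expect_error(build_lineage_graph(obj, bad), class = "bt_validation_error")
  expect_error(infer_tracks(obj, bad), class = "bt_validation_error")
})

test_that("shared objects join links into one track, disjoint links stay apart", {
  obj <- data.frame(object_id = 0:3, frame = 0:3, x = 0:3, y = 0:3)
  shared <- data.frame(link_id = c(0L, 0L, 0L, 1L, 1L),
                       object_id = c(0L, 1L, 2L, 2L, 3L))
  tr <- infer_tracks(obj, shared)
  expect_identical(unique(tr$track_id), 0L)

  obj2 <- data.frame(object_id = 0:3, frame = c(0L, 1L, 0L, 1L), x = 0:3, y = 0:3)
  disjoint <- data.frame(link_id = c(0L, 0L, 1L, 1L), object_id = 0:3)
  tr2 <- infer_tracks(obj2, disjoint)
  expect_identical(tr2$track_id, 0:1)
})

test_that("inferred components equal brute-force DFS on random instances", {
  set.seed(303)
  for (trial in 1:25) {
    inst <- random_link_instance(n_objects = 100, n_links = 50)
    tr <- infer_tracks(inst$objects, inst$links)
    expect_identical(tracks_to_partition(tr), dfs_link_components(inst$links))
  }
})

test_that("track inference is invariant to link input order and relabeling", {
  sim <- fixture_sim_events(seed = 2)
  pkg <- sim$package
  base <- infer_tracks(pkg$objects, pkg$links)

  # shuffle link blocks
  seqs <- split(pkg$links$object_id, pkg$links$link_id)
  perm <- sample(names(seqs))
  shuffled <- data.frame(
    link_id = as.integer(rep(perm, lengths(seqs[perm]))),
    object_id = unlist(seqs[perm], use.names = FALSE)
  )
  expect_identical(infer_tracks(pkg$objects, shuffled), base)

  # relabel link ids by an order-preserving shift: same partition content
  shifted <- pkg$links
  shifted$link_id <- shifted$link_id + 10L
  tr_shift <- infer_tracks(pkg$objects, shifted)
  expect_identical(tr_shift$track_id, base$track_id)
  expect_identical(tr_shift$link_id, base$link_id + 10L)
})

test_that("for a forest of disjoint linear links, #tracks equals #links", {
  sim <- fixture_sim_branchfree(seed = 12)
  tr <- infer_tracks(sim$package$objects, sim$package$links)
  expect_identical(length(unique(tr$track_id)),
                   length(unique(sim$package$links$link_id)))
})

test_that("splits and merges are detected with correct pivots and neighbours", {
  sp <- fixture_split()
  ev <- detect_events(sp$objects, sp$links)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "split")
  expect_identical(ev$pivot_object_id, 1L)
  expect_identical(ev$downstream[[1]], c(2L, 3L))

  mg <- fixture_merge()
  ev2 <- detect_events(mg$objects, mg$links)
  expect_identical(ev2$kind, "merge")
  expect_identical(ev2$pivot_object_id, 2L)
  expect_identical(ev2$upstream[[1]], c(0L, 1L))
})

test_that("branch-free packages yield no events", {
  sim <- fixture_sim_branchfree(seed = 4, dropout = 0.1)
  ev <- detect_events(sim$package$objects, sim$package$links)
  expect_identical(nrow(ev), 0L)
})

test_that("detector recovers the simulator event ledger across seeds", {
  for (s in 1:20) {
    sim <- simulate_tracks(simulation_config(
      n_initial_cells = 5, n_frames = 20, p_split = 0.05, p_merge = 0.03,
      p_dropout = 0.05, seed = s
    ))
    ev <- detect_events(sim$package$objects, sim$package$links)
    expect_identical(ev[c("kind", "pivot_object_id", "frame")],
                     sim$ledger$events)
    tr <- infer_tracks(sim$package$objects, sim$package$links)
    expect_identical(tr, sim$ledger$tracks)
  }
})

test_that("straight-line and closed-loop tracks give their closed-form statistics", {
  pkg <- fixture_345()
  st <- track_stats(0L, pkg$objects, pkg$links, frame_interval = 1, track_id = 0L)
  expect_equal(st$path_length, 5)
  expect_equal(st$net_displacement, 5)
  expect_equal(st$mean_speed, 5)
  expect_equal(st$confinement_ratio, 1)

  sq <- fixture_square()
  st2 <- track_stats(0L, sq$objects, sq$links)
  expect_equal(st2$net_displacement, 0)
  expect_equal(st2$confinement_ratio, 0)
  expect_equal(st2$path_length, 4)
})

test_that("path length of a random walk equals direct step summation", {
  sim <- simulate_tracks(simulation_config(
    n_initial_cells = 1, n_frames = 51, sigma = 1, p_split = 0, p_merge = 0,
    p_dropout = 0, seed = 21
  ))
  pkg <- sim$package
  st <- track_stats(0L, pkg$objects, pkg$links, track_id = 0L)
  o <- pkg$objects[match(pkg$links$object_id, pkg$objects$object_id), ]
  oracle <- sum(sqrt(diff(o$x)^2 + diff(o$y)^2))
  expect_equal(st$path_length, oracle, tolerance = 1e-9)
  expect_true(st$path_length >= st$net_displacement)
  expect_true(st$confinement_ratio >= 0 && st$confinement_ratio <= 1)
})

test_that("mean speed uses the frame span, so gap-closed links are timed right", {
  obj <- data.frame(object_id = 0:1, frame = c(0L, 5L), x = c(0, 10), y = c(0, 0))
  lnk <- data.frame(link_id = c(0L, 0L), object_id = 0:1)
  st <- track_stats(0L, obj, lnk, frame_interval = 2, track_id = 0L)
  expect_equal(st$duration_frames, 5L)
  expect_equal(st$mean_speed, 10 / (5 * 2))
})

test_that("statistics follow the longest root-to-leaf path in branching tracks", {
  # split at 1; one daughter runs 2 more frames, the other stops immediately
  obj <- data.frame(object_id = 0:4, frame = c(0L, 1L, 2L, 2L, 3L),
                    x = c(0, 1, 2, 9, 3), y = 0)
  lnk <- data.frame(link_id = c(0L, 0L, 1L, 1L, 1L, 2L, 2L),
                    object_id = c(0L, 1L, 1L, 2L, 4L, 1L, 3L))
  st <- track_stats(0:2, obj, lnk, track_id = 0L)
  expect_identical(st$duration_frames, 3L)   # path 0-1-2-4, not 0-1-3
  expect_equal(st$path_length, 3)
})

test_that("per-package statistics cover every ledger track", {
  sim <- fixture_sim_events(seed = 8)
  st <- package_stats(sim$package)
  expect_identical(st$track_id, sort(unique(sim$ledger$tracks$track_id)))
  expect_true(all(st$path_length >= st$net_displacement))
})
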