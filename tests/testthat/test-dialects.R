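test_that("a linear TrackMate chain becomes one link and one track", {
  d <- withr::local_tempdir()
  path <- write_tm_fixture_xml(file.path(d, "tm.xml"))
  # drop the branch edge to get a pure chain 10 -> 11 -> 12
  txt <- readLines(path)
  txt <- txt[!grepl('SPOT_TARGET_ID="13"', txt)]
  writeLines(txt, path)
  pkg <- read_trackmate(path)
  expect_identical(nrow(pkg$objects), 4L)
  # source ids 10..13 remapped densely in sorted order
  expect_identical(pkg$objects$object_id, 0:3)
  expect_identical(link_ids_of(pkg), list(`0` = c(0L, 1L, 2L)))
  expect_identical(unique(pkg$tracks$track_id), 0L)
  expect_identical(pkg$objects$QUALITY, c(1.5, 2.5, 3.5, 4.5))
})

test_that("a TrackMate branch decomposes into chains sharing the pivot", {
  d <- withr::local_tempdir()
  pkg <- read_trackmate(write_tm_fixture_xml(file.path(d, "tm.xml")))
  seqs <- link_ids_of(pkg)
  expect_length(seqs, 3L)
  # chains end/start at the branch node (source id 11 -> dense id 1)
  expect_identical(unname(seqs[[1]]), c(0L, 1L))
  expect_setequal(vapply(seqs[-1], `[`, 0L, 1), 1L)
  ev <- detect_events(pkg$objects, pkg$links)
  expect_identical(ev$kind, "split")
  expect_identical(ev$downstream[[1]], c(2L, 3L))
})

test_that("TrackMate conversion preserves cardinalities and lineage", {
  for (s in c(3, 14)) {
    sim <- fixture_sim_events(seed = s)
    d <- withr::local_tempdir()
    emit_trackmate(sim$package, file.path(d, "sim.xml"))
    back <- read_trackmate(file.path(d, "sim.xml"))
    expect_identical(nrow(back$objects), nrow(sim$package$objects))
    expect_true(lineage_graph_equal(sim$package, back))
    # sum(len - 1) over links equals the deduplicated edge count
    g <- build_lineage_graph(back$objects, back$links, validate = FALSE)
    expect_identical(sum(table(back$links$link_id) - 1L), nrow(g$edges))
    # split/merge census identical to the source package
    ev_src <- detect_events(sim$package$objects, sim$package$links)
    ev_back <- detect_events(back$objects, back$links)
    expect_identical(ev_back[c("kind", "pivot_object_id", "frame")],
                     ev_src[c("kind", "pivot_object_id", "frame")])
  }
})

test_that("malformed TrackMate documents are rejected with clear errors", {
  expect_error(read_trackmate("<TrackMate><Model/></TrackMate>"), "no spots")
  bad_edge <- paste0(
    '<TrackMate><Model><AllSpots><SpotsInFrame frame="0">',
    '<Spot ID="1" FRAME="0" POSITION_X="0" POSITION_Y="0"/></SpotsInFrame>',
    '<SpotsInFrame frame="1">',
    '<Spot ID="2" FRAME="1" POSITION_X="1" POSITION_Y="0"/></SpotsInFrame>',
    '</AllSpots><AllTracks><Track>',
    '<Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="7"/>',
    '</Track></AllTracks></Model></TrackMate>'
  )
  expect_error(read_trackmate(bad_edge), "unknown spot")
  expect_error(read_trackmate("<oops"), class = "error")
})

test_that("CellProfiler rows with 1-based frames normalize to 0-based links", {
  df <- data.frame(
    ImageNumber = 1:4, ObjectNumber = 1L,
    Location_Center_X = c(0, 1, 2, 3), Location_Center_Y = 0,
    TrackObjects_Label = 5L
  )
  pkg <- read_cellprofiler(df)
  expect_identical(pkg$objects$frame, 0:3)
  expect_identical(link_ids_of(pkg), list(`0` = 0:3))
})

test_that("interleaved labels give disjoint links and tracks", {
  df <- data.frame(
    ImageNumber = c(1L, 1L, 2L, 2L), ObjectNumber = c(1L, 2L, 1L, 2L),
    Location_Center_X = c(0, 10, 1, 11), Location_Center_Y = 0,
    TrackObjects_Label = c(1L, 2L, 1L, 2L)
  )
  pkg <- read_cellprofiler(df)
  expect_length(link_ids_of(pkg), 2L)
  tr <- infer_tracks(pkg$objects, pkg$links)
  expect_identical(length(unique(tr$track_id)), 2L)
})

test_that("label gaps split links under the default policy, bridge keeps one", {
  df <- data.frame(
    ImageNumber = c(1L, 2L, 6L, 7L), ObjectNumber = 1L,
    Location_Center_X = 1:4, Location_Center_Y = 0,
    TrackObjects_Label = 1L
  )
  # oracle: brute-force segmentation of the frame runs {0,1} and {5,6}
  frames <- sort(df$ImageNumber - 1L)
  runs <- split(frames, cumsum(c(1L, diff(frames) > 1L)))
  expect_length(runs, 2L)

  pkg <- read_cellprofiler(df)  # default gap = "split"
  expect_length(link_ids_of(pkg), length(runs))
  pkg2 <- read_cellprofiler(df, gap = "bridge")
  expect_length(link_ids_of(pkg2), 1L)
})

test_that("duplicate (frame, object-number) rows are refused", {
  df <- data.frame(
    ImageNumber = c(1L, 1L), ObjectNumber = c(1L, 1L),
    Location_Center_X = c(0, 1), Location_Center_Y = 0,
    TrackObjects_Label = c(1L, 2L)
  )
  expect_error(read_cellprofiler(df), "duplicate")
})

test_that("generic CSV without a label column yields objects only, with warning", {
  df <- data.frame(t = 0:9, px = rnorm(10), py = rnorm(10))
  mp <- column_mapping(frame = "t", x = "px", y = "py")
  expect_warning(pkg <- read_generic_csv(df, mp), "no_linking_column")
  expect_identical(nrow(pkg$objects), 10L)
  expect_identical(nrow(pkg$links), 0L)
  rep <- validate_package(pkg)
  expect_true(rep$ok)
  expect_true("no_links" %in% rep$issues$code)
})

test_that("frame-base normalization makes 1-based input identical to 0-based", {
  base0 <- data.frame(t = 0:3, px = c(0, 1, 2, 3), py = 0, lab = 1L)
  base1 <- transform(base0, t = t + 1L)
  m0 <- column_mapping(frame = "t", x = "px", y = "py", label = "lab", frame_base = 0)
  m1 <- column_mapping(frame = "t", x = "px", y = "py", label = "lab", frame_base = 1)
  p0 <- read_generic_csv(base0, m0)
  p1 <- read_generic_csv(base1, m1)
  expect_package_equal(p0, p1)
})

test_that("non-numeric source columns are dropped from features with a warning", {
  df <- data.frame(t = 0:1, px = c(0, 1), py = 0, lab = 1L,
                   note = c("a", "b"), area = c(3, 4))
  mp <- column_mapping(frame = "t", x = "px", y = "py", label = "lab")
  expect_warning(pkg <- read_generic_csv(df, mp), "non-numeric")
  expect_identical(feature_columns(pkg$objects), "area")
})

test_that("a mapping naming absent columns is refused", {
  df <- data.frame(t = 0:1, px = c(0, 1), py = 0)
  mp <- column_mapping(frame = "t", x = "missing_x", y = "py")
  expect_error(read_generic_csv(df, mp), "absent")
  expect_error(column_mapping(frame = "t", x = "t", y = "py"), "distinct")
})

test_that("simulator exports round-trip through the generic reader", {
  sim <- fixture_sim_branchfree(seed = 18)
  d <- withr::local_tempdir()
  emit_cellprofiler(sim$package, file.path(d, "cp.csv"))
  mp <- column_mapping(frame = "ImageNumber", x = "Location_Center_X",
                       y = "Location_Center_Y", label = "TrackObjects_Label",
                       object_number = "ObjectNumber", frame_base = 1)
  back <- read_generic_csv(file.path(d, "cp.csv"), mp)
  expect_package_equal(sim$package, back)
})
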