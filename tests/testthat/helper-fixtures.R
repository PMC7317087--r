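# Tiny in-code fixtures shared across test files.

# the 3-4-5 straight-line track: two objects one frame apart
fixture_345 <- function() {
  obj <- data.frame(object_id = 0:1, frame = 0:1, x = c(0, 3), y = c(0, 4))
  lnk <- data.frame(link_id = c(0L, 0L), object_id = 0:1)
  bt_package(obj, lnk)
}

# a closed unit square returning to the origin
fixture_square <- function() {
  obj <- data.frame(object_id = 0:4, frame = 0:4,
                    x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  lnk <- data.frame(link_id = rep(0L, 5), object_id = 0:4)
  bt_package(obj, lnk)
}

# one split: parent [0,1], daughters [1,2] and [1,3]
fixture_split <- function() {
  obj <- data.frame(object_id = 0:3, frame = c(0L, 1L, 2L, 2L),
                    x = c(0, 1, 2, 2), y = c(0, 0, 1, -1))
  lnk <- data.frame(link_id = c(0L, 0L, 1L, 1L, 2L, 2L),
                    object_id = c(0L, 1L, 1L, 2L, 1L, 3L))
  bt_package(obj, lnk)
}

# one merge: [0,2] and [1,2] flow into [2,3]
fixture_merge <- function() {
  obj <- data.frame(object_id = 0:3, frame = c(0L, 0L, 1L, 2L),
                    x = c(0, 0, 1, 2), y = c(1, -1, 0, 0))
  lnk <- data.frame(link_id = c(0L, 0L, 1L, 1L, 2L, 2L),
                    object_id = c(0L, 2L, 1L, 2L, 2L, 3L))
  bt_package(obj, lnk)
}

# branch-free deterministic simulation, handy for dialect round trips
fixture_sim_branchfree <- function(seed = 7, dropout = 0) {
  simulate_tracks(simulation_config(
    n_initial_cells = 4, n_frames = 12, sigma = 1.5,
    p_split = 0, p_merge = 0, p_dropout = dropout, seed = seed
  ))
}

# mixed-event simulation at desk scale
fixture_sim_events <- function(seed = 1) {
  simulate_tracks(simulation_config(
    n_initial_cells = 6, n_frames = 25, sigma = 2,
    p_split = 0.04, p_merge = 0.02, p_dropout = 0.05, seed = seed
  ))
}

write_tm_fixture_xml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<TrackMate version="7.0"><Model spatialunits="pixel" timeunits="frame">',
    '<AllSpots nspots="4">',
    '<SpotsInFrame frame="0"><Spot ID="10" name="ID10" FRAME="0" POSITION_X="0" POSITION_Y="0" QUALITY="1.5"/></SpotsInFrame>',
    '<SpotsInFrame frame="1"><Spot ID="11" name="ID11" FRAME="1" POSITION_X="1" POSITION_Y="0" QUALITY="2.5"/></SpotsInFrame>',
    '<SpotsInFrame frame="2"><Spot ID="12" name="ID12" FRAME="2" POSITION_X="2" POSITION_Y="1" QUALITY="3.5"/>',
    '<Spot ID="13" name="ID13" FRAME="2" POSITION_X="2" POSITION_Y="-1" QUALITY="4.5"/></SpotsInFrame>',
    '</AllSpots>',
    '<AllTracks><Track TRACK_ID="0" name="Track_0">',
    '<Edge SPOT_SOURCE_ID="10" SPOT_TARGET_ID="11"/>',
    '<Edge SPOT_SOURCE_ID="11" SPOT_TARGET_ID="12"/>',
    '<Edge SPOT_SOURCE_ID="11" SPOT_TARGET_ID="13"/>',
    '</Track></AllTracks>',
    '<FilteredTracks><TrackID TRACK_ID="0"/></FilteredTracks>',
    '</Model></TrackMate>'
  ), path)
  path
}

# error-severity codes of a whole-package validation
report_codes_of <- function(pkg) {
  rep <- validate_package(pkg)
  rep$issues$code[rep$issues$severity == "error"]
}

# ordered object-id sequences per link
link_ids_of <- function(pkg) {
  lapply(split(pkg$links$object_id, pkg$links$link_id), as.integer)
}

# remove a dot-notation path from a nested document
delete_path <- function(doc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  walk <- function(node, ps) {
    if (length(ps) == 1) {
      node[[ps]] <- NULL
      return(node)
    }
    node[[ps[1]]] <- walk(node[[ps[1]]], ps[-1])
    node
  }
  walk(doc, parts)
}
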