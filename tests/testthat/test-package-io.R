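test_that("a minimal package writes three files with long-form link rows", {
  d <- withr::local_tempdir()
  write_biotracks(fixture_345(), d)
  expect_setequal(list.files(d), c("datapackage.json", "objects.csv", "links.csv"))
  links_lines <- readLines(file.path(d, "links.csv"))
  expect_identical(length(links_lines), 3L)  # header + one row per (link, object)
  expect_identical(links_lines[1], "cmso_link_id,cmso_object_id")
})

test_that("write/read round trip is value-identical across simulator seeds", {
  for (s in 1:8) {
    sim <- simulate_tracks(simulation_config(seed = s, n_initial_cells = 5,
                                             n_frames = 20))
    d <- withr::local_tempdir()
    write_biotracks(sim$package, d)
    back <- read_biotracks(d)
    expect_package_equal(sim$package, back)
  }
})

test_that("double-writing the same package is byte-identical", {
  sim <- fixture_sim_events(seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_biotracks(sim$package, d1)
  write_biotracks(sim$package, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # and write(read(write(pkg))) is byte-stable too
  d3 <- withr::local_tempdir()
  write_biotracks(read_biotracks(d1), d3)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d3, f), "raw", 1e7),
                     label = f)
  }
})

test_that("objects schema lists exactly the columns of the in-memory table", {
  obj <- data.frame(object_id = 0:1, frame = 0:1, x = c(0, 1), y = c(0, 1),
                    z = c(2, 3), area = c(10, 11), intensity = c(0.5, 0.7))
  lnk <- data.frame(link_id = c(0L, 0L), object_id = 0:1)
  d <- withr::local_tempdir()
  write_biotracks(bt_package(obj, lnk), d)
  desc <- jsonlite::fromJSON(file.path(d, "datapackage.json"),
                             simplifyVector = FALSE)
  res <- Filter(function(r) r$name == "objects", desc$resources)[[1]]
  declared <- vapply(res$schema$fields, `[[`, "", "name")
  expect_setequal(declared, c("cmso_object_id", "cmso_frame_id", "cmso_x_coord",
                              "cmso_y_coord", "cmso_z_coord", "area", "intensity"))
})

test_that("invalid packages are refused at write time with the report attached", {
  pkg <- fixture_345()
  pkg$links$object_id[2] <- 99L
  err <- tryCatch(write_biotracks(pkg, withr::local_tempdir()),
                  bt_validation_error = function(e) e)
  expect_s3_class(err$report, "bt_report")
  expect_true("dangling_reference" %in% err$report$issues$code)
})

test_that("missing resource files and descriptors are reported as such", {
  d <- withr::local_tempdir()
  sim <- fixture_sim_branchfree()
  write_biotracks(sim$package, d)
  file.remove(file.path(d, "links.csv"))
  err <- tryCatch(read_biotracks(d), bt_validation_error = function(e) e)
  expect_true("missing_resource" %in% err$report$issues$code)

  expect_error(read_biotracks(withr::local_tempdir()),
               class = "bt_validation_error")
})

test_that("hand-written fixtures with extra feature columns are preserved", {
  d <- withr::local_tempdir()
  writeLines(c(
    "cmso_object_id,cmso_frame_id,cmso_x_coord,cmso_y_coord,area,roundness",
    "0,0,1.5,2.5,30,0.9", "1,1,2.5,3.5,31,0.8"
  ), file.path(d, "objects.csv"))
  writeLines(c("cmso_link_id,cmso_object_id", "0,0", "0,1"),
             file.path(d, "links.csv"))
  desc <- list(
    name = "fixture", profile = "tabular-data-package",
    biotracks = list(
      format_version = "0.1",
      bindings = list(object_id = "cmso_object_id", frame = "cmso_frame_id",
                      x = "cmso_x_coord", y = "cmso_y_coord")
    ),
    resources = list(
      list(name = "objects", path = "objects.csv", schema = list(fields = list(
        list(name = "cmso_object_id", type = "integer"),
        list(name = "cmso_frame_id", type = "integer"),
        list(name = "cmso_x_coord", type = "number"),
        list(name = "cmso_y_coord", type = "number"),
        list(name = "area", type = "integer"),
        list(name = "roundness", type = "number")
      ))),
      list(name = "links", path = "links.csv", schema = list(fields = list(
        list(name = "cmso_link_id", type = "integer"),
        list(name = "cmso_object_id", type = "integer")
      )))
    )
  )
  jsonlite::write_json(desc, file.path(d, "datapackage.json"),
                       auto_unbox = TRUE, digits = NA)
  pkg <- read_biotracks(d)
  # oracle: the raw CSV parse
  raw <- utils::read.csv(file.path(d, "objects.csv"))
  expect_identical(pkg$objects$area, raw$area)
  expect_identical(pkg$objects$roundness, raw$roundness)
  expect_setequal(feature_columns(pkg$objects), c("area", "roundness"))
})

test_that("tracks can be materialized on request but never silently", {
  sim <- fixture_sim_events(seed = 10)
  pkg <- sim$package
  pkg$tracks <- NULL
  d <- withr::local_tempdir()
  write_biotracks(pkg, d)
  expect_false(file.exists(file.path(d, "tracks.csv")))
  plain <- read_biotracks(d)
  expect_null(plain$tracks)
  mat <- read_biotracks(d, materialize_tracks = TRUE)
  expect_identical(mat$tracks, sim$ledger$tracks)
})

test_that("descriptor defects are flagged by the structural validator", {
  sim <- fixture_sim_branchfree()
  d <- withr::local_tempdir()
  write_biotracks(sim$package, d)
  desc <- jsonlite::fromJSON(file.path(d, "datapackage.json"),
                             simplifyVector = FALSE)
  expect_true(validate_descriptor(desc)$ok)

  no_obj <- desc
  no_obj$resources <- Filter(function(r) r$name != "objects", no_obj$resources)
  expect_true("missing_objects_resource" %in%
                validate_descriptor(no_obj)$issues$code)

  bad_bind <- desc
  bad_bind$biotracks$bindings$x <- "no_such_column"
  expect_true("dangling_binding" %in% validate_descriptor(bad_bind)$issues$code)

  odd <- desc
  odd$profile <- "mystery-profile"
  rep <- validate_descriptor(odd)
  expect_true("unknown_profile" %in% rep$issues$code)
  expect_true(rep$ok)  # unknown profile is only a warning
})
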