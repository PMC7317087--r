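Package: biotracksr
Title: Cell Tracking Data Packages: Read, Write, Validate, Convert and Simulate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the biotracks open interchange format for cell-migration
    tracking data, a Tabular Data Package holding three CSV tables (objects,
    links, tracks) plus a JSON descriptor. Provides an in-memory data model
    with integrity validation, round-trip safe serialization, converters from
    common tracking-tool outputs (TrackMate-style XML, CellProfiler-style and
    generic tracking CSV), a lineage engine that infers tracks as weakly
    connected components and detects split/merge events, per-track motility
    statistics (path length, net displacement, speed, confinement ratio), a
    MIACME 1.1 experiment-metadata validator driven by a declarative
    requirement table, and a seedable simulator of time-lapse single-cell
    tracking data with a ground-truth lineage ledger for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
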