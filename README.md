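# biotracksr

Cell-migration experiments produce time-lapse movies from which tracking
software (TrackMate, CellProfiler, Icy, ...) extracts trajectories — but every
tool writes its own output format, which blocks data exchange, reuse and
meta-analysis. `biotracksr` implements the **biotracks** open interchange
format for tracking data and the surrounding tooling in R, for cell-migration
researchers, image analysts and tool developers who need to move tracking
results between software, archive them in a self-describing container, or
validate them against minimum-information reporting guidelines.

## The data model

A dataset is a **Tabular Data Package**: three CSV tables plus one JSON
descriptor (`datapackage.json`) carrying general metadata and per-table
schemas. The tables form three levels of information:

* **objects** — one detection per row: an integer id, a 0-based frame index,
  coordinates *(x, y[, z])*, and arbitrary numeric feature columns (area,
  intensity, ...). An object can be any region of interest reduced to a
  representative point plus features.
* **links** — ordered linear chains of objects across strictly increasing
  frames (gaps allowed, as produced by gap-closing trackers), stored in long
  form as `(link_id, object_id)` rows.
* **tracks** — sets of links forming one lineage, stored as
  `(track_id, link_id)` rows. Tracks are *derivable*: a track is a weakly
  connected component of the directed lineage graph whose edges are the
  consecutive object pairs within each link. A node with out-degree ≥ 2 is a
  **split** (one parent, several children); in-degree ≥ 2 is a **merge**.

Per-track motility statistics follow the standard definitions: over a
trajectory with positions $p_0, \dots, p_n$,

* path length $L = \sum_i \lVert p_{i+1}-p_i \rVert$,
* net displacement $D = \lVert p_n - p_0 \rVert$,
* mean speed $v = L / (\Delta f \cdot \tau)$ with frame span $\Delta f$ and
  frame interval $\tau$,
* confinement ratio $D/L \in [0, 1]$ (1 = straight motion, 0 = closed loop).

The package also validates **MIACME 1.1** experiment metadata (Minimum
Information About a Cell Migration Experiment: experimental set-up, imaging
condition, data) against a declarative requirement table, and embeds such
documents into the package descriptor.

## Worked example

Simulate a small lineage (4 cells, 20 frames, occasional divisions and
collisions), inspect the detected events, compute per-track statistics and
round-trip the package through disk:

```r
library(biotracksr)

cfg <- simulation_config(n_initial_cells = 4, n_frames = 20,
                         p_split = 0.05, p_merge = 0.02, seed = 42)
sim <- simulate_tracks(cfg)
sim$package
#> <bt_package> 131 objects, 21 links, 4 tracks
#>   features: area

detect_events(sim$package$objects, sim$package$links)[, 1:3]
#>    kind pivot_object_id frame
#> 1 split               6     1
#> 2 split               8     2
#> 3 merge              11     3
#> 4 split              30     7
#> ...

round(package_stats(sim$package, frame_interval = 1), 3)
#>   track_id n_objects duration_frames path_length net_displacement mean_speed confinement_ratio
#> 1        0        30              19      45.700           13.264      2.405             0.290
#> 2        1        40              19      47.047           16.226      2.476             0.345
#> 3        2        18              19      43.921           10.163      2.312             0.231
#> 4        3        43              19      45.135           15.599      2.376             0.346

d <- tempfile()
write_biotracks(sim$package, d)       # datapackage.json + objects/links/tracks.csv
identical(read_biotracks(d)$links, sim$package$links)
#> [1] TRUE
```

The 21 links in 4 tracks show the lineage encoding at work: every division
closes the parent's link and opens two daughter links that share the pivot
object, so `detect_events()` recovers exactly the simulator's ground-truth
ledger (`sim$ledger$events`). Statistics are computed along each track's
longest root-to-leaf path; a confinement ratio near 0.3 is typical for an
unbiased random walk of this length.

Converting tool output works the same way in reverse:

```r
pkg <- read_trackmate("Model.xml")                      # spots + edges -> package
pkg <- read_cellprofiler("tracks.csv")                  # label column -> links
pkg <- read_generic_csv("any.csv",
         column_mapping(frame = "t", x = "px", y = "py", label = "cell"))
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/biotracks.R`:

```sh
Rscript inst/cli/biotracks.R convert trackmate Model.xml out_pkg/
Rscript inst/cli/biotracks.R validate out_pkg/ --miacme metadata.json
Rscript inst/cli/biotracks.R stats out_pkg/ stats.csv --frame-interval 300
Rscript inst/cli/biotracks.R simulate sim_pkg/ --seed 7
```

Exit codes are stable: 0 ok, 1 validation errors, 2 usage/I-O errors.

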