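---
title: "Tracking data packages: model, design decisions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking data packages: model, design decisions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotracksr)
```

## The three-level model

Tracking software, whatever its linking algorithm, produces three kinds of
information: detections, frame-to-frame connections, and lineages. The
package represents these as three tables.

An **object** is one detection in one frame: a unique non-negative integer
id, a non-negative 0-based frame index, finite coordinates `x`, `y` and
optionally `z`, and any number of numeric feature columns. Objects are
points-with-features; masks and ROI geometry are out of scope, reduced to a
representative point.

A **link** is an ordered chain of objects whose frames strictly increase.
Frames need not be consecutive: gap-closing trackers legitimately connect a
detection at frame 3 to one at frame 6 when the cell was missed in between,
so a gap is data, not an error. A link never revisits an object and has at
least two of them.

A **track** is a set of links forming one weakly connected component of the
directed *lineage graph*, whose nodes are the linked objects and whose edges
are the consecutive pairs within each link (duplicate edges contributed by
several links are collapsed, keeping all contributing link labels). Ignoring
edge direction means a lineage stays together across both divisions and
merges, which is the intended reading of tracks connecting links "across
events". Division and merging are representable precisely because an object
may belong to several links: a split ends the parent link and starts each
daughter link at the shared pivot object (out-degree ≥ 2); a merge ends both
incoming links on the shared merged object (in-degree ≥ 2).

Two modelling questions were genuinely open and are resolved as follows.
First, whether tracks may share links: we enforce a strict partition (each
link belongs to exactly one track), which is what component decomposition
naturally yields and what keeps the tracks table unambiguous to consumers.
Second, whether a lineage should be severed at merges (a merge may be a
fusion or merely a collision under the segmenter's resolution): we keep one
component and expose the merge events instead, leaving the interpretation to
the analyst.

Track numbering is deterministic and input-order independent: components are
sorted by their minimum contained link id and numbered from 0. The same rule
is used by the simulator's ground-truth ledger and by `infer_tracks()`, so
partitions can be compared with `identical()`.

## Per-track statistics

A branching track has no single trajectory, so statistics follow the track's
*principal path*: the directed root-to-leaf path with the largest frame
span, ties broken towards the smaller terminal object id, and towards the
smaller predecessor id while backtracking. Over that path with positions
$p_0,\dots,p_n$: path length $L=\sum\lVert p_{i+1}-p_i\rVert$, net
displacement $D=\lVert p_n-p_0\rVert$, mean speed $L/(\Delta f\,\tau)$ with
frame span $\Delta f$ and frame interval $\tau$, and confinement ratio $D/L$
(defined as 0 when $L=0$). Elapsed time uses the frame span rather than the
object count so gap-closed links are timed correctly. Degenerate components
with fewer than two objects return all-zero statistics with a warning rather
than an error, since an objects-only package is legal.

The frame interval $\tau$ has units of time per frame and defaults to the
value recorded in the package descriptor (itself defaulting to 1, i.e.
speeds in units per frame). Coordinates are stored exactly as the source
tool produced them; the descriptor records the spatial unit label, and no
rescaling is ever applied silently.

## Serialization

A package directory holds `datapackage.json` plus `objects.csv`,
`links.csv` and optionally `tracks.csv` (tracks are derivable; when the file
is absent, `read_biotracks(materialize_tracks = TRUE)` infers them — never
silently). On-disk columns use a fixed `cmso_` namespace
(`cmso_object_id`, `cmso_frame_id`, `cmso_x_coord`, ...) declared through
explicit bindings in the descriptor, so feature columns can never collide
with structural ones. The CSV dialect is pinned — UTF-8, comma delimiter,
`.` decimal mark, LF endings, RFC 4180 quoting, integers without a decimal
point, reals via R's shortest round-trip representation (15 significant
digits) — and descriptor keys are sorted recursively. These choices make
writing *byte-stable*: the same package always produces byte-identical
files, which turns diff-based provenance checking into a trivial operation.
Round-tripping is exact for ids, frames and topology and accurate to better
than $10^{-12}$ relative error for coordinates (the tolerance asserted in
the tests; observed error is at the $10^{-15}$ level of double decimal
round-trip).

Converters normalize two source conventions: frame bases (0- or 1-based,
declared in the column mapping) and identifiers. Source ids are remapped to
dense non-negative integers in sorted source-id order, and the mapping is
stored in the descriptor (`source_id_map`) for traceability.

## Converters

**Edge-list sources** (TrackMate-style XML: spots plus source→target edges)
are decomposed into maximal linear chains: a link is a maximal path whose
interior nodes have in-degree = out-degree = 1, so branch and terminal nodes
are chain endpoints and splits/merges surface exactly as objects shared
between links. This rule keeps links linear while preserving the lineage
graph edge-for-edge, which is the converter's tested contract. When the
source groups its edges into tracks we recompute components and warn on
disagreement — the recomputed partition is authoritative because it is the
one consistent with the shipped model. Numeric spot attributes become
features; non-numeric ones are dropped with a warning (features are numeric
by contract).

**Label-column sources** (CellProfiler-style or generic CSV) connect
same-label rows in frame order. A frame gap within a label either closes the
link and opens a new one (`gap = "split"`, the default, because a reused
label after a long gap frequently denotes a different cell depending on the
tracker's configuration) or is kept inside a single gap-closed link
(`gap = "bridge"`). A label occurring twice in one frame cannot form a
linear chain and is refused. The generic reader requires only frame, x and y
mappings; without a label column it produces a valid objects-only package
with a warning.

The label-column dialect cannot express branching, so the CellProfiler
emitter refuses packages with shared objects with an
`unexpressible_topology` error rather than silently flattening the lineage.
Icy and MosaicSuite dialects are not implemented: their structure would have
to be reverse-engineered, and the generic reader with a mapping covers
simple per-object exports.

## MIACME validation

MIACME 1.1 organizes experiment metadata into an investigation block plus
three cell-migration-specific domains: experimental set-up, imaging
condition, and data. The published guideline assigns each field a
requirement level in accompanying material rather than in a single canonical
machine-readable table, so the validator here is driven by a *declarative
requirement table* shipped as YAML (`inst/extdata/miacme-requirements.yaml`):
field path → MUST/SHOULD/MAY. The shipped table is an explicit, editable
approximation with MUST reserved for the assay type, cell model, imaging
modality and raw-data summary; changing institutional policy means editing
data, not code. Validation is open-world (unknown fields are preserved and
never flagged, field order is irrelevant) and fully offline: term
annotations are shape-checked — non-empty label; an accession requires a
source — but never resolved against a live ontology service, so the test
suite has no network dependency. The shipped example document is synthetic,
modeled on a Ba/F3-style single-cell migration study, with illustrative
accession strings.

Embedding places the validated document verbatim (keys canonicalized) under
a `miacme` key in the package descriptor, where it round-trips
byte-identically; documents with MUST-level errors are refused, and
re-embedding replaces the previous block with a warning.

## The simulator and what it does (not) show

The simulator exists so that every component is testable against known
ground truth without downloads. Cells perform a biased random walk: per
frame, each coordinate moves by `drift + N(0, sigma²)`. Defaults are chosen
once as a realistic desk-scale experiment: 10 cells, 40 frames, σ = 2
units/frame in a 100-unit arena, division probability 0.01 per cell per
frame, merge probability 0.005 per eligible pair per frame, 5% detection
dropout, and a lognormal area feature (meanlog = log 100, sdlog = 0.25).
Split and merge probabilities also accept per-frame vectors, which lets
tests force an event at an exact frame.

Events use the shared-object encoding directly, so the ground-truth ledger
(event kind, pivot object, frame; track partition via union-find over
streams) is exact by construction, and detector recovery is an equality
check, not an approximation. Two representational constraints follow: a
pivot needs at least one frame on each side, so events are only drawn at
frames 1 to n−2; and two sibling daughters are never merged with each other
in the frame after their birth (that would collapse into a duplicate edge
and express no merge). Merges are restricted to pairs within a capture
radius of 3σ (unbounded when σ = 0, so drift-only deterministic configs can
still exercise merges), emulating collision-driven under-segmentation.
Dropout removes only interior stream detections — boundary objects are
exactly the shared event pivots — producing within-link frame gaps while
keeping the package valid. After dropout, ids are compacted to dense
0-based integers, matching what converters emit.

With no events and no dropout the step lengths are i.i.d. Rayleigh in 2D,
with mean $\sigma\sqrt{\pi/2}$; the suite checks the empirical mean over
more than 10⁴ simulated steps against this closed form within three
standard errors. Randomness comes from R's generator seeded per run, with
the caller's RNG state saved and restored, so identical configs and seeds
give byte-identical packages.

The simulator emulates detections, linear links, lineage events, feature
noise and missed detections. It does **not** emulate: localization error
correlated with features, false-positive detections, linking errors
(mis-assignments), persistent or confined motility modes, crowding, or
pixel data. Passing tests therefore demonstrate that the *representation,
serialization and graph algorithms* are correct — not that any tracking
algorithm performs well on real images, which is out of scope (the package
never creates links from raw detections except in the simulator).

## Numerical and testing choices

* Coordinates round-trip through text at 15 significant digits; tests assert
  $10^{-12}$ relative tolerance, identity for integers and strings.
* Brute-force oracles (pairwise duplicate scans, naive DFS components,
  exhaustive edge enumeration) are implemented independently in the test
  helpers and never call the package's graph machinery, which uses igraph.
* Validation never throws on malformed *content* — it returns a report with
  stable codes (`duplicate_object_id`, `frame_order`, `dangling_reference`,
  `unassigned_link`, `track_disconnected`, `missing_resource`, ...) — while
  structurally impossible requests (writing an invalid package, embedding a
  rejected document) raise a condition carrying that report.
* Problem sizes are desk scale by design: round-trip and recovery batteries
  use 4–6 cells over 12–25 frames across 20 seeds; the oracle-equivalence
  battery uses 100 random instances of up to 400 objects and 200 links; the
  Rayleigh check uses 210 cells over 51 frames (10,500 steps). The whole
  suite runs in well under a minute.

## Known limitations

* One field of view per package; bundling multiple objects tables is left
  open.
* Objects are points; mask references on object rows are deferred.
* The MIACME requirement table is an approximation of the guideline's
  supplementary material and is meant to be curated.
* The CellProfiler dialect cannot express lineage; use the TrackMate-style
  XML emitter when branching must survive a round trip.
* Statistics summarize one principal path per track; per-link statistics or
  mean-squared-displacement model fitting are intentionally not provided.
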