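# fptseg

First-Passage-Time segmentation of central-place forager GPS tracks, with
nightly trip decomposition and foraging-area characterization — built for
nectar-feeding bats commuting from a maternity roost to distant flower
patches, and usable for any animal that alternates fast directed transit
with slow area-restricted search.

## What it computes

For each relocation of a planar track, the **first passage time** t(r) is
the time the trajectory needs to cross a circle of radius r centred on that
fix (first crossing backward plus first crossing forward, found by exact
segment–circle intersection on the piecewise-linear path).  Directed flight
at speed v gives t(r) = 2r/v; looping search inside a resource patch keeps
t(r) large.  The variance of log passage times across a track,

    S(r) = Var[ log t(r) ],

peaks at the characteristic scale of area-restricted search.  The pipeline
selects each track's optimal radius r\* = argmax S(r) on a 300–500 m grid,
recomputes FPT at the cohort mean radius, and labels each fix **FF**
(foraging flight) when log t exceeds 2.7141 (natural log, minutes) and
**CF** (commuting flight) otherwise.  Fixes then aggregate into maximal
same-mode segments, roost-to-roost trips (split at ≥30-min near-roost
gaps), and foraging areas (FF segments of ≥30 min and ≥2 relocations,
sized as πr\*², placed by fix centroid, habitat-classified by majority
land cover, compared across habitats with Kruskal–Wallis and across modes
with Mann–Whitney).

Field data of this kind are expensive and rarely redistributable, so the
package also ships a first-class, seeded simulator: two-mode correlated random
walks (7 m/s commutes, 1.5 m/s patch-confined foraging, 1–3 trips per
night, 30–90 min roost dwells, 13–40 km patch distances) sampled through a
realistic GPS duty-cycle / error / dropout model, plus matching land-cover
and elevation rasters — so every stage is validated against known ground
truth.  See the methods vignette (`vignettes/fpt-segmentation.Rmd`) for
the model, parameter defaults, and known limitations.

## Worked example

Simulate a 21-night cohort and run the full chain:

```r
library(fptseg)
rep <- run_pipeline(pipeline_config(seed = 7, out_dir = "run7"))
print(rep)
```

prints (abridged):

```
fptseg 0.1.0 cohort report (seed 7)
tracks: 21 read, 21 analyzed; 90 segments, 34 trips, 36 areas
population mean optimal radius: 316 +/- 34.43 m (n = 21)

cohort statistics (mean +/- sd):
  total_distance_km         55.37 +/- 22.70
  n_trips                    1.62 +/- 0.59
  n_areas                    1.71 +/- 0.85
  area_km2                   0.32 +/- 0.08
  roost_distance_km         15.21 +/- 6.69
  search_time_h              1.92 +/- 0.99

CF vs FF (Mann-Whitney U on per-track means):
  length_km    U =  344.0  p = 0.001478  (exact)
  speed_ms     U =  408.0  p = 1.959e-07  (exact)

foraging areas by habitat:
  shrubland  n = 18 (50%)
  forest     n =  9 (25%)
  farmland   n =  9 (25%)
```

Read it as: 21 simulated bat-nights averaged 55 km of flight across 1.6
round trips, foraging in 1–2 areas of ~0.32 km² located ~15 km from the
roost; commuting and foraging flight differ strongly in per-track segment
length and speed, and the areas split across habitats roughly as the
generator drew them.  `run7/` contains the per-track CSV tables
(`night_summary.csv`, `segments.csv`, `trips.csv`, `areas.csv`), GeoJSON
geometries, ASCII-grid rasters, a plain-text report, and the full config
echo for traceability.

Individual stages are exported too — `read_fixes()`, `filter_track()`,
`project_track()`, `passage_times()`, `var_log_fpt()`, `optimal_radius()`,
`classify_modes()`, `build_segments()`, `split_trips()`,
`find_foraging_areas()`, `assign_habitat()` — and a thin CLI wraps the
pipeline:

```sh
Rscript inst/cli/fptseg.R simulate --out run1 --seed 1
Rscript inst/cli/fptseg.R analyze  --out run1
Rscript inst/cli/fptseg.R summarize --in run1
```

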