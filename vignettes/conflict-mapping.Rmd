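---
title: "Methods: mapping conflicts between wind energy development and wildlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping conflicts between wind energy development and wildlife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windconflict)
```

`windconflict` implements a municipal-scale screening procedure for onshore
wind development: where is wind energy attractive, where are birds and bats
sensitive to it, and where do the two collide. This vignette documents the
models, the tunable parameters, the numerical choices, and what the synthetic
test landscapes do and do not demonstrate.

## Wind resources

Station anemometers measure at 10 m; resource assessment happens at hub-scale
heights. Under the neutral logarithmic profile,

$$u(z) = u(z_{10}) \, \frac{\ln(z/z_0)}{\ln(z_{10}/z_0)},$$

where $z_0$ is the roughness length in metres. `extrapolate_speed()` applies
this directly; the ratio is independent of the measured speed, so calm hours
stay calm. $z_0$ is a per-station user input (typical values: 0.01 m open
water to about 1 m for forest or towns; default 0.03 m, open farmland). No
terrain or orography modelling is attempted: that is the domain of dedicated
flow models, and out of scope here.

The speed distribution is summarised by a two-parameter Weibull law fitted by
maximum likelihood (`fit_weibull()`). Calms (zero speeds) are removed before
fitting — the log-likelihood is undefined at zero — and counted on the
returned object; this is the standard wind-analysis convention. The shape $k$
solves the profile score equation by damped Newton iteration from $k = 2$
with relative tolerance $10^{-8}$ and at most 200 iterations; Newton steps
are halved whenever they would leave the positive half-line, which in
practice makes the iteration globally convergent for non-degenerate samples.
A minimum of 30 positive speeds is required, and constant samples are
rejected as degenerate rather than returned as a boundary fit.

Mean power density per swept area is the third Weibull moment,

$$P = \tfrac12 \rho\, c^3\, \Gamma(1 + 3/k) \quad [\mathrm{W\,m^{-2}}],$$

with air density $\rho = 1.225$ kg m$^{-3}$ (sea-level standard) by default
and configurable, since no density is prescribed by the assessment itself.
For a fixed mean speed, power density decreases with $k$: gustier regimes
(lower $k$) carry more cubic-mean energy. The test suite verifies parameter
recovery (median shape error below 0.05 at $n = 5000$ over 20 seeded
replicates) and cross-checks the fit against an independent ML fitter.

## Municipal development priority

Five criteria describe how attractive a municipality is for wind development:
wind power density at 50 m (A, W m$^{-2}$), free 110 kV grid capacity (B,
MW), special-plan status (C, 0/1), planned wind-farm capacity (D, MW) and
forest share (E, %). Each of A, B, D, E is scored 1–3 by which third of its
national range contains the raw value; the ranges (A 60–342, B 0–295,
D 0–213, E 11–69) are configuration with the published national values as
defaults, not re-derived from data. The index is

$$I = 0.35A + 0.25B + 0.20C + 0.10D - 0.10E,$$

classified I (> 1.1), II (0.6–1.1, boundaries inclusive) or III (< 0.6).

Three scoring conventions are deliberate and matter at the margins:

* **Right-closed bins.** Thirds are $(lo, lo+\Delta]$, $(lo+\Delta,
  lo+2\Delta]$, $(lo+2\Delta, \infty)$; a value of 100 MW against the 0–295
  range scores 2 (boundary 98.33). Out-of-range values clamp: below the range
  scores 1, above it 3.
* **Raw zero scores zero — for B and D only.** A municipality with no free
  grid capacity or no planned farms gets no contribution from that criterion
  at all, and a missing planned capacity is treated as zero. Wind density and
  forest share always score at least 1.
* **Two-decimal arithmetic.** The index is rounded to two decimals before
  classification, matching how such indexes are tabulated.

With these conventions the packaged national reference table of 51
municipalities reproduces the published index column for 49 rows; the two
exceptions (Kalvarija and Marijampole) are not derivable from their own
printed criterion values under any consistent reading of the scheme, so the
package reports both the computed and the reference value rather than
special-casing them. One municipality's printed priority class ("0") is an
evident typo; its index places it in class III and the package classifies it
so. Installed-power shares per class are computed against the table's total
installed capacity.

## Wildlife sensitivity

The packaged species catalog freezes the published parameter base: 69
breeding bird species, 43 migratory bird species and all 17 national bat
species, each with a conservation score $B \in \{1,2,3\}$ (national red-list
based), effect scores for collision, disturbance, barrier effect and habitat
change whose sum is the summed sensitivity $C$, a disturbance-free buffer
radius (100–2000 m, from feeding distance and home range), and abundance
thresholds. Species occurring in both bird tables are two distinct records —
their seasonal scores differ — and a synonym map aligns alternative
binomials across tables. Order names are stored as printed in the source
tables, including their idiosyncrasies, since they are labels, not analysis
inputs. Everything is validated at load: summed scores, score domains,
threshold ordering, group sizes.

An observation of a species at a place scores

$$A = D \times (B + C),$$

where $D$ is local abundance: for breeders 3/2/1 by whether the local pairs
reach the species' 0.5 %-of-national-population count, its 0.1 % count, or
neither; for migrants 3/2/1 against the species' significant and minimal
stopover abundances (all thresholds inclusive at the boundary). For bats $D$
is the number of bat species recorded in the 1-km cell — richness, not
abundance — combined with the largest $(B + C)$ among the species present;
it is unbounded, as specified.

Scores become classes on group-specific scales: breeders high > 12, medium
7–12; migrants high > 20, medium 9–20 (low below those bands). No separate bat scale is published;
the package applies the migrant scale to bats by default (bat scores share
the migrant scale's arithmetic range) and makes the choice configurable.

**Rasterization.** Observations are buffered by their species/season radius
(bats: 1000 m breeding, 2000 m wintering; dump sites: fixed 2000 m;
protected-site footprints: configurable extra buffer, default 0) and burned
onto a 1-km grid. Buffers are implicit: a cell is touched exactly when the
Euclidean distance from the cell square to the base geometry is at most the
radius, which is exact Minkowski-dilation semantics with no polygon-offset
approximation. Cells combine features by **maximum severity** — published
schemes of this kind leave the combination rule open, and the conservative
maximum is the standard choice in sensitivity mapping; each feature is
classified on its own group's scale before combination. Protected
(Natura 2000) and dump-site footprints force cells to high regardless of any
score. Cells touched by nothing are `not_estimated` unless a
survey-coverage mask says the area was searched, in which case they are low:
absence of evidence only counts where observers actually looked, and low
sensitivity must never be inferred from missing surveys. The per-cell
numeric score of the severest feature is retained for audit.

**Seasonal comparison.** For species present in both bird tables the paired
summed-sensitivity scores are compared with a Wilcoxon signed-rank test.
Scores are small integers, so ties dominate; the package therefore computes
the exact null distribution of the rank-sum statistic under sign flips by
dynamic programming on the (doubled, hence integral) midranks for up to 25
non-zero pairs, and a tie-corrected normal approximation beyond. Zero
differences are dropped (the classic convention); if every pair is tied the
test degenerates and returns $p = 1$ with a warning rather than an error.

## Conflict assessment

Priority and sensitivity combine through a fixed 3×3 matrix: priorities I
and II map sensitivity straight through (high→high, medium→medium,
low→low); priority III downgrades one level (high→medium, medium→low,
low→low). `not_estimated` propagates — the conflict layer never claims low
conflict where wildlife was not assessed. The matrix is monotone in both
arguments, which the tests check over all nine cells.

Zonal statistics report, per municipality, the share of its area in each
conflict class and the estimated share (their sum). Cells straddling
municipal borders are apportioned by the exact polygon–cell intersection
area (Sutherland–Hodgman clipping plus the shoelace formula), so no area is
counted twice. Cross-municipality summary means are unweighted by area —
the arithmetic that reproduces the published national summary from the
packaged per-municipality table.

## Geometry, formats, grids

The geometry layer is planar and lives in the package: point-in-polygon,
segment distances, rectangle–polygon distance and intersection, convex
clipping, and half-plane Voronoi tessellation. All coordinates are assumed
projected in metres; GeoJSON readers reject inputs whose coordinates all
look like longitude/latitude degrees, since metre buffers would be
meaningless there. Grid cells are half-open $[x, x+1000) \times
[y, y+1000)$, and a feature touches a cell whenever their intersection is
non-empty — boundary contact counts. Class rasters are written as ESRI
ASCII grids (a plain-text raster format readable by standard GIS software)
with integer codes 3/2/1/0 for high/medium/low/not-estimated, alongside a
per-cell CSV audit table; vector data move as GeoJSON and tables as
UTF-8 CSV with dot decimals.

## The synthetic landscape generator

`generate_scenario()` builds a fully synthetic study region from one seeded
random stream: municipalities as a Voronoi tessellation of a square extent,
species observations drawn from the packaged catalog with counts placed in
all three abundance bands, rectangular protected and dump sites, a
survey-coverage band leaving part of the extent unsurveyed, per-region
Weibull wind regimes with shape 1.6–2.4 and scale 5–9 m s$^{-1}$ (the
realistic envelope for low-terrain northern-European sites), and criterion
values drawn within the published national ranges. Geometry is generated
before attributes, so municipality shapes are stable under attribute
changes; identical seeds give byte-identical output files.

The generator emulates the *shapes* of real inputs, not their spatial
structure: no migration corridors, no habitat autocorrelation, no clustering
of observations along coasts or wetlands, and rectangular rather than
naturally shaped protected areas. Passing tests on synthetic scenarios
therefore demonstrate that the machinery is correct — scoring, buffering,
rasterization, combination, zonal accounting — not that any particular real
landscape would yield similar class shares. The published national map
products themselves depend on an observation database that is not
redistributable, and are accordingly not reproduced; the quantities the
package does reproduce are those derivable from its packaged tables
(the index regression, class counts, installed-power and zonal summaries,
and the seasonal score comparison).

Test problem sizes are deliberately modest — grids of 10–50 km a side,
tens of observations, wind samples of $10^3$–$10^5$ — chosen so the full
suite exercises every stage in seconds while keeping estimator checks
(e.g. MLE recovery at $n = 5000$, 20 replicates) statistically meaningful.

## Known limitations

* Priority thresholds (1.1/0.6) and the conflict matrix are fixed
  conventions of the published scheme; the package validates but does not
  calibrate them.
* The per-cell maximum-severity rule cannot represent cumulative load from
  many co-occurring low-scoring species.
* Polygon dilation areas reported by `buffer_observation()` use the convex
  Minkowski formula $A + Pr + \pi r^2$, an upper bound for non-convex
  rings; rasterization itself is distance-based and exact either way.
* The conflict grid assigns each cell the priority of the municipality
  containing its centre; zonal shares, by contrast, apportion border cells
  exactly.
* Installed-power-by-conflict splits would require turbine coordinates,
  which are not part of the packaged data; they are out of scope.
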