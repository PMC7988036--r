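---
title: "Methods: place-cell connectivity analyses in a four-room maze"
author: "fourrooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place-cell connectivity analyses in a four-room maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourrooms)
```

## The scientific problem

Hippocampal CA1 place cells fire at specific locations, forming the
presumed substrate of a cognitive map. In a connected environment an
animal must track not only *where* it is but *which transitions are
currently possible*. This package implements a complete analysis
pipeline for asking whether place cells encode such environmental
connectivity: four geometrically identical 60 x 60 cm boxes arranged in
a 2 x 2 square, joined by 16 x 16 cm pushable door units that can be
locked in one or both directions without any visible change. A recording
day is a five-session sequence — `O1, O2` (all doors open), `C1, C2`
(one door locked both ways in *Closed-Door* sequences, or every door
locked in one direction in *One-Way* sequences) and `O3` (reopened) —
with twelve bell-cued trials per session alternating goal-directed runs
with in-box foraging.

Because the original tetrode recordings are not required, the package
ships a synthetic-data generator with fully known ground truth; every
analysis stage is validated by parameter recovery against it.

## Maze model

The maze lives in a fixed coordinate frame: origin at the outer
lower-left corner, axes in cm, `y` up; boxes are labeled `A`
(upper-left), `B` (upper-right), `C` (lower-right), `D` (lower-left),
giving a 136 x 136 cm footprint with a 16 cm door gap between adjacent
boxes. The arrangement of labels and which door is locked are
configuration, since only the physical dimensions are dictated by the
apparatus. Connectivity is a directed graph on the four boxes: edge
`(u, v)` exists iff the shared door can be pushed open from `u` toward
`v`. Shortest door paths (and the set of first doors on any optimal
path, used to score the rat's first push after a bell) come from this
graph; with all doors open, adjacent boxes are 1 door crossing apart,
and locking their shared door in both directions raises that to 3.

Each box splits into 2 x 2 quadrants around its centroid (16 in all)
with half-open boundaries, left/bottom inclusive, so a point exactly on
the centroid falls in the upper-right quadrant; the numbering
(`(box-1)*4 + subquadrant`, boxes in A–D order, subquadrants lower-left,
lower-right, upper-left, upper-right) is fixed so confusion matrices are
reproducible bit-exactly. Door-gap samples belong to the box the animal
last occupied for visit segmentation, and to the nearest box centroid
for decoding ground truth — the recordings' own labeling of corridor
samples is not documented anywhere, so a deterministic convention is
declared instead.

## Synthetic data generator

`sim_config()` collects every tunable with its default:

* tracking 50 Hz, sessions 23 min, 12 trials following a pseudo-random
  goal list (each box three times, all four before any repeat);
* foraging speeds 6–16 cm/s (slow, circuitous, uniform waypoints inside
  the goal box), goal-directed speeds 30–60 cm/s (direct door-to-door
  legs with a smooth lateral bow);
* place fields as planar Gaussians confined to their box, width
  `field_sigma = 8` cm, peak rates uniform on 3–10 Hz, 1–4 fields per
  cell; a configurable fraction of cells repeat one field template in
  `repeat_k` boxes (their other boxes receive independent fields, so
  repetition rides on an otherwise box-unique map);
* slow across-session drift as a per-session random walk of field
  centers (sd 1 cm) plus multiplicative log-normal rate noise (sd 0.1)
  — the recordings show correlations decaying with session separation
  but give no model, so magnitude is a declared knob;
* an optional fraction of cells that redraw their map at the `O2 -> C1`
  connectivity change (default 0, the recordings' own finding);
* spikes by inhomogeneous-Poisson thinning against the cell's planted
  rate surface, with position linearly interpolated between tracking
  samples.

The behaving agent plans on its *believed* connectivity graph: naive
agents push locked doors, and each failed push teaches avoidance of that
door side with probability `push_avoidance_learning = 0.6`; beliefs
persist across sessions (so avoidance learned in `C1`/`C2` carries into
`O3`) and are cleared by a successful crossing. Exploratory pushes
during foraging (0.8/min) preferentially avoid believed-locked sides.
This reproduces the qualitative behavioral signatures the pipeline
measures — post-bell acceleration, falling push rates on locked doors,
above-chance first-door choices — without claiming to model rat
locomotion statistics, which the source recordings do not quantify
beyond speed filters and session durations.

What the generator deliberately does **not** emulate: theta rhythm and
phase coding, replay/reactivation events, LFP of any kind, directional
or speed modulation of firing, overdispersion beyond Poisson, cluster
contamination, or multi-animal variability. Passing recovery tests
therefore demonstrates that the *analysis code* is correct under the
stated generative assumptions, not that real data would behave this way.

## Rate maps and spatial information

Maps use 2 cm square bins on a grid anchored to the maze geometry (not
to the data extent), so sessions are comparable bin-by-bin without
registration. Samples slower than 5 cm/s are removed; maps are built
from all data, foraging only, or goal-directed only. Spike and dwell
histograms are smoothed *separately* with a Gaussian kernel (sd 2.5
bins, 9 x 9 support) and then divided; bins occupied for less than
0.05 s are flagged empty. The kernel is renormalized over valid bins at
mask edges — whether the original analysis did so is not stated, so the
choice is documented and covered by a test showing a constant field
stays exactly constant beside a mask. Box-specific maps are cut to each
box's enclosing rectangle before smoothing (never smoothing across door
gaps), and 25 cm doorway sub-maps are extracted from them.

Spatial information is the Skaggs rate
`SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` in bits/s,
with occupancy from the smoothed dwell map to match the smoothed rates.
Significance uses 100 circular spike-train time shifts drawn uniformly
from 20 s to the session duration minus 20 s, preserving inter-spike
structure; a cell is significant above the shuffle's 95th percentile.
Putative place cells must exceed 0.1 Hz in at least two sessions and, in
their highest-rate session, fire between 0.1 and 5 Hz, carry more than
0.5 bits/s, beat the shuffle, and have a peak-to-trough waveform width
over 300 microseconds.

## Place fields, bridge index, overrepresentation

Fields are connected regions of the foraging map above 20% of its
maximum with at least 9 bins and an in-region peak above 1 Hz.
Contiguity is 8-connectivity by default (the source text does not state
it; 4-connectivity is available and both are tested). Each field carries
its area, rate-weighted centroid, convex hull and mean rate.

The **bridge index** of a field near a door is `1 - |a - b| / (a + b)`
over the bin counts `a`, `b` on either side of the infinite line through
the door center along the door axis: 0 for a one-sided field, 1 for an
even split; bins exactly on the line would count half to each side
(with the default grid no bin center can hit the line). The hull is also
projected on the axis perpendicular to the door for visualization.

Overrepresentation compares field counts within 25 cm of doors, dummy
doors and box centers against expectations proportional to the surveyed
surface: the median dwell map across sessions, thresholded at 0.01 s,
with each surviving bin assigned to its *nearest* test point within
25 cm. The nearest-point partition is a declared choice — the 25 cm
disks of neighboring test areas overlap, and an unpartitioned count
would not sum to the field total, breaking the chi-square construction.
Locked-versus-open door counts are tested against a 50/50 split
(One-Way sequences use locked versus open door *sides*), with the
package's Holm–Bonferroni variant (non-significant values censored to
0.99, the rest unadjusted) across sessions.

Field tracking pools weighted centroids over sessions, clusters them
with k-means (50 restarts) choosing k by gap statistic (100 uniform
reference draws, `firstSEmax`), reports within-cluster consecutive-
session shifts (shifts above 60 cm — one box side — are excluded as
identity errors), and summarizes each door's distance to its nearest 16
fields (8 per side for One-Way) grouped into changed versus unchanged
doors.

## Remapping analyses

Map pairs correlate (Pearson) over bins visited in both, and return no
value unless at least one map peaks above 1 Hz and at least 10 common
bins exist. Session-level, doorway-level (closed/control versus open
door sides, one value per cell per group) and box-level (six box pairs
per cell, adjacent versus diagonal) analyses all reuse this primitive.
The Fuhs rate-remapping metric, `sum|f1 - f2| / sum(|f1| + |f2|)` after
per-map mean subtraction, is 0 for identical fields, approaches 1 for
unrelated ones, and is symmetric, bounded and offset-invariant — all
property-tested.

Individual remapping compares each cell's consecutive-session
correlation to a shuffle of random *different-cell* pairings within the
same sequence (1000 draws, pooled over sequences with more than 10
simultaneous place cells). The source text says a cell remapped when its
correlation was "lower than the 95th percentile" of this shuffle; read
literally that makes remapping the default outcome for any cell whose
correlation is merely unremarkable, so the package defaults to the
conservative reading — below the shuffle's **5th** percentile — and
exposes the literal reading via `bound = "above_95"`. Both are tested.
A companion calibration in the test suite shows the bounds fire at their
nominal 5% rate exactly when the shuffle's own null holds (cells whose
session maps come from different cells); for genuinely stable cells the
cross-cell shuffle is conservative and flags essentially nothing, under
either reading. The four per-transition booleans encode into a 0–15
pattern (O1–O2 is the most significant bit).

Repetition shuffles rebuild the cross-box correlation distribution
expected under k-box repetition by duplicating a random compartment of
each cell's session-O1 maps into k−1 other compartments, using that
compartment's maps from *other sessions* as duplicates. The pipeline's
self-consistency test generates a 200-cell population with planted
2-box repetition and compares its cross-box distribution against the
k = 2 shuffle built from a matched non-repeating population with one
field per box — matched because the shuffle's construction presumes
box-unique source maps, which a fully repeating population cannot
supply.

## Bayesian decoding

The decoder is memoryless: spike counts of N cells in non-overlapping
τ = 300 ms windows (anchored at the session start) are scored against
each map bin x by the independent-Poisson likelihood
`P(sigma|x) = prod_i Poiss(sigma_i | lambda_xi * tau)`, a uniform prior,
and explicit normalization of the posterior over bins. Rates come from
the *training* session's maps; training and test sessions must differ
(O1 maps decode O2, O2 maps decode C1). Windows with mean speed below
5 cm/s are dropped; at least 15 simultaneous place cells are required,
otherwise the session is skipped with a log entry. A rate floor of
0.01 Hz inside the likelihood prevents `log 0` at silent bins; arg-max
ties break to the lowest bin index (a seeded random tie-break is
available). Decoded bins map to the 16 quadrants, giving a 16 x 16
confusion matrix whose rows are normalized to probabilities; summaries
report the mean probability on the diagonal, same-quadrant-wrong-box,
same-box-wrong-quadrant and the rest, against the 1/16 chance level.
The log-domain implementation is tested to 1e-10 against the direct
product formula.

## Quality-control statistics

The chi-square of expected proportions (`sum (O-E)^2 / E`, df = N−1,
upper tail), the censoring Holm–Bonferroni, isolation distance (squared
Mahalanobis distance of the n_C-th closest non-cluster spike under the
cluster's own mean and covariance; undefined when fewer than n_C
non-cluster spikes exist) and L-ratio (`sum 1 - CDF_chisq(df)(D^2)`
over non-cluster spikes, divided by n_C, df = 8 for two features on four
channels) are implemented directly from their definitions and verified
against brute-force oracles to 1e-10. Waveform width is the absolute
peak-to-trough time on the highest-amplitude channel; the generator's
two-parameter biphasic template exercises it.

## Problem sizes and numerical choices

The test suite runs its heavier simulations at the following sizes,
chosen to estimate each quantity comfortably within its tolerance:
an 18-cell, 8-minute shared dataset for unit-level checks; 20–30 cells
with full 23-minute sessions for decoder chance and accuracy (≥ 2000
windows surviving the speed filter); 500 cells for the remapping-flag
calibration; 200-cell populations for the repetition self-consistency
test; 40 single-field cells for centroid recovery. Seeds are fixed
throughout; regeneration is bit-identical.

## Known limitations

* The simulator's behavioral statistics (speeds, visit durations, push
  rates) are plausible but not fitted to animal data.
* Tracking gaps and their spline reconstruction are out of scope: the
  generator emits complete trajectories.
* Omnibus ANOVA machinery (repeated-measures designs, estimated
  marginal means, Tukey–Kramer) is deliberately delegated to standard
  tools and not re-implemented here.
* The maze model is specialized to the 2 x 2 arrangement; the geometry
  code is parameterized but untested beyond it.
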