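---
title: "Quantifying vascular remodeling with flow-weighted network centralities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular remodeling with flow-weighted network centralities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Endothelial cells seeded in a hydrogel chamber spontaneously form a lumen
meshwork which, under sustained perfusion, reorganises over weeks: the
network sprouts along the flow direction, prunes redundant low-flow
segments, stabilises, and — in closed culture systems — is eventually eroded
by cell overgrowth from the perfusion channels. The question this package
addresses is how to *quantify* that remodeling from time-lapse imagery
alone: given one binary lumen mask per time point, decide where flow goes,
how strongly it shears the walls, and whether the evolving network topology
is moving toward a hydrodynamically better layout.

`vesselflow` implements the full chain: mask hygiene and area measurement,
image-based creeping-flow simulation with wall-shear-stress (WSS)
extraction, skeleton-based graph extraction, hydrodynamic edge weighting,
and weighted-centrality summaries, together with a synthetic five-stage
time-lapse generator so that every stage of the chain can be validated
offline against closed forms and known ground truth.

## Flow model

Culture-scale perfusion is deep inside the creeping-flow regime: with a
mean inlet velocity of order 1e-4 m/s, lumen widths of order 1e-4 m and
medium viscosity near 1e-3 Pa s, the Reynolds number is about 1e-2. We
therefore solve the steady incompressible Stokes equations; at this
Reynolds number the solution is indistinguishable from a full
Navier–Stokes solution, and linearity buys exact velocity scaling (used by
the scale-invariance tests).

The solver works directly on the pixel lattice as a marker-and-cell (MAC)
staggered grid: velocity components live on cell faces, pressure at cell
centres. Two rectangular port channels are attached flush to the image
borders along the flow axis, spanning the lumen's border footprint; the
inlet carries a parabolic profile with prescribed mean velocity, walls are
no-slip (enforced through ghost values, second-order at straight walls),
and the outlet is open: zero normal velocity gradient with the pressure
level pinned to zero inside the outlet port. Dropping the continuity
equation only in the outlet-port cells makes global inlet/outlet mass
conservation exact by telescoping, which the conservation tests exploit.

Incompressibility is enforced by a divergence penalty on the compatible
staggered operators (penalty 1e8 on the dimensionless system). This keeps
the linear system symmetric positive definite, so one sparse Cholesky
factorisation solves a 256 x 384 px frame in well under a second; the
divergence residual it leaves is of order 1e-7 relative to the inlet flux,
far below every tolerance used downstream. The solve is performed
dimensionlessly (unit pixel, viscosity and mean inlet velocity) and
rescaled, so conditioning does not depend on the physical parameters.

Wall shear stress is evaluated at wall pixels (lumen pixels with a wall
4-neighbour; the image frame counts as wall except along the flow axis).
The inward normal comes from the distance-map gradient, and the tangential
speed is sampled at the pixel centre and one pixel further inward. Because
the no-slip surface sits half a pixel outside the wall-pixel centre, a
two-point fit of `u_t = a y + b y^2` through zero at the wall recovers the
wall gradient `a` exactly for a parabolic profile; `tau = mu |a|`. On a
64-cell-wide channel this reproduces the plane-Poiseuille wall stress
`6 mu U / w` to about 1%, and the acceptance suite requires 5%.

## From mask to weighted graph

Skeletonization is parallel homotopic thinning (Zhang–Suen) followed by a
sequential cleanup pass that deletes simple pixels (Yokoi connectivity
number 1) with two or more neighbours — parallel thinning leaves redundant
staircase pixels on diagonal runs which would otherwise masquerade as
junctions — and finally pruning of terminal spurs shorter than 5 px that
end at a junction. Skeleton pixels with 8-neighbour degree other than 2,
clustered by mutual adjacency, become nodes; the remaining chains become
edges; isolated cycles receive one artificial anchor node. The distance
map of the *unpruned* mask supplies the local half-width along each chain.

Each edge then reclaims its share of the lumen: chain pixels seed a
multi-source breadth-first label propagation over the lumen (ties resolve
to the lower edge id), realising the inverse-distance-transform idea of
painting a disc of the local half-width around every chain pixel while
assigning junction-area pixels to their nearest edge. Edge regions cover
the perfused lumen completely and are disjoint by construction.

Two dimensionless weights are attached per edge:

* **Wall-shear ratio** `R_tau(e) = [sum over the edge's wall pixels of
  tau_i * h] / (tau_ref * d_ch)`, with `h` the pixel size and
  `tau_ref = 8 mu U_inlet / (A_lumen / d_ch)` the Poiseuille-like stress
  of an equivalent channel whose width is the total lumen area `A_lumen`
  divided by the chamber length `d_ch`. The grouping of this normalisation
  is genuinely ambiguous as a flat formula; we adopt the
  equivalent-channel reading (`rtau_grouping = "per_area"`) because it is
  the one consistent with a reference stress *computed from the total
  lumen area*, and keep the literal flat division available
  (`rtau_grouping = "flat"`). Any fixed positive normalisation rescales
  all edges uniformly, so shortest paths, centralities and trend
  directions do not depend on this choice.
* **Flow-rate ratio** `R_Q(e) = |Q(e)| / (U_inlet * w_inlet)`, with `Q(e)`
  the median of cross-sectional fluxes at the 25/50/75% chain positions
  (median, because junction-adjacent sections are distorted; a single
  midpoint section serves chains shorter than 3 px). The magnitude is used
  because perfusion direction alternates daily in the cultures this
  analysis targets, while centralities need magnitudes.

Edges in components with no inlet–outlet path get both weights zero and a
flag; zero weights are lifted to 1e-8 when used as shortest-path distances.

## Centralities

Remodeling is summarised per frame by two node centralities of the weighted
multigraph (parallel edges and self-loops retained):

* **Betweenness**, with `R_tau` as the edge cost: a node's share of
  minimum-cost paths over all node pairs, endpoints excluded, computed per
  connected component (igraph's weighted algorithm — the default
  `path_count` variant). A verbal alternative that ratios summed
  shortest-path weights (pairs routed through the node over all pairs) is
  retained as variant `paper_text`; the two differ and both are exposed
  rather than silently merged. Mean betweenness falling over time means
  wall-shear cost concentrates less on bottleneck nodes.
* **Strength** (weighted degree) with `R_Q` weights, self-loops counted
  twice. Mean strength rising means a larger share of nodes sits on
  well-perfused segments — transport efficiency improving.

Means are taken over *all* nodes, endpoints included. Cross-sample series
are aligned on a common day grid (nearest day within 0.5 day) and
summarised with Student-t 95% bands, reported absent below two samples.

## The synthetic generator

No public accession exists for the microscopy this pipeline targets, so the
`generate_timelapse()` module *is* the test bed, emulating a 2 mm (flow
direction) x 3 mm chamber. Full scale is 1280 x 1920 px at 1.5625 um/px;
the routine test raster is 4x coarser (256 x 384 px at 7.8125 um/px),
chosen so a five-stage, 20-frame study over five seeds — the problem size
used by the acceptance suite — completes in minutes while still resolving
40 um segments at 5 px.

The five stages and their generator semantics:

1. **Meshwork** — random segments with orientations *stratified* over
   [0, pi), so the drawn population is isotropic by construction and the
   measured anisotropy baseline is small with low seed-to-seed variance.
   Area rises as segments accrue.
2. **Sprouting** — two strong, nearly straight channels first span the
   chamber between the port borders (the perfusion path), together with
   three narrow tortuous spanning channels whose steep lateral jogs are
   exactly the "not oriented along the flow" lumens that remodeling later
   removes; flow-aligned sprouts (orientation sd `(1 - sprout_anisotropy)
   * pi / 2`) then grow from the existing lumen. Area and orientation
   anisotropy both rise.
3. **Remodeling** — closed-loop: each frame the full pipeline runs on the
   current mask, and `apply_pruning_event()` erases the
   `prune_fraction_per_frame` lowest-`R_Q` flow-bearing edges among those
   oriented within 45 degrees of perpendicular to the flow axis (ties to
   the lower edge id), skipping port-touching edges, any edge with
   `R_Q >= 0.2` (pruning targets low-flow segments, never the high-flow
   vessels they bridge), and any candidate whose removal would disconnect
   the ports. Unperfused structure regresses alongside: dead-end segments
   with essentially zero flow lose their regions, and connected components
   with no inlet–outlet path are resorbed smallest-first at about 40% of
   their area per frame, spreading the area decline over the stage. Area
   falls; flow consolidates into the surviving channels.
4. **Stable** — 5% of wall pixels get a ±1 px dilation/erosion jitter;
   area moves by far less than 1% per frame.
5. **Erosion** — morphological dilation seeded from the two port borders
   in an inward-growing band, area rising again.

All randomness comes from one stream seeded once per dataset, so a
configuration reproduces its mask sequence bit-exactly; the caller's RNG
state is restored afterwards.

What the generator does *not* emulate: brightfield appearance (only an
Otsu baseline exists for noisy renders), cell-scale mechanics, 3D geometry
(the chamber is shallow and the analysis two-dimensional), pulsatile flow,
and sub-pixel wall motion. Passing tests therefore demonstrate that the
*analysis chain* recovers planted hydrodynamic-topological structure, not
that real cultures behave like the generator.

## Stage classification

`classify_stages()` operationalises the stage taxonomy from two observable
series: the smoothed area derivative (centred moving average, window 3
frames; centred slope) and the orientation anisotropy (one minus the
circular variance of doubled, length-weighted skeleton-edge angles).
Rising area is meshwork until anisotropy first exceeds 0.3 (then
sprouting); a slope below -1% of the maximum area per frame starts
remodeling; |slope| under that tolerance after remodeling is stable; a
rise after stable is erosion. Stages advance only in canonical order and
must persist at least 2 frames. Day-range fallbacks are deliberately not
built in: the rule set is observable-driven, and the smoothing window
inevitably smears each boundary by about one frame, which is why the
stage-recovery acceptance check asks for 80% frame agreement rather than
exactness.

## Numerical choices and degenerate inputs

* Divergence penalty 1e8: large enough that the continuity residual is
  negligible against every 1–2% tolerance, small enough that the Cholesky
  factorisation keeps ~8 significant digits.
* Connectivity conventions: 8-connectivity for foreground, 4 for
  background throughout (standard digital-topology pairing); the
  8-connected labelling is a 4-connected pass with diagonal label merging.
* Masks touching neither border along the flow axis raise a perfusion
  error at domain construction, except inside the pipeline, which flags
  the frame no-flow and carries zero weights (early vasculogenic frames
  are legitimately unperfused).
* A solid disc thins to nearly nothing: the skeleton is flagged
  degenerate instead of producing a spurious graph. Isolated pixels with
  undefined wall normals get `tau = 0` and a flag. Zero-length chains and
  empty graphs are allowed and flagged.
* `U_inlet` and `mu` default to 1e-4 m/s and 1e-3 Pa s (typical capillary
  velocity, culture-medium viscosity). Absolute `tau` and `Q` scale with
  the configuration; only the dimensionless `R_tau`/`R_Q` are
  configuration-independent, which is what every cross-frame comparison
  uses.

## Limitations

The flow model is 2D with unit depth: absolute stresses in a 100-um-deep
chamber would need a Hele-Shaw correction, which cancels from the
dimensionless ratios. The staircase wall representation limits WSS
accuracy on oblique walls to a few percent. The pruning rule is an
operationalisation of qualitative phenomenology (low flow, near
perpendicular, bridging) — its thresholds (45 degrees, `rq_max = 0.2`) are
exposed as parameters rather than claimed as measured biology. The
betweenness variants differ and no attempt is made to decide which is
"right"; the default is the one computable by standard shortest-path
counting.
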