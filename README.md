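# vesselflow

Flow-weighted network analysis of in vitro vascular remodeling.

Endothelial cells cultured under perfusion in a hydrogel chamber form a
lumen network that remodels over weeks: it sprouts along the flow
direction, prunes redundant low-flow segments, stabilises, and is finally
eroded by cell overgrowth. `vesselflow` quantifies that process from binary
lumen masks (one per time point): it solves creeping flow directly on the
pixel lattice, extracts wall shear stress (WSS), converts the lumen into a
node–edge vessel graph, weights every edge with two dimensionless
hydrodynamic ratios, and tracks network optimization through weighted
centralities.

For each edge *e* of the vessel graph:

- **WSS ratio**
  `R_tau(e) = [ Σ_{i ∈ W(e)} τ_i · h ] / (τ_ref · d_ch)` with
  `τ_ref = 8 μ U_inlet / (A_lumen / d_ch)` — the edge's wall-integrated
  shear normalised by the Poiseuille-like stress of an equivalent channel
  whose width is the total lumen area over the chamber length. `W(e)` is
  the edge's wall-pixel set, `h` the pixel size.
- **Flow-rate ratio** `R_Q(e) = |Q(e)| / (U_inlet · w_inlet)` — the edge's
  cross-sectional flux as a fraction of the total inlet flow.

Per frame, the network summary is the mean `R_tau`-weighted betweenness
centrality (a transport *cost* measure: how much wall-shear expense
concentrates on bottleneck nodes) and the mean `R_Q`-weighted strength
(an *importance* measure: how much of the perfusion the nodes carry).
Across a remodeling phase, a well-optimising network shows falling mean
betweenness and rising mean strength, alongside a falling total lumen
area.

Because raw time-lapse microscopy of such cultures is not publicly
available, the package ships a synthetic five-stage time-lapse generator
(meshwork → sprouting → remodeling → stable → erosion) with closed-loop
flow-dependent pruning, so the entire pipeline is testable offline; toy
geometries (straight channel, Y-branch, lattice, bridge lattice) provide
closed-form and symmetry oracles for the solver and the graph weights.

## Worked example

A mirror-symmetric Y-branch, 40 µm channels, perfused left to right at a
mean inlet velocity of 0.1 mm/s:

```r
library(vesselflow)

mask <- generate_toy_geometry(
  toy_geometry_spec("y_branch", width_um = 40,
                    image_shape_px = c(128L, 256L), pixel_size_um = 1.5625))
cfg <- flow_config(mu = 1e-3, U_inlet = 1e-4, flow_axis = "cols")
a <- analyze_mask(mask, cfg)

for (e in a$wgraph$edges)
  cat(sprintf("edge %d (%d-%d): R_Q = %.4f  R_tau = %.4f\n",
              e$id, e$from, e$to, e$R_Q, e$R_tau))
#> edge 1 (1-2): R_Q = 0.9996  R_tau = 0.0380
#> edge 2 (2-3): R_Q = 0.5001  R_tau = 0.0151
#> edge 3 (2-4): R_Q = 0.5001  R_tau = 0.0151
a$centrality$mean_betweenness
#> [1] 0.75
```

The parent edge carries the full inlet flow (`R_Q ≈ 1`), each daughter
exactly half (`R_Q ≈ 0.5`, by symmetry and mass conservation, both
recovered by the solver to a fraction of a percent), and the junction node
is the only node with nonzero betweenness. A full time-lapse study is one
call per sample:

```r
ds  <- generate_timelapse(timelapse_config(pixel_size_um = 7.8125, seed = 1))
res <- run_pipeline(ds, output_dir = "out")   # per-frame graphs + metrics.csv
head(res$metrics[, c("frame_id", "area_px", "mean_betweenness",
                     "mean_strength", "stage")])
```

During the generated remodeling stage the metrics reproduce the remodeling
signature: total area falls, mean WSS-weighted betweenness falls, and mean
flow-weighted strength rises.

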