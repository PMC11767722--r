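test_that("toy geometries have their defining shapes", {
  ## straight channel: round(100/1.5625) = 64 lumen rows in every column
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 256L), 1.5625))
  expect_true(all(colSums(m$pixels) == 64L))

  ## y-branch equals its own transverse mirror image
  my <- generate_toy_geometry(toy_geometry_spec("y_branch", 40,
                                                c(128L, 256L), 1.5625))
  expect_identical(my$pixels, my$pixels[rev(seq_len(128)), ])

  ## resolvability guard
  expect_error(toy_geometry_spec("straight_channel", width_um = 5,
                                 pixel_size_um = 1.5625), "resolvability")
})

test_that("bridge lattice yields two degree-3 junctions and one bridge edge", {
  m <- generate_toy_geometry(toy_geometry_spec("bridge_lattice", 50,
                                               c(256L, 192L), 7.8125))
  g <- extract_graph(skeletonize_mask(m))
  junctions <- g$nodes[g$nodes$kind == "junction", ]
  expect_identical(nrow(junctions), 2L)
  deg <- table(c(vapply(g$edges, function(e) e$from, numeric(1)),
                 vapply(g$edges, function(e) e$to, numeric(1))))
  expect_true(all(deg[as.character(junctions$id)] == 3))
  perp <- Filter(function(e) abs(e$orientation - pi / 2) < 10 * pi / 180,
                 g$edges)
  expect_identical(length(perp), 1L)
})

test_that("timelapse obeys stage area semantics and determinism", {
  cfg <- timelapse_config(stage_durations = c(meshwork = 3L, sprouting = 3L,
                                              remodeling = 3L, stable = 3L,
                                              erosion = 3L),
                          pixel_size_um = 7.8125, seed = 1L)
  ds <- generate_timelapse(cfg)
  expect_identical(length(ds$masks), 15L)
  a <- ds$areas_px
  expect_gt(a[6], a[1])    # sprouting above meshwork start (0-based 5 vs 0)
  expect_lt(a[9], a[6])    # remodeling end below sprouting end (8 vs 5)
  expect_gt(a[15], a[12])  # erosion end above stable (14 vs 11)
  expect_identical(ds$stage_labels,
                   rep(STAGES, each = 3L))

  ## stable frames move area by < 1% per frame
  stab <- which(ds$stage_labels == "stable")
  expect_true(all(abs(diff(a[stab])) < 0.01 * max(a)))

  ## bit-exact reproducibility
  ds2 <- generate_timelapse(cfg)
  expect_identical(lapply(ds$masks, `[[`, "pixels"),
                   lapply(ds2$masks, `[[`, "pixels"))
})

test_that("zero prune fraction makes remodeling a no-op", {
  cfg <- timelapse_config(stage_durations = c(meshwork = 2L, sprouting = 2L,
                                              remodeling = 2L, stable = 1L,
                                              erosion = 1L),
                          pixel_size_um = 7.8125, seed = 3L,
                          prune_fraction_per_frame = 0)
  ds <- generate_timelapse(cfg)
  last_sprout <- ds$masks[[4]]$pixels
  expect_identical(ds$masks[[5]]$pixels, last_sprout)
  expect_identical(ds$masks[[6]]$pixels, last_sprout)
})

test_that("sprouting lowers the circular variance of edge orientations", {
  hits <- 0L
  for (sd in 1:10) {
    cfg <- timelapse_config(stage_durations = c(meshwork = 2L, sprouting = 2L,
                                                remodeling = 1L, stable = 1L,
                                                erosion = 1L),
                            pixel_size_um = 7.8125, seed = sd,
                            prune_fraction_per_frame = 0)
    ds <- generate_timelapse(cfg)
    aniso <- function(i)
      orientation_anisotropy(extract_graph(skeletonize_mask(ds$masks[[i]])))
    ## circular variance = 1 - anisotropy: strictly lower when sprouting
    if (aniso(4) > aniso(2)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pruning removes low-flow perpendicular edges but spares the ports", {
  cfg <- flow_config()
  ## straight channel: the only edge is port-to-port, nothing prunable
  ms <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                                c(64L, 256L), 1.5625))
  as_ <- analyze_mask(ms, flow_config(flow_axis = "cols"))
  ps <- apply_pruning_event(ms, as_$wgraph, 1)
  expect_true(attr(ps, "warning"))
  expect_identical(ps$pixels, ms$pixels)

  ## 3x3 lattice, k = 2: two edges go, ports stay connected
  ml <- generate_toy_geometry(toy_geometry_spec("lattice", 50,
                                                c(256L, 384L), 7.8125))
  al <- analyze_mask(ml, cfg)
  pl <- apply_pruning_event(ml, al$wgraph, 2)
  removed <- attr(pl, "pruned_edges")
  expect_identical(length(removed), 2L)
  expect_true(vesselflow:::ports_connected(pl$pixels))
  g2 <- extract_graph(skeletonize_mask(pl))
  expect_lte(length(g2$edges), length(al$wgraph$edges) - 2L)
})
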