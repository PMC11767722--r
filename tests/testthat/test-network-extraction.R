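test_that("skeletons of canonical shapes have the expected topology", {
  ## rectangle: single medial line, 2 endpoints, no junctions
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 256L), 1.5625))
  g <- extract_graph(skeletonize_mask(m))
  expect_identical(sum(g$nodes$kind == "junction"), 0L)
  expect_identical(sum(g$nodes$kind == "endpoint"), 2L)
  expect_identical(length(g$edges), 1L)

  ## y-branch: one junction, three endpoints after spur pruning
  my <- generate_toy_geometry(toy_geometry_spec("y_branch", 40,
                                                c(128L, 256L), 1.5625))
  gy <- extract_graph(skeletonize_mask(my))
  expect_identical(sum(gy$nodes$kind == "junction"), 1L)
  expect_identical(sum(gy$nodes$kind == "endpoint"), 3L)

  ## solid disc collapses to a degenerate skeleton
  disc <- matrix(FALSE, 41, 41)
  for (r in 1:41) for (c in 1:41)
    disc[r, c] <- (r - 21)^2 + (c - 21)^2 <= 15^2
  sk <- skeletonize_mask(lumen_mask(disc, 1))
  expect_true(sk$degenerate)
  expect_error(skeletonize_mask(lumen_mask(matrix(FALSE, 4, 4) | FALSE,
                                           1)), "empty")
})

test_that("graph cycle rank equals the number of lattice holes", {
  m <- generate_toy_geometry(toy_geometry_spec("lattice", 50,
                                               c(256L, 384L), 7.8125))
  g <- extract_graph(skeletonize_mask(m))
  V <- nrow(g$nodes); E <- length(g$edges)
  C <- 1L
  ## independent hole count from the mask: interior background components
  bg <- !m$pixels
  lab <- EBImage::bwlabel(matrix(as.numeric(bg), nrow(bg)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  holes <- length(setdiff(unique(as.vector(lab)), c(0, border_labels)))
  expect_identical(E - V + C, as.integer(holes))
})

test_that("edge chains plus node clusters reproduce the skeleton exactly", {
  for (kind in c("y_branch", "bridge_lattice", "lattice")) {
    shape <- if (kind == "y_branch") c(128L, 256L) else c(256L, 192L)
    pu <- if (kind == "y_branch") 1.5625 else 7.8125
    wd <- if (kind == "y_branch") 40 else 50
    m <- generate_toy_geometry(toy_geometry_spec(kind, wd, shape, pu))
    sk <- skeletonize_mask(m)
    g <- extract_graph(sk)
    recon <- matrix(FALSE, nrow(sk$pixels), ncol(sk$pixels))
    for (e in g$edges) recon[e$chain] <- TRUE
    for (np in g$node_px) recon[np] <- TRUE
    expect_identical(recon, sk$pixels)
  }
})

test_that("bridge chain is perpendicular to the flow axis", {
  m <- generate_toy_geometry(toy_geometry_spec("bridge_lattice", 50,
                                               c(256L, 192L), 7.8125))
  g <- extract_graph(skeletonize_mask(m))
  perp <- Filter(function(e) abs(e$orientation - pi / 2) < 10 * pi / 180,
                 g$edges)
  expect_identical(length(perp), 1L)
})

test_that("edge regions cover the lumen and stay disjoint", {
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 256L), 1.5625))
  g <- extract_graph(skeletonize_mask(m))
  reg <- assign_edge_regions(g, m)
  expect_gte(reg$coverage, 0.99)      # single edge claims ~whole lumen

  mb <- generate_toy_geometry(toy_geometry_spec("bridge_lattice", 50,
                                                c(256L, 192L), 7.8125))
  gb <- extract_graph(skeletonize_mask(mb))
  regb <- assign_edge_regions(gb, mb)
  expect_gte(regb$coverage, 0.95)
  ## disjoint by construction: one label per pixel
  expect_true(all(regb$label[!mb$pixels] == 0L))
})

test_that("hydrodynamic weights match closed forms on the channel toy", {
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 256L), 1.5625))
  cfg <- flow_config(mu = 1e-3, U_inlet = 1e-4, flow_axis = "cols")
  a <- analyze_mask(m, cfg)
  e <- a$wgraph$edges[[1]]
  expect_lt(abs(e$R_Q - 1), 0.02)

  ## wall integral: 6 mu U / w over both walls and the full length
  h <- 1.5625e-6
  wall_sum <- sum(a$wss$wall$tau) * h
  L <- 256 * h
  expect_lt(abs(wall_sum / (6e-3 * 2 * L) - 1), 0.05)

  ## and hence the closed-form wall-shear ratio
  A <- measure_area(m)$area_um2 * 1e-12
  tau_ref <- 8 * 1e-3 * 1e-4 * 2e-3 / A
  expect_lt(abs(e$R_tau / (wall_sum / (tau_ref * 2e-3)) - 1), 1e-6)
})

test_that("weights are scale-invariant in the inlet velocity", {
  m <- generate_toy_geometry(toy_geometry_spec("bridge_lattice", 50,
                                               c(256L, 192L), 7.8125))
  a1 <- analyze_mask(m, flow_config(U_inlet = 1e-4))
  a10 <- analyze_mask(m, flow_config(U_inlet = 1e-3))
  w1 <- vapply(a1$wgraph$edges, function(e) c(e$R_tau, e$R_Q), numeric(2))
  w10 <- vapply(a10$wgraph$edges, function(e) c(e$R_tau, e$R_Q), numeric(2))
  expect_equal(w10, w1, tolerance = 1e-8)
})

test_that("signed flow ratios across an inlet-separating cut sum to one", {
  m <- generate_toy_geometry(toy_geometry_spec("bridge_lattice", 50,
                                               c(256L, 192L), 7.8125))
  a <- analyze_mask(m, flow_config())
  ## the two upper main edges cut every inlet-outlet path
  up <- Filter(function(e) abs(e$orientation) < 0.2 &&
                 min(e$chain[, 1]) < 50, a$wgraph$edges)
  expect_identical(length(up), 2L)
  expect_lt(abs(sum(vapply(up, function(e) e$R_Q, numeric(1))) - 1), 0.02)
})
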