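test_that("betweenness on elementary graphs matches hand results", {
  ## path A-B-C: middle node carries the single through pair
  wg <- wgraph_from_edges(3, c(1, 2), c(2, 3), c(1, 1))
  b <- betweenness_centrality(wg)
  expect_equal(unname(b), c(0, 1, 0))

  ## 4-leaf star: center carries all choose(4, 2) = 6 leaf pairs
  ws <- wgraph_from_edges(5, rep(1, 4), 2:5, rep(1, 4))
  bs <- betweenness_centrality(ws)
  expect_equal(unname(bs), c(6, 0, 0, 0, 0))

  expect_error(betweenness_centrality(
    wgraph_from_edges(2, 1, 2, -0.5)), "negative")
})

test_that("weighted betweenness matches the brute-force oracle exactly", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_test_graph(n = sample(5:10, 1), extra_edges = sample(2:4, 1))
    wg <- wgraph_from_edges(g$n, g$from, g$to, g$w)
    mine <- unname(betweenness_centrality(wg, "R_tau", "path_count"))
    ref <- oracle_betweenness(g$n, g$from, g$to, g$w)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("equal weights reduce to classic unweighted betweenness", {
  set.seed(77)
  for (rep in 1:5) {
    g <- random_test_graph(n = 8, extra_edges = 4)
    w1 <- rep(1, length(g$from))
    wg <- wgraph_from_edges(g$n, g$from, g$to, w1)
    expect_equal(unname(betweenness_centrality(wg)),
                 oracle_betweenness(g$n, g$from, g$to, w1),
                 tolerance = 1e-12)
  }
})

test_that("betweenness is invariant under uniform weight scaling", {
  set.seed(5)
  g <- random_test_graph(n = 9, extra_edges = 4)
  base <- betweenness_centrality(wgraph_from_edges(g$n, g$from, g$to, g$w))
  for (c_ in c(0.1, 10)) {
    scaled <- betweenness_centrality(
      wgraph_from_edges(g$n, g$from, g$to, g$w * c_))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("the verbal-definition variant is a weight-sum ratio", {
  ## path A-B-C, unit weights: only the A-C path passes through B, with
  ## weight 2; all-pairs shortest-path weights sum to 1 + 1 + 2 = 4
  wg <- wgraph_from_edges(3, c(1, 2), c(2, 3), c(1, 1))
  b <- betweenness_centrality(wg, variant = "paper_text")
  expect_equal(unname(b), c(0, 0.5, 0))
})

test_that("node strength sums incident weights with the loop convention", {
  wg <- wgraph_from_edges(3, c(1, 2), c(2, 3), c(0.3, 0.7))
  s <- node_strength(wg)
  expect_equal(unname(s), c(0.3, 1.0, 0.7))

  ## isolated node and handshake identity
  wi <- wgraph_from_edges(4, c(1, 2), c(2, 3), c(0.25, 0.5))
  si <- node_strength(wi)
  expect_equal(unname(si[4]), 0)
  expect_equal(sum(si), 2 * (0.25 + 0.5))

  ## self-loop counts twice
  wl <- wgraph_from_edges(2, c(1, 1), c(2, 1), c(0.5, 0.25))
  expect_equal(unname(node_strength(wl)), c(0.5 + 2 * 0.25, 0.5))

  ## mean strength identity
  cr <- frame_centralities(wi)
  expect_equal(cr$mean_strength, 2 * 0.75 / 4)
})

test_that("remodeling metrics aggregate samples with Student-t bands", {
  s1 <- data.frame(time_point = 0:3, area_um2 = c(10, 20, 30, 40),
                   mean_betweenness = c(5, 4, 3, 2),
                   mean_strength = c(0.1, 0.2, 0.3, 0.4))
  ## single sample: mean equals the sample, no band
  r1 <- remodeling_metrics(list(s1))
  expect_equal(r1$summary$area_um2, s1$area_um2)
  expect_true(all(is.na(r1$summary$area_um2_ci)))

  ## two identical samples: zero-width band
  r2 <- remodeling_metrics(list(s1, s1))
  expect_equal(r2$summary$mean_strength, s1$mean_strength)
  expect_true(all(r2$summary$mean_strength_ci == 0))

  ## known spread: CI half-width = t * sd / sqrt(n)
  s2 <- s1; s2$area_um2 <- s1$area_um2 + 2
  r3 <- remodeling_metrics(list(s1, s2))
  expect_equal(r3$summary$area_um2, s1$area_um2 + 1)
  expect_equal(r3$summary$area_um2_ci,
               rep(qt(0.975, 1) * sd(c(0, 2)) / sqrt(2), 4))

  ## nearest-day alignment within tolerance
  s3 <- s1; s3$time_point <- s1$time_point + 0.4
  r4 <- remodeling_metrics(list(s1, s3))
  expect_equal(r4$summary$n_samples, rep(2L, 4))
  expect_error(remodeling_metrics(list()), "no samples")
})
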