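# Shared fixtures and independent oracles.

## Minimal weighted vessel graph built directly from an edge table, for
## centrality tests that need arbitrary topologies.
wgraph_from_edges <- function(n_nodes, from, to, w) {
  nodes <- data.frame(id = seq_len(n_nodes), row = seq_len(n_nodes),
                      col = 1, kind = "junction")
  edges <- lapply(seq_along(from), function(i)
    list(id = i, from = from[i], to = to[i],
         chain = matrix(c(1L, 1L), 1, 2), halfwidth = 1,
         length_px = 1L, orientation = 0,
         R_tau = w[i], R_Q = w[i], Q_signed = w[i], flow_bearing = TRUE))
  structure(list(nodes = nodes, node_px = list(), edges = edges,
                 dim = c(2L, 2L), pixel_size_um = 1),
            class = c("weighted_vessel_graph", "vessel_graph"))
}

## Brute-force weighted betweenness oracle: exhaustively enumerates every
## simple path between each node pair, keeps the minimum-weight ones, and
## accumulates through-node fractions. Independent of igraph.
oracle_betweenness <- function(n, from, to, w) {
  adj <- lapply(seq_len(n), function(i) which(from == i | to == i))
  btw <- numeric(n)
  eps <- 1e-9
  for (s in seq_len(n - 1L)) {
    for (t_ in (s + 1L):n) {
      best <- Inf
      paths <- list()
      dfs <- function(v, visited, wsum, interior) {
        if (wsum > best + eps) return()
        if (v == t_) {
          if (wsum < best - eps) {
            best <<- wsum
            paths <<- list(interior)
          } else paths[[length(paths) + 1L]] <<- interior
          return()
        }
        for (ei in adj[[v]]) {
          u <- if (from[ei] == v) to[ei] else from[ei]
          if (u %in% visited) next
          dfs(u, c(visited, u), wsum + w[ei],
              if (u == t_) interior else c(interior, u))
        }
      }
      dfs(s, s, 0, integer(0))
      if (!is.finite(best)) next
      sigma <- length(paths)
      for (v in setdiff(seq_len(n), c(s, t_))) {
        cnt <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + cnt / sigma
      }
    }
  }
  btw
}

## Random connected sparse graph with tie-friendly exact-binary weights
## (multiples of 1/8), so shortest-path ties are detected without floating
## point ambiguity by both routes.
random_test_graph <- function(n, extra_edges = 3L) {
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {            # random spanning tree
    from <- c(from, sample.int(v - 1L, 1L)); to <- c(to, v)
  }
  for (i in seq_len(extra_edges)) {
    pair <- sample.int(n, 2L)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  keep <- from != to & !duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[keep]; to <- to[keep]
  w <- sample(1:8, length(from), replace = TRUE) / 8
  list(n = n, from = from, to = to, w = w)
}

## The small-raster synthetic study shared by the remodeling-trend and
## stage-recovery acceptance tests (computed once per session).
.study_cache <- new.env(parent = emptyenv())
acceptance_study <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = "-")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  study <- lapply(seeds, function(sd) {
    cfg <- timelapse_config(pixel_size_um = 7.8125, seed = sd)
    ds <- generate_timelapse(cfg)
    res <- suppressWarnings(run_pipeline(ds))
    list(dataset = ds, metrics = res$metrics)
  })
  .study_cache[[key]] <- study
  study
}
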