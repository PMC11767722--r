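#' Convert a weighted vessel graph to an igraph object
#'
#' Builds an undirected multigraph (parallel edges and self-loops retained)
#' whose edge attribute `weight` carries the chosen hydrodynamic weight.
#' Zero weights are lifted to a tiny positive floor so weights remain valid
#' shortest-path distances.
#'
#' @param wgraph a [weight_graph()] result.
#' @param weight `"R_tau"` or `"R_Q"`.
#' @param eps floor applied to zero weights.
#' @return An igraph graph with vertex attribute `name` = node id.
#' @export
as_igraph <- function(wgraph, weight = c("R_tau", "R_Q"), eps = 1e-8) {
  stopifnot(inherits(wgraph, "weighted_vessel_graph"))
  weight <- match.arg(weight)
  n <- nrow(wgraph$nodes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(wgraph$nodes$id)
  if (length(wgraph$edges) > 0L) {
    el <- t(vapply(wgraph$edges, function(e) c(e$from, e$to), numeric(2)))
    w <- vapply(wgraph$edges, function(e) e[[weight]], numeric(1))
    if (any(w < 0)) stop("negative edge weight")
    g <- igraph::add_edges(g, as.vector(t(el)),
                           attr = list(weight = pmax(w, eps)))
  }
  g
}

#' Weighted betweenness centrality of the vessel network
#'
#' Per-node betweenness with edge weights treated as distances (a high
#' wall-shear ratio is a high transport cost). Two variants:
#'
#' * `"path_count"` (default, the semantics of the igraph routine the
#'   analysis standardises on): for each pair `(s, t)` a node `v` accrues
#'   `sigma_st(v) / sigma_st`, the fraction of minimum-weight paths through
#'   `v`, endpoints excluded. Computed per connected component.
#' * `"paper_text"`: the ratio of weight sums — the summed shortest-path
#'   distances over the pairs whose shortest path passes through `v`
#'   (`d(s,v) + d(v,t) = d(s,t)` to within a tolerance), divided by the
#'   summed shortest-path distances over all connected pairs.
#'
#' @param wgraph a [weight_graph()] result.
#' @param weight `"R_tau"` (default) or `"R_Q"`.
#' @param variant `"path_count"` or `"paper_text"`.
#' @return Named numeric vector of per-node betweenness (names = node ids).
#' @export
betweenness_centrality <- function(wgraph, weight = c("R_tau", "R_Q"),
                                   variant = c("path_count", "paper_text")) {
  weight <- match.arg(weight)
  variant <- match.arg(variant)
  g <- as_igraph(wgraph, weight)
  if (igraph::vcount(g) == 0L) return(numeric(0))
  if (variant == "path_count") {
    b <- igraph::betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$weight)
    return(stats::setNames(as.numeric(b), igraph::V(g)$name))
  }
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  n <- nrow(d)
  tol <- 1e-9
  den <- 0
  num <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (!is.finite(d[s, t])) next
      den <- den + d[s, t]
      via <- which(d[s, ] + d[, t] <= d[s, t] + tol)
      via <- setdiff(via, c(s, t))
      num[via] <- num[via] + d[s, t]
    }
  }
  out <- if (den > 0) num / den else num
  stats::setNames(out, igraph::V(g)$name)
}

#' Node strength (weighted degree)
#'
#' Sum of the weights of all edges incident to each node; self-loops count
#' twice (the standard degree convention).
#'
#' @inheritParams betweenness_centrality
#' @return Named numeric vector of per-node strengths.
#' @export
node_strength <- function(wgraph, weight = c("R_tau", "R_Q")) {
  stopifnot(inherits(wgraph, "weighted_vessel_graph"))
  weight <- match.arg(weight)
  s <- stats::setNames(numeric(nrow(wgraph$nodes)),
                       as.character(wgraph$nodes$id))
  for (e in wgraph$edges) {
    w <- e[[weight]]
    s[as.character(e$from)] <- s[as.character(e$from)] + w
    s[as.character(e$to)] <- s[as.character(e$to)] + w
  }
  s
}

#' Per-frame centrality summary
#'
#' Mean WSS-ratio-weighted betweenness and mean flow-ratio-weighted strength
#' of one frame's weighted vessel graph, averaged over all nodes (endpoints
#' included).
#'
#' @param wgraph a [weight_graph()] result.
#' @param variant betweenness variant, see [betweenness_centrality()].
#' @return List of class `centrality_result`.
#' @export
frame_centralities <- function(wgraph, variant = "path_count") {
  b <- betweenness_centrality(wgraph, "R_tau", variant)
  s <- node_strength(wgraph, "R_Q")
  structure(list(betweenness = b, strength = s,
                 mean_betweenness = if (length(b)) mean(b) else 0,
                 mean_strength = if (length(s)) mean(s) else 0,
                 n_nodes = nrow(wgraph$nodes),
                 n_edges = length(wgraph$edges)),
            class = "centrality_result")
}

#' Aggregate remodeling metrics across samples
#'
#' Aligns per-sample time series of (total area, mean betweenness, mean
#' strength) on a common day grid (nearest day within `align_tol`) and
#' reports the cross-sample mean with a Student-t 95% confidence band at
#' each aligned time point. The band is reported absent (`NA`) when fewer
#' than 2 samples cover a time point.
#'
#' @param samples list of data.frames with columns `time_point`, `area_um2`,
#'   `mean_betweenness`, `mean_strength` (one per sample).
#' @param align_tol alignment tolerance in days.
#' @param conf confidence level.
#' @return Object of class `remodeling_metrics`: `per_sample` (input, with
#'   sample ids) and `summary` data.frame with mean and CI half-width
#'   columns per metric.
#' @export
remodeling_metrics <- function(samples, align_tol = 0.5, conf = 0.95) {
  if (length(samples) == 0L) stop("no samples supplied")
  samples <- lapply(seq_along(samples), function(i) {
    df <- samples[[i]]
    stopifnot(all(c("time_point", "area_um2", "mean_betweenness",
                    "mean_strength") %in% names(df)))
    df$sample_id <- i
    df
  })
  all_days <- sort(unique(unlist(lapply(samples, function(d) d$time_point))))
  ## merge days closer than align_tol into single reference points
  ref <- numeric(0)
  for (d in all_days) {
    if (length(ref) == 0L || d - ref[length(ref)] > align_tol) ref <- c(ref, d)
  }
  metrics <- c("area_um2", "mean_betweenness", "mean_strength")
  rows <- lapply(ref, function(d) {
    vals <- sapply(samples, function(df) {
      i <- which.min(abs(df$time_point - d))
      if (abs(df$time_point[i] - d) <= align_tol)
        unlist(df[i, metrics]) else rep(NA_real_, 3)
    })
    vals <- matrix(vals, nrow = 3)
    n <- colSums(!is.na(t(vals)))
    out <- data.frame(time_point = d)
    for (k in seq_along(metrics)) {
      v <- vals[k, ]
      v <- v[!is.na(v)]
      m <- mean(v)
      ci <- if (length(v) >= 2L)
        stats::qt(1 - (1 - conf) / 2, df = length(v) - 1L) *
          stats::sd(v) / sqrt(length(v)) else NA_real_
      out[[metrics[k]]] <- m
      out[[paste0(metrics[k], "_ci")]] <- ci
    }
    out$n_samples <- length(vals[1, ][!is.na(vals[1, ])])
    out
  })
  structure(list(per_sample = do.call(rbind, samples),
                 summary = do.call(rbind, rows)),
            class = "remodeling_metrics")
}
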