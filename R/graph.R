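#' Extract a node-edge vessel graph from a skeleton
#'
#' Skeleton pixels whose 8-neighbour skeleton degree differs from 2 are node
#' pixels; mutually 8-adjacent node pixels are clustered into single nodes
#' (kind `junction` when any pixel has degree >= 3, else `endpoint`). The
#' remaining degree-2 pixels form edge chains traced between node clusters.
#' Isolated cycles (all pixels degree 2) receive one artificial degree-2
#' anchor node. Parallel edges and self-loops are retained: lattice-like
#' lumens are genuinely cyclic multigraphs.
#'
#' @param skel a `vf_skeleton` from [skeletonize_mask()].
#' @return An object of class `vessel_graph`: `nodes` data.frame
#'   (`id`, `row`, `col`, `kind`), `node_px` list of pixel matrices,
#'   `edges` list (each with `id`, `from`, `to`, `chain` (n x 2), `halfwidth`,
#'   `length_px`, `orientation` in radians measured from the row axis),
#'   `dim`, `pixel_size_um`.
#' @export
extract_graph <- function(skel) {
  stopifnot(inherits(skel, "vf_skeleton"))
  sk <- skel$pixels
  deg <- neighbour_count8(sk)
  node_mask <- sk & deg != 2

  ## isolated cycles: components with no node pixel get an anchor
  sk_lab <- label8(sk)
  if (max(sk_lab) > 0L) {
    has_node <- unique(sk_lab[node_mask & sk_lab > 0L])
    for (comp in setdiff(seq_len(max(sk_lab)), c(0L, has_node))) {
      idx <- which(sk_lab == comp)
      if (length(idx) > 0L) node_mask[idx[1]] <- TRUE
    }
  }

  node_lab <- label8(node_mask)
  n_nodes <- max(node_lab)
  node_px <- vector("list", n_nodes)
  nodes <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      kind = character(0))
  if (n_nodes > 0L) {
    for (k in seq_len(n_nodes)) {
      pxk <- which(node_lab == k, arr.ind = TRUE)
      node_px[[k]] <- pxk
      kind <- if (any(deg[pxk] >= 3)) "junction" else "endpoint"
      nodes <- rbind(nodes, data.frame(id = k, row = mean(pxk[, 1]),
                                       col = mean(pxk[, 2]), kind = kind))
    }
  }

  ## edge chains: connected components of the degree-2 pixels
  edge_mask <- sk & !node_mask
  edge_lab <- label8(edge_mask)
  edges <- list()
  eid <- 0L
  if (max(edge_lab) > 0L) {
    comp_px <- split(seq_along(edge_lab)[edge_lab > 0L], edge_lab[edge_lab > 0L])
    for (cp in comp_px) {
      pxc <- arrayInd(cp, dim(sk))
      chain <- order_chain(edge_mask, pxc)
      from <- attach_node(node_lab, chain[1, , drop = FALSE])
      to <- attach_node(node_lab, chain[nrow(chain), , drop = FALSE])
      if (is.na(from) && is.na(to)) next        # stray fragment, flagged out
      if (is.na(from)) from <- to
      if (is.na(to)) to <- from
      eid <- eid + 1L
      hw <- skel$distance[chain]
      edges[[eid]] <- list(id = eid, from = from, to = to, chain = chain,
                           halfwidth = hw, length_px = nrow(chain),
                           orientation = chain_orientation(chain))
    }
  }
  structure(list(nodes = nodes, node_px = node_px, edges = edges,
                 dim = dim(sk), pixel_size_um = skel$pixel_size_um,
                 skeleton = skel),
            class = "vessel_graph")
}

## Order a degree-<=2 pixel component into a chain. Open chains start at a
## component end (pixel with <= 1 in-component neighbour, lexicographically
## smallest for determinism); cycles start at the smallest pixel.
order_chain <- function(edge_mask, pxc) {
  n <- nrow(pxc)
  if (n == 1L) return(pxc)
  key <- pxc[, 1] + pxc[, 2] * 1e7
  in_comp <- function(r, c) {
    hit <- edge_mask[cbind(r, c)]
    hit
  }
  deg_in <- vapply(seq_len(n), function(i) {
    rr <- pxc[i, 1] + NBR8[, 1]; cc <- pxc[i, 2] + NBR8[, 2]
    ok <- rr >= 1 & rr <= nrow(edge_mask) & cc >= 1 & cc <= ncol(edge_mask)
    sum(edge_mask[cbind(rr[ok], cc[ok])] &
          (rr[ok] + cc[ok] * 1e7) %in% key)
  }, integer(1))
  start <- if (any(deg_in <= 1L)) which(deg_in <= 1L)[order(key[deg_in <= 1L])][1] else which.min(key)
  used <- logical(n)
  lookup <- stats::setNames(seq_len(n), key)
  chain <- matrix(NA_integer_, n, 2)
  cur <- start
  for (i in seq_len(n)) {
    chain[i, ] <- pxc[cur, ]
    used[cur] <- TRUE
    rr <- pxc[cur, 1] + NBR8[, 1]; cc <- pxc[cur, 2] + NBR8[, 2]
    kk <- rr + cc * 1e7
    nxt <- lookup[as.character(kk)]
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[!used[nxt]]
    if (length(nxt) == 0L) break
    ## prefer 4-adjacent continuation for stable tracing on staircases
    d4 <- abs(pxc[nxt, 1] - pxc[cur, 1]) + abs(pxc[nxt, 2] - pxc[cur, 2]) == 1
    cur <- if (any(d4)) nxt[d4][1] else nxt[1]
  }
  chain[stats::complete.cases(chain), , drop = FALSE]
}

## Node cluster label adjacent (8-conn) to a chain end pixel, NA if none.
attach_node <- function(node_lab, px) {
  rr <- px[1, 1] + NBR8[, 1]; cc <- px[1, 2] + NBR8[, 2]
  ok <- rr >= 1 & rr <= nrow(node_lab) & cc >= 1 & cc <= ncol(node_lab)
  labs <- node_lab[cbind(rr[ok], cc[ok])]
  labs <- labs[labs > 0L]
  if (length(labs) == 0L) NA_integer_ else min(labs)
}

## Dominant orientation of a chain in radians in [0, pi), measured from the
## row (flow) axis, via principal axis of the centred coordinates.
chain_orientation <- function(chain) {
  if (nrow(chain) < 2L) return(0)
  x <- chain[, 1] - mean(chain[, 1])
  y <- chain[, 2] - mean(chain[, 2])
  th <- 0.5 * atan2(2 * sum(x * y), sum(x^2) - sum(y^2))
  th %% pi
}

#' Assign a lumen region to every graph edge
#'
#' Reconstructs the lumen area belonging to each edge from the inverse
#' distance transform idea: each chain pixel claims a disc of radius equal to
#' its distance-map value, and competing claims resolve to the nearest chain
#' pixel. Implemented as a multi-source breadth-first label propagation from
#' the chain pixels over the lumen (ties broken toward the lower edge id),
#' which assigns junction-area pixels to their nearest edge as well.
#'
#' @param graph a `vessel_graph`.
#' @param mask the originating [lumen_mask()].
#' @return An object of class `edge_regions`: `label` matrix (0 = unassigned,
#'   else edge id), `wall` data.frame of wall pixels (`row`, `col`, `edge`),
#'   `coverage` fraction of lumen pixels assigned.
#' @export
assign_edge_regions <- function(graph, mask) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(mask, "lumen_mask"))
  px <- mask$pixels
  lab <- matrix(0L, nrow(px), ncol(px))
  for (e in graph$edges) lab[e$chain] <- e$id
  if (length(graph$edges) > 0L) {
    repeat {
      grow <- matrix(Inf, nrow(px), ncol(px))
      for (k in seq_len(nrow(NBR8))) {
        nbv <- nb_shift(lab, NBR8[k, 1], NBR8[k, 2])
        nbv[nbv == 0] <- Inf
        grow <- pmin(grow, nbv)
      }
      new <- px & lab == 0L & is.finite(grow)
      if (!any(new)) break
      lab[new] <- as.integer(grow[new])
    }
  }
  w <- wall_pixels(px)
  widx <- which(w, arr.ind = TRUE)
  wall <- data.frame(row = widx[, 1], col = widx[, 2],
                     edge = lab[widx])
  structure(list(label = lab, wall = wall, lumen = px,
                 coverage = if (any(px)) sum(lab > 0L & px) / sum(px) else 0),
            class = "edge_regions")
}
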