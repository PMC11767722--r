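#' Weight a vessel graph with the WSS ratio and flow-rate ratio
#'
#' Attaches to every edge the two dimensionless hydrodynamic weights used in
#' the remodeling analysis:
#'
#' * the wall-shear-stress ratio `R_tau`: the wall-integrated WSS magnitude
#'   over the edge's lumen region, normalised by a reference WSS computed
#'   from the total lumen area. With grouping `"per_area"` (default) the
#'   reference stress is `tau_ref = 8 mu U_inlet / (A_lumen / d_ch)` — the
#'   Poiseuille-like stress of an equivalent channel whose width is the total
#'   lumen area divided by the chamber length — and the discrete wall sum
#'   becomes a line integral via the pixel size, non-dimensionalised by
#'   `d_ch`:
#'   `R_tau(e) = [sum_{i in W(e)} tau_i * h] / (tau_ref * d_ch)`.
#'   Grouping `"flat"` instead divides the raw wall sum by
#'   `8 mu U_inlet A_lumen d_ch` literally. Any fixed positive normalisation
#'   rescales all edges uniformly and leaves shortest paths and trends
#'   unchanged; the grouping is exposed because the reference form is
#'   genuinely ambiguous.
#' * the flow-rate ratio `R_Q(e) = |Q(e)| / (U_inlet * w_inlet)`, with `Q(e)`
#'   the median of cross-sectional fluxes taken at the 25/50/75% positions
#'   along the edge chain (a single midpoint section for chains shorter than
#'   3 px). The magnitude is used because perfusion direction alternates in
#'   the experiment the analysis targets.
#'
#' Edges lying in no-flow components (not on any inlet-outlet path) get both
#' weights 0 and are flagged.
#'
#' @param graph a [extract_graph()] result.
#' @param regions a [assign_edge_regions()] result.
#' @param wss a [compute_wss()] result.
#' @param field a [solve_flow()] result.
#' @param area a [measure_area()] result for the same frame.
#' @return Object of class `weighted_vessel_graph`: the graph plus per-edge
#'   `R_tau`, `R_Q`, `Q_signed` and `flow_bearing`, and the `regions` used.
#' @export
weight_graph <- function(graph, regions, wss, field, area) {
  stopifnot(inherits(graph, "vessel_graph"),
            inherits(regions, "edge_regions"),
            inherits(wss, "wall_shear_map"),
            inherits(field, "flow_field"),
            inherits(area, "area_measurement"))
  config <- field$config
  if (area$area_px == 0L) stop("total lumen area is zero")
  h <- field$h_m
  A_m2 <- area$area_um2 * 1e-12
  tau_ref <- 8 * config$mu * config$U_inlet * config$d_ch / A_m2
  Q_ref <- config$U_inlet * field$w_inlet

  ## flow-bearing test per edge via the domain's component labels
  dom <- field$domain
  mask_px <- if (is.null(dom)) NULL else dom$mask_comp
  edge_flow_bearing <- function(e) {
    if (field$no_flow || is.null(mask_px)) return(FALSE)
    mid <- e$chain[ceiling(nrow(e$chain) / 2), , drop = FALSE]
    rc <- if (dom$transposed) cbind(mid[, 2], mid[, 1]) else mid
    dom$mask_comp[rc] %in% dom$flow_bearing_labels
  }

  wall_by_edge <- split(wss$wall$tau, regions$label[cbind(wss$wall$row, wss$wall$col)])

  mask_for_flux <- lumen_mask(regions$lumen, graph$pixel_size_um)

  edges <- graph$edges
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    fb <- edge_flow_bearing(e)
    R_tau <- 0; R_Q <- 0; Q_sgn <- 0
    if (fb) {
      tw <- wall_by_edge[[as.character(e$id)]]
      wall_sum <- if (is.null(tw)) 0 else sum(tw) * h
      R_tau <- switch(config$rtau_grouping,
                      per_area = wall_sum / (tau_ref * config$d_ch),
                      flat = (if (is.null(tw)) 0 else sum(tw)) /
                        (8 * config$mu * config$U_inlet * A_m2 * config$d_ch))
      Q_sgn <- edge_flux_median(field, mask_for_flux, e)
      R_Q <- abs(Q_sgn) / Q_ref
    }
    edges[[k]]$R_tau <- R_tau
    edges[[k]]$R_Q <- R_Q
    edges[[k]]$Q_signed <- Q_sgn
    edges[[k]]$flow_bearing <- fb
  }
  out <- graph
  out$edges <- edges
  out$regions <- regions
  out$area <- area
  class(out) <- c("weighted_vessel_graph", "vessel_graph")
  out
}

## Median of cross-sectional fluxes at the 25/50/75% chain positions;
## single midpoint section for chains shorter than 3 px. Tangents come from
## a local chain window so junction-adjacent distortion does not bias them.
edge_flux_median <- function(field, mask, e) {
  n <- nrow(e$chain)
  pos <- if (n >= 3L) unique(pmax(1L, pmin(n, round(c(0.25, 0.5, 0.75) * n))))
         else ceiling(n / 2)
  qs <- vapply(pos, function(i) {
    i0 <- max(1L, i - 3L); i1 <- min(n, i + 3L)
    tg <- e$chain[i1, ] - e$chain[i0, ]
    if (all(tg == 0)) tg <- c(1, 0)
    q <- try(edge_flux(field, mask, as.numeric(e$chain[i, ]), as.numeric(tg)),
             silent = TRUE)
    if (inherits(q, "try-error")) NA_real_ else q
  }, numeric(1))
  qs <- qs[!is.na(qs)]
  if (length(qs) == 0L) return(0)
  stats::median(qs)
}
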