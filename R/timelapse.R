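#' Configuration of a synthetic remodeling time-lapse
#'
#' Parameters of the stochastic five-stage generator. The chamber defaults
#' to the 2 mm (flow direction) x 3 mm culture chamber of the targeted
#' device; at the full-scale default `pixel_size_um = 1.5625` this rasters
#' to 1280 x 1920 px. For routine testing a 4x coarser raster
#' (`pixel_size_um = 7.8125`, 256 x 384 px) resolves the same geometry at a
#' fraction of the cost.
#'
#' @param stage_durations named integer vector of frame counts per stage, in
#'   canonical order (all >= 1).
#' @param chamber_um chamber extent `(flow direction, transverse)` in um.
#' @param pixel_size_um raster pixel size in um.
#' @param seed integer; fixes the full mask sequence bit-exactly.
#' @param initial_segment_count random segments in the first meshwork frame.
#' @param sprout_anisotropy in `[0, 1]`; 0 = isotropic sprouting, 1 =
#'   perfectly flow-aligned sprouts.
#' @param prune_fraction_per_frame fraction of flow-bearing edges pruned per
#'   remodeling frame (0 disables pruning).
#' @param mesh_segments_per_frame segments added per meshwork frame.
#' @param sprouts_per_frame segments added per sprouting frame.
#' @param segment_width_um log-normal median segment width in um.
#' @return List of class `timelapse_config`.
#' @export
timelapse_config <- function(stage_durations = c(meshwork = 4L, sprouting = 4L,
                                                 remodeling = 4L, stable = 4L,
                                                 erosion = 4L),
                             chamber_um = c(2000, 3000),
                             pixel_size_um = 1.5625,
                             seed = 1L,
                             initial_segment_count = 40L,
                             sprout_anisotropy = 0.8,
                             prune_fraction_per_frame = 0.15,
                             mesh_segments_per_frame = 5L,
                             sprouts_per_frame = 16L,
                             segment_width_um = 40) {
  stopifnot(all(stage_durations >= 1L),
            all(names(stage_durations) == STAGES),
            all(chamber_um > 0), pixel_size_um > 0,
            sprout_anisotropy >= 0, sprout_anisotropy <= 1,
            prune_fraction_per_frame >= 0, prune_fraction_per_frame <= 1)
  structure(list(stage_durations = stage_durations,
                 chamber_um = chamber_um, pixel_size_um = pixel_size_um,
                 seed = as.integer(seed),
                 initial_segment_count = as.integer(initial_segment_count),
                 sprout_anisotropy = sprout_anisotropy,
                 prune_fraction_per_frame = prune_fraction_per_frame,
                 mesh_segments_per_frame = as.integer(mesh_segments_per_frame),
                 sprouts_per_frame = as.integer(sprouts_per_frame),
                 segment_width_um = segment_width_um),
            class = "timelapse_config")
}

#' Generate a synthetic five-stage remodeling time-lapse
#'
#' Produces an ordered mask sequence obeying the stage semantics of
#' long-term perfusion culture: an isotropic random meshwork (area rising),
#' directional sprouting in which two flow-spanning channels penetrate the
#' pillar borders and flow-aligned sprouts develop (area rising, orientation
#' anisotropy rising), closed-loop flow-dependent pruning of low-flow
#' near-perpendicular segments with gradual regression of unperfused
#' components (area falling), a stable plateau with sub-percent boundary
#' jitter, and erosion growing inward from the two port borders (area
#' rising again). All randomness is drawn from a
#' single stream seeded once, so a given configuration reproduces the mask
#' sequence bit-exactly.
#'
#' @param config a [timelapse_config()].
#' @param flow a [flow_config()] for the closed-loop remodeling stage;
#'   `flow_axis` must be `"rows"` (the chamber convention).
#' @return Object of class `timelapse_dataset`: `masks` (list of
#'   [lumen_mask()], `time_point` = frame index in days), `stage_labels`,
#'   `areas_px` ground-truth per-frame pixel counts, `config`.
#' @export
generate_timelapse <- function(config, flow = flow_config()) {
  stopifnot(inherits(config, "timelapse_config"))
  stopifnot(flow$flow_axis == "rows")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  pu <- config$pixel_size_um
  nr <- round(config$chamber_um[1] / pu)
  nc <- round(config$chamber_um[2] / pu)
  wseg_px <- function() max(4, round(stats::rlnorm(1, log(config$segment_width_um), 0.25) / pu))

  masks <- list(); labels <- character(0); areas <- integer(0)
  frame <- 0L
  push <- function(px, stage) {
    frame <<- frame + 1L
    masks[[frame]] <<- lumen_mask(px, pu, time_point = frame - 1L,
                                  frame_id = frame - 1L)
    labels[frame] <<- stage
    areas[frame] <<- sum(px)
  }

  ## isotropic by construction: orientations stratified over [0, pi)
  add_random_segments <- function(px, n) {
    ths <- ((seq_len(n) - 1L) + stats::runif(n)) * pi / n
    for (th in ths) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      len <- stats::runif(1, 250, 550) / pu
      px <- stamp_segment(px, r0 - len / 2 * cos(th), c0 - len / 2 * sin(th),
                          r0 + len / 2 * cos(th), c0 + len / 2 * sin(th),
                          wseg_px())
    }
    px
  }
  add_sprout <- function(px) {
    idx <- which(px)
    if (length(idx) == 0L) return(px)
    p <- arrayInd(idx[sample.int(length(idx), 1L)], dim(px))
    th <- stats::rnorm(1, 0, (1 - config$sprout_anisotropy) * pi / 2)
    len <- stats::runif(1, 400, 800) / pu
    sgn <- sample(c(-1, 1), 1)
    stamp_segment(px, p[1], p[2],
                  p[1] + sgn * len * cos(th), p[2] + sgn * len * sin(th),
                  wseg_px())
  }

  ## weak tortuous spanning channel: narrow, with steep lateral jogs, the
  ## redundant parallel paths that remodeling later eliminates
  add_weak_channel <- function(px) {
    w <- max(4, round(0.8 * config$segment_width_um / pu))
    steps <- 8L
    rr <- seq(1, nr, length.out = steps + 1L)
    cur <- stats::runif(1, nc * 0.15, nc * 0.85)
    for (s in seq_len(steps)) {
      lat <- if (s %% 2L == 0L)
        sample(c(-1, 1), 1) * stats::runif(1, 280, 430) / pu
      else stats::runif(1, -60, 60) / pu
      nxt <- min(max(cur + lat, 4), nc - 3)
      px <- stamp_segment(px, rr[s], cur, rr[s + 1L], nxt, w)
      cur <- nxt
    }
    px
  }

  ## ---- meshwork: isotropic random segment mesh, growing ----
  px <- matrix(FALSE, nr, nc)
  px <- add_random_segments(px, config$initial_segment_count)
  push(px, "meshwork")
  for (f in seq_len(config$stage_durations[["meshwork"]] - 1L)) {
    px <- add_random_segments(px, config$mesh_segments_per_frame)
    push(px, "meshwork")
  }

  ## ---- sprouting: directional development along the perfusion axis ----
  ## Flow-spanning channels penetrate the pillar borders first: two strong
  ## straight mains plus weak tortuous parallel paths; flow-aligned sprouts
  ## then develop on the lumen.
  w_main <- max(6, round(1.6 * config$segment_width_um / pu))
  for (f in seq_len(config$stage_durations[["sprouting"]])) {
    if (f == 1L) {
      for (fr in c(1 / 3, 2 / 3)) {
        cc <- nc * fr + stats::runif(1, -nc / 12, nc / 12)
        way <- cc + c(0, stats::runif(2, -nc / 20, nc / 20), 0)
        rows <- c(1, nr / 3, 2 * nr / 3, nr)
        for (s in 1:3)
          px <- stamp_segment(px, rows[s], way[s], rows[s + 1], way[s + 1],
                              w_main)
      }
      for (i in 1:3) px <- add_weak_channel(px)
    }
    for (i in seq_len(config$sprouts_per_frame)) px <- add_sprout(px)
    push(px, "sprouting")
  }

  ## ---- remodeling: closed-loop pruning of low-R_Q perpendicular edges ----
  for (f in seq_len(config$stage_durations[["remodeling"]])) {
    if (config$prune_fraction_per_frame > 0) {
      an <- analyze_mask(lumen_mask(px, pu), flow)
      if (an$field$no_flow)
        stop("remodeling requested on a mask with no inlet-outlet connected path: flow undefined")
      n_fb <- sum(vapply(an$wgraph$edges, function(e) e$flow_bearing, logical(1)))
      k <- max(1L, round(config$prune_fraction_per_frame * n_fb))
      pruned <- apply_pruning_event(lumen_mask(px, pu), an$wgraph, k)
      px <- regress_deadend_twigs(pruned$pixels, an$wgraph, fraction = 0.5)
      px <- resorb_noflow(px, fraction = 0.4)
      px <- clean_mask(matrix(as.numeric(px), nr, nc),
                       min_object_px = 30L, fill_holes = FALSE,
                       pixel_size_um = pu)$pixels
    }
    push(px, "remodeling")
  }

  ## ---- stable: +/-1 px boundary jitter on 5% of wall pixels ----
  for (f in seq_len(config$stage_durations[["stable"]])) {
    w <- which(wall_pixels(px), arr.ind = TRUE)
    njit <- max(1L, round(0.05 * nrow(w)))
    pick <- w[sample.int(nrow(w), njit), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      r <- pick[i, 1]; c <- pick[i, 2]
      if (stats::runif(1) < 0.5) {
        px[r, c] <- FALSE                       # 1 px erosion
      } else {                                   # 1 px dilation outward
        for (k in seq_len(nrow(NBR4))) {
          rr <- r + NBR4[k, 1]; cc <- c + NBR4[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !px[rr, cc]) {
            px[rr, cc] <- TRUE
            break
          }
        }
      }
    }
    push(px, "stable")
  }

  ## ---- erosion: dilation seeded from the two port borders ----
  brush <- EBImage::makeBrush(5, shape = "disc")
  for (f in seq_len(config$stage_durations[["erosion"]])) {
    band <- max(4L, round(nr * 0.08 * f))
    zone <- matrix(FALSE, nr, nc)
    zone[seq_len(min(band, nr)), ] <- TRUE
    zone[seq(max(1L, nr - band + 1L), nr), ] <- TRUE
    grown <- EBImage::dilate(matrix(as.numeric(px & zone), nr, nc), brush)
    px <- px | (matrix(as.numeric(grown) != 0, nr, nc) & zone)
    push(px, "erosion")
  }

  structure(list(masks = masks, stage_labels = labels, areas_px = areas,
                 config = config),
            class = "timelapse_dataset")
}

#' Remove the lowest-flow near-perpendicular edges from a mask
#'
#' Operationalises flow-dependent pruning: among flow-bearing edges whose
#' orientation is within `angle_max_deg` of perpendicular to the flow axis
#' and whose lumen region does not touch the inlet/outlet borders, the `k`
#' lowest-`R_Q` edges (ties broken by lowest edge id) have their lumen
#' regions erased. A candidate whose removal would disconnect the inlet
#' border from the outlet border is skipped and the next-lowest taken.
#'
#' @param mask the [lumen_mask()] the graph was computed from.
#' @param wgraph a [weight_graph()] result for that mask.
#' @param k number of edges to prune (>= 1).
#' @param angle_max_deg angular half-window around perpendicular.
#' @param rq_max only edges whose flow-rate ratio is below this ceiling are
#'   prunable: pruning targets segments that themselves carry little flow,
#'   never the high-flow vessels they bridge.
#' @return The pruned [lumen_mask()]; attribute `warning` is `TRUE` and the
#'   mask unchanged when no edge is prunable; attribute `pruned_edges` lists
#'   the removed edge ids.
#' @export
apply_pruning_event <- function(mask, wgraph, k, angle_max_deg = 45,
                                rq_max = 0.2) {
  stopifnot(inherits(mask, "lumen_mask"),
            inherits(wgraph, "weighted_vessel_graph"), k >= 1)
  px <- mask$pixels
  nr <- nrow(px)
  lab <- wgraph$regions$label
  cand <- Filter(function(e) {
    if (!isTRUE(e$flow_bearing)) return(FALSE)
    if (e$R_Q >= rq_max) return(FALSE)
    dperp <- abs(e$orientation - pi / 2)
    if (dperp > angle_max_deg * pi / 180) return(FALSE)
    reg <- lab == e$id
    !any(reg[1, ]) && !any(reg[nr, ])           # not port-touching
  }, wgraph$edges)
  if (length(cand) == 0L) {
    out <- mask
    attr(out, "warning") <- TRUE
    attr(out, "pruned_edges") <- integer(0)
    return(out)
  }
  ord <- order(vapply(cand, function(e) e$R_Q, numeric(1)),
               vapply(cand, function(e) e$id, numeric(1)))
  cand <- cand[ord]
  removed <- integer(0)
  for (e in cand) {
    if (length(removed) >= k) break
    trial <- px & !(lab == e$id)
    if (ports_connected(trial)) {
      px <- trial
      removed <- c(removed, e$id)
    }
  }
  out <- lumen_mask(px, mask$pixel_size_um, mask$time_point, mask$frame_id)
  attr(out, "warning") <- length(removed) == 0L
  attr(out, "pruned_edges") <- removed
  out
}

## Regression of unperfused dead-end segments: edges on the perfused
## component that end blind (one endpoint node) carry essentially no flow
## and regress during remodeling whatever their orientation. Removes the
## lowest-edge-id `fraction` of them per call; port-touching regions are
## never removed.
regress_deadend_twigs <- function(px, wgraph, fraction = 0.5, rq_tiny = 0.01) {
  lab <- wgraph$regions$label
  nr <- nrow(px)
  endpoint_ids <- wgraph$nodes$id[wgraph$nodes$kind == "endpoint"]
  cand <- Filter(function(e) {
    isTRUE(e$flow_bearing) && e$R_Q < rq_tiny &&
      (e$from %in% endpoint_ids || e$to %in% endpoint_ids) &&
      { reg <- lab == e$id; !any(reg[1, ]) && !any(reg[nr, ]) }
  }, wgraph$edges)
  if (length(cand) == 0L) return(px)
  n_kill <- ceiling(fraction * length(cand))
  for (e in cand[seq_len(n_kill)]) {
    trial <- px & !(lab == e$id)
    if (ports_connected(trial)) px <- trial
  }
  px
}

## Gradual regression of unperfused lumens during remodeling: connected
## components not on any inlet-outlet path carry no flow and regress.
## Each call resorbs components, smallest first, until about `fraction` of
## the current unperfused area is gone, so the area decline is spread over
## the whole stage.
resorb_noflow <- function(px, fraction = 0.4) {
  lab <- label8(px)
  if (max(lab) == 0L) return(px)
  top <- unique(lab[1, px[1, ]])
  bot <- unique(lab[nrow(px), px[nrow(px), ]])
  flowing <- intersect(top, bot)
  noflow <- setdiff(seq_len(max(lab)), c(0L, flowing))
  if (length(noflow) == 0L) return(px)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))[noflow]
  ord <- order(sizes)
  budget <- fraction * sum(sizes)
  kill <- noflow[ord[cumsum(sizes[ord]) <= budget]]
  if (length(kill) == 0L) kill <- noflow[ord[1]]
  px & !matrix(lab %in% kill, nrow(px), ncol(px))
}

## TRUE when some 8-connected lumen component touches both the inlet (top)
## and outlet (bottom) border rows.
ports_connected <- function(px) {
  if (!any(px[1, ]) || !any(px[nrow(px), ])) return(FALSE)
  lab <- label8(px)
  length(intersect(lab[1, px[1, ]], lab[nrow(px), px[nrow(px), ]])) > 0L
}
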