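#' Analyze a single lumen mask
#'
#' Runs the per-frame chain: flow domain construction, Stokes solve, wall
#' shear stress, skeletonization, graph extraction, edge-region assignment
#' and hydrodynamic edge weighting, returning every intermediate product.
#'
#' @param mask a [lumen_mask()] (already cleaned).
#' @param flow a [flow_config()].
#' @param spur_min_px skeleton spur-pruning threshold (px).
#' @param port_length_px port channel length (px).
#' @param variant betweenness variant, see [betweenness_centrality()].
#' @return List of class `frame_analysis` with `area`, `domain`, `field`,
#'   `wss`, `skeleton`, `graph`, `regions`, `wgraph`, `centrality`,
#'   `anisotropy`.
#' @export
analyze_mask <- function(mask, flow = flow_config(), spur_min_px = 5L,
                         port_length_px = 20L, variant = "path_count") {
  stopifnot(inherits(mask, "lumen_mask"))
  area <- measure_area(mask)
  domain <- build_domain(mask, flow, port_length_px, require_path = FALSE)
  field <- solve_flow(domain, flow)
  wss <- compute_wss(field, mask)
  skel <- skeletonize_mask(mask, spur_min_px)
  graph <- extract_graph(skel)
  regions <- assign_edge_regions(graph, mask)
  wgraph <- weight_graph(graph, regions, wss, field, area)
  cent <- frame_centralities(wgraph, variant)
  structure(list(area = area, domain = domain, field = field, wss = wss,
                 skeleton = skel, graph = graph, regions = regions,
                 wgraph = wgraph, centrality = cent,
                 anisotropy = orientation_anisotropy(graph)),
            class = "frame_analysis")
}

#' Run the full remodeling-analysis pipeline
#'
#' Orchestrates the per-frame analysis over a mask sequence — either a
#' directory of `frame_####.tif`/`.png` masks or a synthetic
#' [timelapse_config()] — then classifies stages and assembles the per-frame
#' metric series. In partial-results mode a failing frame is logged and
#' skipped; in strict mode it aborts the run.
#'
#' @param input a `timelapse_dataset`, a [timelapse_config()], or a
#'   directory path containing mask images.
#' @param flow a [flow_config()].
#' @param output_dir optional directory; when given, per-frame graph JSON,
#'   a metrics CSV, stage labels and the serialized run configuration are
#'   written there with stable filenames.
#' @param strict abort on the first frame error instead of skipping.
#' @param min_object_px,spur_min_px,port_length_px,variant stage parameters.
#' @param classify run the stage classifier on the resulting series?
#' @return List of class `pipeline_result`: `frames` (per-frame analyses),
#'   `metrics` data.frame (`frame_id`, `time_point`, `area_px`, `area_um2`,
#'   `mean_betweenness`, `mean_strength`, `anisotropy`, `stage`), `stages`
#'   ([classify_stages()] output or `NULL`), `errors` (named list), `config`.
#' @export
run_pipeline <- function(input, flow = flow_config(), output_dir = NULL,
                         strict = FALSE, min_object_px = 30L,
                         spur_min_px = 5L, port_length_px = 20L,
                         variant = "path_count", classify = TRUE) {
  ## frame suppliers: already-loaded masks, or per-file lazy readers so a
  ## corrupt file fails only its own frame
  suppliers <- if (inherits(input, "timelapse_dataset")) {
    lapply(input$masks, function(m) function() m)
  } else if (inherits(input, "timelapse_config")) {
    lapply(generate_timelapse(input, flow)$masks, function(m) function() m)
  } else if (is.character(input) && length(input) == 1L) {
    files <- sort(list.files(input, pattern = "^frame_\\d+\\.(tif|tiff|png)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no frame_####.tif/.png masks in ", input)
    meta <- list(pixel_size_um = 1.5625, time_points = seq_along(files) - 1)
    side <- file.path(input, "timelapse.json")
    if (file.exists(side)) {
      sj <- jsonlite::read_json(side, simplifyVector = TRUE)
      if (!is.null(sj$pixel_size_um)) meta$pixel_size_um <- sj$pixel_size_um
      if (!is.null(sj$time_points) && length(sj$time_points) == length(files))
        meta$time_points <- sj$time_points
    }
    lapply(seq_along(files), function(i) function()
      read_mask(files[i], pixel_size_um = meta$pixel_size_um,
                time_point = meta$time_points[i], frame_id = i - 1L,
                min_object_px = min_object_px))
  } else stop("input must be a timelapse dataset/config or a mask directory")

  frames <- vector("list", length(suppliers))
  masks <- vector("list", length(suppliers))
  errors <- list()
  for (i in seq_along(suppliers)) {
    res <- try({
      m <- suppliers[[i]]()
      list(mask = m,
           analysis = analyze_mask(m, flow, spur_min_px, port_length_px,
                                   variant))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      msg <- conditionMessage(attr(res, "condition"))
      if (strict) stop(sprintf("frame %d failed: %s", i - 1L, msg))
      errors[[as.character(i - 1L)]] <- msg
      frames[i] <- list(NULL)
    } else {
      frames[[i]] <- res$analysis
      masks[[i]] <- res$mask
    }
  }
  ok <- !vapply(frames, is.null, logical(1))
  if (!any(ok)) stop("no frame could be analyzed")

  metrics <- do.call(rbind, lapply(which(ok), function(i) {
    fr <- frames[[i]]
    data.frame(frame_id = masks[[i]]$frame_id,
               time_point = masks[[i]]$time_point,
               area_px = fr$area$area_px,
               area_um2 = fr$area$area_um2,
               mean_betweenness = fr$centrality$mean_betweenness,
               mean_strength = fr$centrality$mean_strength,
               anisotropy = fr$anisotropy)
  }))
  stages <- NULL
  if (classify && nrow(metrics) >= 5L) {
    stages <- classify_stages(metrics$area_um2, metrics$anisotropy)
    metrics$stage <- stages$per_frame
  }
  out <- structure(list(frames = frames, metrics = metrics, stages = stages,
                        errors = errors, flow = flow),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

#' Per-sample metric series for cross-sample aggregation
#'
#' @param result a [run_pipeline()] result.
#' @return data.frame suitable for [remodeling_metrics()].
#' @export
metrics_series <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  result$metrics[, c("time_point", "area_um2", "mean_betweenness",
                     "mean_strength")]
}
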