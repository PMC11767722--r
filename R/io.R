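#' Read a binary mask image
#'
#' Reads an 8-bit single-channel TIFF or PNG mask (0 = background, nonzero =
#' lumen) and cleans it into a [lumen_mask()].
#'
#' @param path image file path.
#' @param pixel_size_um,time_point,frame_id see [lumen_mask()].
#' @param ... passed to [clean_mask()].
#' @return A `lumen_mask`.
#' @export
read_mask <- function(path, pixel_size_um = 1.5625, time_point = NA_real_,
                      frame_id = NA_integer_, ...) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  clean_mask(matrix(as.numeric(img > 0.5), nrow(img), ncol(img)),
             pixel_size_um = pixel_size_um, time_point = time_point,
             frame_id = frame_id, ...)
}

#' Read an ordered directory of mask frames
#'
#' Frames named `frame_####.tif` (or `.png`) are read in lexical order; a
#' `timelapse.json` sidecar, when present, supplies pixel size and per-frame
#' days.
#'
#' @param dir directory path.
#' @param pixel_size_um fallback pixel size when no sidecar exists.
#' @param ... passed to [read_mask()].
#' @return List of `lumen_mask`.
#' @export
read_mask_dir <- function(dir, pixel_size_um = 1.5625, ...) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame_####.tif/.png masks in ", dir)
  side <- file.path(dir, "timelapse.json")
  days <- seq_along(files) - 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$time_points) && length(meta$time_points) == length(files))
      days <- meta$time_points
  }
  lapply(seq_along(files), function(i)
    read_mask(files[i], pixel_size_um = pixel_size_um, time_point = days[i],
              frame_id = i - 1L, ...))
}

#' Write a timelapse dataset to disk
#'
#' Masks as 8-bit single-channel TIFF (`0`/`255`), filenames
#' `frame_####.tif`, plus a `timelapse.json` sidecar holding the stage
#' labels and generator configuration.
#'
#' @param dataset a [generate_timelapse()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_timelapse <- function(dataset, dir) {
  stopifnot(inherits(dataset, "timelapse_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$masks)) {
    m <- dataset$masks[[i]]
    tiff::writeTIFF(matrix(as.numeric(m$pixels), nrow(m$pixels)),
                    file.path(dir, sprintf("frame_%04d.tif", i - 1L)),
                    bits.per.sample = 8L)
  }
  jsonlite::write_json(
    list(pixel_size_um = dataset$config$pixel_size_um,
         time_points = vapply(dataset$masks, function(m) m$time_point,
                              numeric(1)),
         stage_labels = dataset$stage_labels,
         config = dataset$config[setdiff(names(dataset$config), NULL)]),
    file.path(dir, "timelapse.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export a weighted vessel graph as JSON
#'
#' Nodes with pixel and micrometre coordinates; edges with their chain,
#' half-width profile and hydrodynamic weights.
#'
#' @param wgraph a [weight_graph()] result.
#' @param path output file.
#' @param config_hash optional run-configuration hash embedded in the header.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(wgraph, path, config_hash = NULL) {
  stopifnot(inherits(wgraph, "weighted_vessel_graph"))
  pu <- wgraph$pixel_size_um
  nodes <- wgraph$nodes
  nodes$row_um <- nodes$row * pu
  nodes$col_um <- nodes$col * pu
  edges <- lapply(wgraph$edges, function(e)
    list(id = e$id, from = e$from, to = e$to,
         chain = unname(apply(e$chain, 1, as.integer, simplify = FALSE)),
         halfwidth_px = e$halfwidth, length_px = e$length_px,
         orientation_rad = e$orientation,
         R_tau = e$R_tau, R_Q = e$R_Q, Q_m2_s = e$Q_signed,
         flow_bearing = e$flow_bearing))
  payload <- list(pixel_size_um = pu, nodes = nodes, edges = edges)
  if (!is.null(config_hash)) payload <- c(list(config_hash = config_hash),
                                          payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a plain-text weighted edge list
#'
#' One line per edge: `from to R_tau R_Q length_px`.
#'
#' @param wgraph a [weight_graph()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(wgraph, path) {
  stopifnot(inherits(wgraph, "weighted_vessel_graph"))
  df <- do.call(rbind, lapply(wgraph$edges, function(e)
    data.frame(from = e$from, to = e$to, R_tau = e$R_tau, R_Q = e$R_Q,
               length_px = e$length_px)))
  if (is.null(df)) df <- data.frame(from = integer(0), to = integer(0),
                                    R_tau = numeric(0), R_Q = numeric(0),
                                    length_px = integer(0))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the weighted adjacency matrix as dense CSV
#'
#' Node-by-node matrix of summed edge weights (parallel edges add).
#'
#' @param wgraph a [weight_graph()] result.
#' @param path output file.
#' @param weight which weight to export.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(wgraph, path, weight = c("R_tau", "R_Q")) {
  stopifnot(inherits(wgraph, "weighted_vessel_graph"))
  weight <- match.arg(weight)
  n <- nrow(wgraph$nodes)
  A <- matrix(0, n, n, dimnames = list(wgraph$nodes$id, wgraph$nodes$id))
  for (e in wgraph$edges) {
    A[e$from, e$to] <- A[e$from, e$to] + e[[weight]]
    if (e$from != e$to) A[e$to, e$from] <- A[e$to, e$from] + e[[weight]]
  }
  utils::write.csv(A, path, row.names = TRUE)
  invisible(path)
}

## Stable digest of a configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[], tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write per-run pipeline outputs
#'
#' Metrics CSV (`frame_id, day, area_px, area_um2, mean_betweenness,
#' mean_strength, stage`), per-frame graph JSONs, a wall-shear CSV per frame
#' and the flow configuration, all under stable filenames.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(result$flow)
  m <- result$metrics
  names(m)[names(m) == "time_point"] <- "day"
  con <- file(file.path(dir, "metrics.csv"), "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(m, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(c(list(config_hash = hash), result$flow[]),
                       file.path(dir, "flow_config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(result$frames)) {
    fr <- result$frames[[i]]
    if (is.null(fr)) next
    write_graph_json(fr$wgraph,
                     file.path(dir, sprintf("graph_%04d.json", i - 1L)),
                     config_hash = hash)
    con <- file(file.path(dir, sprintf("wall_tau_%04d.csv", i - 1L)), "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.csv(fr$wss$wall, con, row.names = FALSE)
    close(con)
    write_edge_list(fr$wgraph,
                    file.path(dir, sprintf("edges_%04d.txt", i - 1L)))
  }
  if (length(result$errors))
    writeLines(unlist(Map(function(k, v) paste0("frame ", k, ": ", v),
                          names(result$errors), result$errors)),
               file.path(dir, "errors.log"))
  invisible(dir)
}
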