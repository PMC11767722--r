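#' Canonical morphological stages
#'
#' The five stages of long-term perfusion culture, in their canonical
#' temporal order: an isotropic vasculogenic meshwork, flow-aligned
#' sprouting, flow-dependent remodeling (pruning, area decreasing), a stable
#' plateau, and erosion (cell invasion from the perfusion channels, area
#' rising again).
#'
#' @export
STAGES <- c("meshwork", "sprouting", "remodeling", "stable", "erosion")

#' Orientation anisotropy of a skeletonized network
#'
#' One minus the circular variance of the doubled skeleton-edge orientation
#' angles, weighted by chain length: 0 for an isotropic meshwork, 1 when all
#' segments share one axis. Doubling the angles identifies a direction with
#' its opposite, as appropriate for undirected segments.
#'
#' @param graph a [extract_graph()] result (a weighted graph works too).
#' @return Scalar in `[0, 1]`.
#' @export
orientation_anisotropy <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (length(graph$edges) == 0L) return(0)
  th <- vapply(graph$edges, function(e) e$orientation, numeric(1))
  len <- vapply(graph$edges, function(e) e$length_px, numeric(1))
  if (sum(len) == 0) return(0)
  cx <- sum(len * cos(2 * th)) / sum(len)
  sx <- sum(len * sin(2 * th)) / sum(len)
  sqrt(cx^2 + sx^2)
}

#' Classify morphological stages from area and anisotropy series
#'
#' Piecewise labelling of a time-ordered frame sequence from the smoothed
#' area derivative: rising area is `meshwork` until the orientation
#' anisotropy first exceeds `aniso_threshold` (then `sprouting`); falling
#' area is `remodeling`; a flat run (|slope| below `flat_tol` of the maximum
#' area per frame) after remodeling is `stable`; rising area after a stable
#' run is `erosion`. Stages only ever advance in the canonical order, and a
#' new stage must persist at least `min_stage_frames` frames before the next
#' transition is allowed.
#'
#' @param areas list of [measure_area()] results (or numeric vector of
#'   areas), time-ordered.
#' @param anisotropy numeric vector of per-frame orientation anisotropy.
#' @param smooth_window moving-average window (frames) for the area series.
#' @param aniso_threshold anisotropy level separating meshwork from
#'   sprouting.
#' @param flat_tol slope threshold as a fraction of the maximum area.
#' @param min_stage_frames minimum persistence of a stage.
#' @return Object of class `stage_labels`: `per_frame` character vector and
#'   `ranges` data.frame (`stage`, `start`, `end`, 1-based inclusive).
#' @export
classify_stages <- function(areas, anisotropy,
                            smooth_window = 3L, aniso_threshold = 0.3,
                            flat_tol = 0.01, min_stage_frames = 2L) {
  a <- if (is.numeric(areas)) areas
       else vapply(areas, function(x) x$area_um2, numeric(1))
  n <- length(a)
  if (n < 5L) stop("need at least 5 frames to classify stages")
  if (n < smooth_window) stop("fewer frames than the smoothing window")
  stopifnot(length(anisotropy) == n)

  ## centred moving average, shrinking at the ends
  half <- floor(smooth_window / 2)
  s <- vapply(seq_len(n), function(i) {
    mean(a[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  ## centred slope
  slope <- numeric(n)
  slope[1] <- s[2] - s[1]
  slope[n] <- s[n] - s[n - 1]
  if (n > 2L) slope[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / 2
  flat <- flat_tol * max(a)

  lab <- character(n)
  state <- 1L   # index into STAGES
  entered <- 1L
  for (i in seq_len(n)) {
    can_advance <- (i - entered) >= min_stage_frames || i == 1L
    if (can_advance) {
      new_state <- state
      if (state == 1L && anisotropy[i] > aniso_threshold && slope[i] > -flat) {
        new_state <- 2L
      }
      if (state <= 2L && slope[i] < -flat) new_state <- 3L
      if (state == 3L && abs(slope[i]) <= flat) new_state <- 4L
      if (state == 4L && slope[i] > flat) new_state <- 5L
      if (new_state != state) {
        state <- new_state
        entered <- i
      }
    }
    lab[i] <- STAGES[state]
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  ranges <- data.frame(stage = r$values,
                       start = c(1L, utils::head(ends, -1) + 1L),
                       end = ends)
  structure(list(per_frame = lab, ranges = ranges),
            class = "stage_labels")
}
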