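#' Binary lumen mask at one time point
#'
#' Container for a single-frame binary lumen mask with its physical pixel
#' size. Row 0-style raster conventions: the matrix is row-major with row 1 at
#' the top of the image; perfusion by default runs top to bottom (along rows).
#'
#' @param pixels logical or 0/1 matrix, `TRUE` = lumen.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param time_point acquisition time in days (may be `NA`).
#' @param frame_id integer frame index.
#' @return An object of class `lumen_mask`.
#' @export
lumen_mask <- function(pixels, pixel_size_um, time_point = NA_real_,
                       frame_id = NA_integer_) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  px <- matrix(as.logical(pixels != 0), nrow(pixels), ncol(pixels))
  structure(list(pixels = px,
                 pixel_size_um = as.numeric(pixel_size_um),
                 time_point = as.numeric(time_point),
                 frame_id = as.integer(frame_id)),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("<lumen_mask> %d x %d px @ %.4f um/px, %d lumen px, day %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels), format(x$time_point)))
  invisible(x)
}

#' Clean a raw binary mask
#'
#' Removes connected components (8-connectivity) smaller than
#' `min_object_px` and optionally fills interior holes (4-connected
#' background), returning a validated [lumen_mask()].
#'
#' @param raw 2D matrix with values 0 / nonzero.
#' @param min_object_px components with fewer pixels are discarded.
#' @param fill_holes fill enclosed background holes?
#' @param pixel_size_um,time_point,frame_id passed to [lumen_mask()].
#' @return A `lumen_mask`.
#' @export
clean_mask <- function(raw, min_object_px = 50L, fill_holes = TRUE,
                       pixel_size_um = 1, time_point = NA_real_,
                       frame_id = NA_integer_) {
  stopifnot(is.matrix(raw))
  px <- raw != 0
  if (!any(px)) stop("no lumen pixels: mask is empty")
  lab <- label8(px)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  px <- matrix(lab %in% keep, nrow(px), ncol(px))
  if (!any(px)) stop("no lumen pixels: all objects smaller than min_object_px")
  if (fill_holes) {
    f <- EBImage::fillHull(matrix(as.numeric(px), nrow(px), ncol(px)))
    px <- matrix(as.numeric(f) != 0, nrow(px), ncol(px))
  }
  lumen_mask(px, pixel_size_um, time_point, frame_id)
}

#' Total lumen area of a mask
#'
#' Exact count of lumen pixels and its conversion to square micrometres
#' (`area_um2 = area_px * pixel_size_um^2`). This is the total-lumen-area
#' metric used to normalise the wall-shear-stress ratio and to classify
#' remodeling stages.
#'
#' @param mask a [lumen_mask()].
#' @return A list of class `area_measurement` with `area_px`, `area_um2`,
#'   `time_point`, `frame_id`.
#' @export
measure_area <- function(mask) {
  stopifnot(inherits(mask, "lumen_mask"))
  n <- sum(mask$pixels)
  structure(list(area_px = as.integer(n),
                 area_um2 = n * mask$pixel_size_um^2,
                 time_point = mask$time_point,
                 frame_id = mask$frame_id),
            class = "area_measurement")
}

#' Otsu-threshold baseline segmentation
#'
#' A deliberately simple global-threshold baseline for converting a noisy
#' greyscale render into a binary lumen mask. Real brightfield segmentation
#' is out of scope; this utility exists so the synthetic generator's optional
#' noisy renders can be pushed through the pipeline.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param ... passed to [clean_mask()].
#' @return A `lumen_mask`.
#' @export
segment_otsu <- function(img, ...) {
  stopifnot(is.matrix(img))
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  clean_mask(matrix(as.numeric(img > thr), nrow(img), ncol(img)), ...)
}
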