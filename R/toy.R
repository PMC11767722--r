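#' Specification of a toy vessel geometry
#'
#' Deterministic fixture geometries with closed-form or symmetry-known flow,
#' used to validate the solver, the graph extraction and the pruning rule:
#'
#' * `straight_channel`: one axis-aligned rectangular channel spanning the
#'   image along its longer axis.
#' * `y_branch`: a parent channel splitting into two mirror-symmetric
#'   daughters.
#' * `lattice`: a rectangular grid of channels (`n_long` channels along the
#'   long axis crossed by `n_cross` channels).
#' * `bridge_lattice`: two parallel main channels spanning the flow
#'   direction, joined by one perpendicular bridge at mid-length — the
#'   canonical low-flow segment bridging two high-flow vessels.
#'
#' @param kind one of the four geometry kinds.
#' @param width_um channel width in micrometres.
#' @param image_shape_px integer `(rows, cols)`.
#' @param pixel_size_um pixel size in micrometres.
#' @param n_long,n_cross lattice channel counts (lattice kind only).
#' @return List of class `toy_geometry_spec`.
#' @export
toy_geometry_spec <- function(kind = c("straight_channel", "y_branch",
                                       "lattice", "bridge_lattice"),
                              width_um = 100, image_shape_px = c(64L, 256L),
                              pixel_size_um = 1.5625,
                              n_long = 3L, n_cross = 3L) {
  kind <- match.arg(kind)
  stopifnot(width_um > 0, pixel_size_um > 0, length(image_shape_px) == 2L)
  if (width_um < 4 * pixel_size_um)
    stop("width_um below resolvability: need width_um >= 4 * pixel_size_um")
  structure(list(kind = kind, width_um = width_um,
                 image_shape_px = as.integer(image_shape_px),
                 pixel_size_um = pixel_size_um,
                 n_long = as.integer(n_long), n_cross = as.integer(n_cross)),
            class = "toy_geometry_spec")
}

#' Generate a toy geometry mask
#'
#' Renders the [toy_geometry_spec()] as a binary lumen mask. Channels span
#' the image's longer axis border-to-border so every flow-bearing kind is
#' perfusable; for flow solves, set the [flow_config()] `flow_axis` to the
#' longer image axis.
#'
#' @param spec a [toy_geometry_spec()].
#' @return A [lumen_mask()].
#' @export
generate_toy_geometry <- function(spec) {
  stopifnot(inherits(spec, "toy_geometry_spec"))
  nr <- spec$image_shape_px[1]; nc <- spec$image_shape_px[2]
  wpx <- round(spec$width_um / spec$pixel_size_um)
  px <- matrix(FALSE, nr, nc)
  along_cols <- nc >= nr   # channel axis = longer image axis
  ## work in (long, cross) coordinates, transpose at the end if needed
  L <- if (along_cols) nc else nr
  Wd <- if (along_cols) nr else nc
  m <- matrix(FALSE, Wd, L)   # rows = cross axis, cols = long axis
  band <- function(center, width) {
    lo <- max(1L, floor(center - width / 2 + 1))
    hi <- min(Wd, lo + width - 1L)
    lo:hi
  }
  mid <- (Wd + 1) / 2
  if (spec$kind == "straight_channel") {
    m[band(mid, wpx), ] <- TRUE
  } else if (spec$kind == "y_branch") {
    split_at <- round(L / 3)
    m[band(mid, wpx), 1:split_at] <- TRUE
    offset <- round(Wd / 4)
    m <- stamp_segment(m, mid, split_at, mid - offset, L, wpx)
    m <- m | m[rev(seq_len(Wd)), ]    # transverse mirror: exact symmetry
  } else if (spec$kind == "lattice") {
    ctrs_long <- round(seq(wpx / 2 + 1, Wd - wpx / 2, length.out = spec$n_long))
    for (ctr in ctrs_long) m[band(ctr, wpx), ] <- TRUE
    ctrs_cross <- round(seq(L / (spec$n_cross + 1), L * spec$n_cross / (spec$n_cross + 1),
                            length.out = spec$n_cross))
    span <- (min(ctrs_long) - floor(wpx / 2)):(max(ctrs_long) + floor(wpx / 2))
    span <- span[span >= 1 & span <= Wd]
    for (ctr in ctrs_cross) {
      lo <- max(1L, floor(ctr - wpx / 2 + 1)); hi <- min(L, lo + wpx - 1L)
      m[span, lo:hi] <- TRUE
    }
  } else { # bridge_lattice
    ctrs <- round(c(Wd / 4, 3 * Wd / 4))
    for (ctr in ctrs) m[band(ctr, wpx), ] <- TRUE
    lo <- max(1L, floor(L / 2 - wpx / 2 + 1)); hi <- min(L, lo + wpx - 1L)
    span <- (min(ctrs)):(max(ctrs))
    m[span, lo:hi] <- TRUE
  }
  px <- if (along_cols) m else t(m)
  stopifnot(all(dim(px) == c(nr, nc)))
  lumen_mask(px, spec$pixel_size_um)
}
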