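# Internal raster helpers shared across modules.

## Value of the 8-neighbour at offset (dr, dc); zero outside the image.
nb_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  vr <- ri >= 1L & ri <= nr
  vc <- ci >= 1L & ci <= nc
  if (any(vr) && any(vc))
    out[which(vr), which(vc)] <- m[ri[vr], ci[vc]]
  out
}

NBR8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
NBR4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

## Count of TRUE 8-neighbours for every pixel.
neighbour_count8 <- function(px) {
  s <- matrix(0, nrow(px), ncol(px))
  for (k in seq_len(nrow(NBR8))) s <- s + nb_shift(px, NBR8[k, 1], NBR8[k, 2])
  s
}

## 8-connected labelling: 4-connected pass (EBImage) then merge labels that
## touch diagonally. Standard digital-topology pairing: 8-connectivity for
## foreground objects, 4-connectivity for background.
label8 <- function(px) {
  m <- matrix(as.numeric(px), nrow(px), ncol(px))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  n <- max(lab)
  if (n <= 1L) return(lab)
  pairs <- NULL
  for (d in list(c(-1L, -1L), c(-1L, 1L))) {
    b <- nb_shift(lab, d[1], d[2])
    sel <- lab > 0L & b > 0L & lab != b
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(unique(pairs)))
  memb <- igraph::components(g)$membership
  out <- lab
  out[lab > 0L] <- as.integer(memb[lab[lab > 0L]])
  out
}

## Euclidean distance (in px) from each foreground pixel to the nearest
## background pixel. The image frame counts as wall (background padding),
## except along `open_axis` ("rows": top/bottom borders, "cols": left/right)
## where the lumen continues into the perfusion ports and the border row is
## replicated instead.
distance_map <- function(px, open_axis = NULL) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  if (!is.null(open_axis)) {
    if (open_axis == "rows") {
      pad[1L, 2:(nc + 1L)] <- px[1L, ]
      pad[nr + 2L, 2:(nc + 1L)] <- px[nr, ]
    } else {
      pad[2:(nr + 1L), 1L] <- px[, 1L]
      pad[2:(nr + 1L), nc + 2L] <- px[, nc]
    }
  }
  d <- EBImage::distmap(pad)
  matrix(as.numeric(d), nr + 2L, nc + 2L)[2:(nr + 1L), 2:(nc + 1L)]
}

## Bilinear interpolation of a matrix at fractional (row, col) positions.
## Cell centres sit at integer coordinates; values clamp at the borders.
interp2 <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

## Draw a thick line segment into a logical mask (disc-stamped Bresenham-ish
## walk); endpoints in (row, col) pixel coordinates, width in pixels.
stamp_segment <- function(px, r0, c0, r1, c1, width_px) {
  nr <- nrow(px); nc <- ncol(px)
  len <- max(abs(r1 - r0), abs(c1 - c0), 1)
  ts <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
  rad <- max(width_px / 2, 0.5)
  ir <- ceiling(rad)
  dd <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  dd <- dd[dd$dr^2 + dd$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
  rs <- round(r0 + ts * (r1 - r0))
  cs <- round(c0 + ts * (c1 - c0))
  keep <- !duplicated(cbind(rs, cs))
  rs <- rs[keep]; cs <- cs[keep]
  allr <- rep(rs, each = nrow(dd)) + dd$dr
  allc <- rep(cs, each = nrow(dd)) + dd$dc
  ok <- allr >= 1 & allr <= nr & allc >= 1 & allc <= nc
  px[cbind(allr[ok], allc[ok])] <- TRUE
  px
}

## TRUE where a lumen pixel has at least one 4-neighbour that is wall.
## Beyond the image frame counts as wall, except along `open_axis` where the
## borders are the open perfusion ports.
wall_pixels <- function(px, open_axis = NULL) {
  nr <- nrow(px); nc <- ncol(px)
  w <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(NBR4))) {
    dr <- NBR4[k, 1]; dc <- NBR4[k, 2]
    nbv <- nb_shift(px, dr, dc)
    inside <- nb_inside(px, dr, dc)
    outside_is_wall <- !inside
    if (!is.null(open_axis)) {
      if (open_axis == "rows" && dc == 0) outside_is_wall[] <- FALSE
      if (open_axis == "cols" && dr == 0) outside_is_wall[] <- FALSE
      outside_is_wall <- outside_is_wall & !inside
    }
    w <- w | (px & ((inside & !nbv) | outside_is_wall))
  }
  w
}

## TRUE where the neighbour at offset (dr, dc) lies inside the image.
nb_inside <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- matrix(seq_len(nr) + dr, nr, nc)
  ci <- matrix(rep(seq_len(nc) + dc, each = nr), nr, nc)
  ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
}
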