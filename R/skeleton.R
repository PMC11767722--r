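#' Skeletonize a lumen mask
#'
#' Homotopic thinning of the lumen to a one-pixel-wide medial representation
#' (vectorized Zhang–Suen parallel thinning, which preserves the mask's
#' connected components and cycles), followed by pruning of terminal spurs
#' shorter than `spur_min_px`. The Euclidean distance map is computed on the
#' original (unpruned) mask so skeleton values give the local lumen
#' half-width in pixels.
#'
#' @param mask a [lumen_mask()].
#' @param spur_min_px terminal branches strictly shorter than this (and ending
#'   at a junction) are removed.
#' @return An object of class `vf_skeleton`: list with `pixels` (logical
#'   matrix), `distance` (px units), `pixel_size_um`, `degenerate` flag.
#' @export
skeletonize_mask <- function(mask, spur_min_px = 5L) {
  stopifnot(inherits(mask, "lumen_mask"))
  px <- mask$pixels
  if (!any(px)) stop("cannot skeletonize an empty mask")
  dm <- distance_map(px)
  sk <- thin_zhang_suen(px)
  sk <- remove_redundant_px(sk)
  sk <- prune_spurs(sk, spur_min_px)
  structure(list(pixels = sk, distance = dm,
                 pixel_size_um = mask$pixel_size_um,
                 degenerate = sum(sk) <= spur_min_px),
            class = "vf_skeleton")
}

## Zhang–Suen parallel thinning, vectorized over the whole image.
## Neighbours p2..p9 clockwise from north; a pixel is deleted when it has
## 2..6 foreground neighbours, exactly one 0->1 transition around the ring,
## and passes the sub-iteration's directional conditions.
thin_zhang_suen <- function(px) {
  P <- matrix(as.numeric(px), nrow(px), ncol(px))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- nb_shift(P, -1, 0);  p3 <- nb_shift(P, -1, 1)
      p4 <- nb_shift(P, 0, 1);   p5 <- nb_shift(P, 1, 1)
      p6 <- nb_shift(P, 1, 0);   p7 <- nb_shift(P, 1, -1)
      p8 <- nb_shift(P, 0, -1);  p9 <- nb_shift(P, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
           (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
      if (sub == 1L) {
        cond <- (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      del <- P > 0 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        P[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P > 0
}

## Yokoi connectivity number for 8-connected foreground at one pixel: the
## number of foreground components its removal would locally split into.
## 1 means the pixel is simple (removable without topology change).
yokoi8_at <- function(px, r, c) {
  val <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nrow(px) || cc < 1 || cc > ncol(px)) 0L
    else as.integer(px[rr, cc])
  }
  ## cyclic neighbour order: E, NE, N, NW, W, SW, S, SE
  n <- c(val(0, 1), val(-1, 1), val(-1, 0), val(-1, -1),
         val(0, -1), val(1, -1), val(1, 0), val(1, 1))
  x <- 1L - n
  s <- 0L
  for (k in c(1L, 3L, 5L, 7L)) {
    k1 <- (k %% 8L) + 1L; k2 <- ((k + 1L) %% 8L) + 1L
    s <- s + x[k] - x[k] * x[k1] * x[k2]
  }
  s
}

## Sequentially delete simple pixels with >= 2 neighbours: parallel thinning
## leaves redundant staircase pixels on diagonal runs, which would otherwise
## masquerade as degree-3 junctions. Interior pixels of a minimal line have
## two mutually non-adjacent neighbours (Yokoi number 2) and survive;
## endpoints (degree 1) are never touched.
remove_redundant_px <- function(sk) {
  repeat {
    deg <- neighbour_count8(sk)
    cand <- which(sk & deg >= 2, arr.ind = TRUE)
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (!sk[r, c]) next
      if (neighbour_count8_at(sk, r, c) < 2L) next
      if (yokoi8_at(sk, r, c) == 1L) {
        sk[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

## Remove terminal spurs: walk from each endpoint along degree-2 pixels; if a
## junction (degree >= 3) is reached within spur_min_px steps the walked
## pixels are spur artefacts of thinning and are deleted. Repeats until
## stable so that nested spurs collapse.
prune_spurs <- function(sk, spur_min_px) {
  if (spur_min_px <= 0L) return(sk)
  repeat {
    deg <- neighbour_count8(sk)
    ends <- which(sk & deg == 1, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      r <- ends[i, 1]; c <- ends[i, 2]
      if (!sk[r, c] || neighbour_count8_at(sk, r, c) != 1L) next
      chain <- matrix(c(r, c), 1, 2)
      prev <- c(-1L, -1L)
      hit_junction <- FALSE
      while (nrow(chain) < spur_min_px) {
        cur <- chain[nrow(chain), ]
        nbrs <- neighbours_of(sk, cur[1], cur[2])
        nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nbrs) == 0L) break
        if (nrow(nbrs) > 1L) { hit_junction <- TRUE; break }
        nxt <- nbrs[1, ]
        if (neighbour_count8_at(sk, nxt[1], nxt[2]) >= 3L) { hit_junction <- TRUE; break }
        prev <- cur
        chain <- rbind(chain, nxt)
      }
      if (hit_junction && nrow(chain) < spur_min_px) {
        sk[chain] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

neighbour_count8_at <- function(px, r, c) {
  nr <- nrow(px); nc <- ncol(px)
  rr <- pmax(1L, r - 1L):pmin(nr, r + 1L)
  cc <- pmax(1L, c - 1L):pmin(nc, c + 1L)
  sum(px[rr, cc]) - px[r, c]
}

neighbours_of <- function(px, r, c) {
  rr <- r + NBR8[, 1]; cc <- c + NBR8[, 2]
  ok <- rr >= 1 & rr <= nrow(px) & cc >= 1 & cc <= ncol(px)
  rr <- rr[ok]; cc <- cc[ok]
  on <- px[cbind(rr, cc)]
  cbind(rr[on], cc[on])
}
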