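#' Flow configuration
#'
#' Physical parameters of the perfusion. Defaults follow typical
#' capillary-scale culture conditions: medium viscosity 1e-3 Pa s and mean
#' inlet velocity 1e-4 m/s; `d_ch` is the distance between the two pillar
#' rows bounding the chamber along the flow direction (2 mm). `w_inlet` is
#' the physical inlet width in metres; when `NA` it is derived from the
#' inlet-port footprint at domain construction.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param U_inlet mean inlet velocity (m/s).
#' @param w_inlet inlet width (m) or `NA` to derive from the mask.
#' @param d_ch chamber length along the flow direction (m).
#' @param flow_axis `"rows"` (top to bottom, default) or `"cols"`.
#' @param rtau_grouping normalisation grouping of the wall-shear ratio; see
#'   [weight_graph()].
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(mu = 1e-3, U_inlet = 1e-4, w_inlet = NA_real_,
                        d_ch = 2e-3, flow_axis = c("rows", "cols"),
                        rtau_grouping = c("per_area", "flat")) {
  flow_axis <- match.arg(flow_axis)
  rtau_grouping <- match.arg(rtau_grouping)
  stopifnot(mu > 0, U_inlet > 0, d_ch > 0, is.na(w_inlet) || w_inlet > 0)
  structure(list(mu = mu, U_inlet = U_inlet, w_inlet = w_inlet, d_ch = d_ch,
                 flow_axis = flow_axis, rtau_grouping = rtau_grouping),
            class = "flow_config")
}

#' Build the flow domain for a lumen mask
#'
#' Attaches rectangular inlet and outlet port channels flush to the image
#' borders along the flow axis. Each port spans the lumen's footprint on that
#' border (min to max lumen pixel). Connected components of the lumen are
#' classified as flow-bearing (on an inlet-outlet path) or no-flow.
#'
#' @param mask a [lumen_mask()].
#' @param config a [flow_config()].
#' @param port_length_px length of the attached port channels in pixels;
#'   long enough for the parabolic inlet profile to develop.
#' @param require_path error when the lumen touches neither border along the
#'   flow axis (the default); `FALSE` returns a flagged no-flow domain
#'   instead, so early vasculogenic frames without a perfusion path can
#'   still move through the pipeline with zero weights.
#' @return An object of class `flow_domain`.
#' @export
build_domain <- function(mask, config, port_length_px = 20L,
                         require_path = TRUE) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(config, "flow_config"))
  px <- mask$pixels
  transposed <- config$flow_axis == "cols"
  if (transposed) px <- t(px)
  nr <- nrow(px); nc <- ncol(px)
  in_cols <- which(px[1, ])
  out_cols <- which(px[nr, ])
  if (length(in_cols) == 0L && length(out_cols) == 0L) {
    if (require_path)
      stop("no perfusion path: lumen touches neither border along the flow axis")
    return(structure(list(fluid = NULL, comp = NULL,
                          mask_comp = matrix(0L, nrow(mask$pixels), ncol(mask$pixels)),
                          solve_comp = integer(0),
                          flow_bearing_labels = integer(0),
                          inlet_cols = integer(0), outlet_cols = integer(0),
                          port_len = as.integer(port_length_px),
                          transposed = transposed,
                          mask_dim = dim(mask$pixels),
                          pixel_size_um = mask$pixel_size_um,
                          flow_ok = FALSE),
                     class = "flow_domain"))
  }
  if (length(in_cols) == 0L) in_cols <- out_cols
  if (length(out_cols) == 0L) out_cols <- in_cols
  in_cols <- seq(min(in_cols), max(in_cols))
  out_cols <- seq(min(out_cols), max(out_cols))

  pl <- as.integer(port_length_px)
  fluid <- matrix(FALSE, nr + 2L * pl, nc)
  fluid[pl + seq_len(nr), ] <- px
  fluid[seq_len(pl), in_cols] <- TRUE
  fluid[pl + nr + seq_len(pl), out_cols] <- TRUE

  comp <- label8(fluid)
  inlet_comp <- unique(comp[1, in_cols])
  outlet_comp <- unique(comp[nrow(fluid), out_cols])
  flow_ok <- length(intersect(inlet_comp, outlet_comp)) > 0L
  solve_comp <- union(inlet_comp, outlet_comp)
  mask_comp <- comp[pl + seq_len(nr), , drop = FALSE]
  flow_bearing_labels <- intersect(inlet_comp, outlet_comp)

  structure(list(fluid = fluid, comp = comp, mask_comp = mask_comp,
                 solve_comp = solve_comp,
                 flow_bearing_labels = flow_bearing_labels,
                 inlet_cols = in_cols, outlet_cols = out_cols,
                 port_len = pl, transposed = transposed,
                 mask_dim = dim(mask$pixels),
                 pixel_size_um = mask$pixel_size_um,
                 flow_ok = flow_ok),
            class = "flow_domain")
}

#' Solve steady creeping flow on a lumen domain
#'
#' Steady incompressible Stokes flow on the pixel lattice (MAC staggered
#' grid): no-slip walls, parabolic inlet profile with prescribed mean
#' velocity, and an open outlet (zero normal velocity gradient with the
#' pressure level pinned to zero in the outlet port). Inertia is neglected:
#' at these velocities and length scales the Reynolds number is ~1e-2, where
#' the Stokes and Navier-Stokes solutions coincide. Incompressibility is
#' enforced through a divergence penalty on the compatible staggered
#' operators, giving a symmetric positive-definite system solved by sparse
#' Cholesky factorisation.
#'
#' @param domain a [build_domain()] result.
#' @param config a [flow_config()].
#' @param penalty dimensionless divergence penalty (1/epsilon).
#' @return Object of class `flow_field` with mask-aligned cell-centred
#'   velocity components `Vrow`, `Vcol` (m/s), `div_max` residual, inlet
#'   flux `Q_in` (m^2/s per unit depth), effective `w_inlet` (m), and the
#'   originating domain.
#' @export
solve_flow <- function(domain, config, penalty = 1e8) {
  stopifnot(inherits(domain, "flow_domain"), inherits(config, "flow_config"))
  h <- domain$pixel_size_um * 1e-6
  w_in <- if (is.na(config$w_inlet)) length(domain$inlet_cols) * h else config$w_inlet
  md <- domain$mask_dim
  empty <- function() {
    z <- matrix(0, md[1], md[2])
    structure(list(Vrow = z, Vcol = z, div_max = 0,
                   Q_in = 0, w_inlet = w_in, h_m = h, config = config,
                   domain = domain, no_flow = TRUE),
              class = "flow_field")
  }
  if (!domain$flow_ok) return(empty())

  Fm <- domain$fluid & matrix(domain$comp %in% domain$solve_comp,
                              nrow(domain$comp), ncol(domain$comp))
  sol <- stokes_mac(Fm, domain$inlet_cols, penalty)

  ## cell-centred velocities on the extended grid (dimensionless, mean inlet 1)
  nr <- nrow(Fm); nc <- ncol(Fm)
  Vc_row <- (sol$Vfull[1:nr, , drop = FALSE] + sol$Vfull[2:(nr + 1), , drop = FALSE]) / 2
  Vc_col <- (sol$Ufull[, 1:nc, drop = FALSE] + sol$Ufull[, 2:(nc + 1), drop = FALSE]) / 2

  pl <- domain$port_len
  rows <- pl + seq_len(if (domain$transposed) md[2] else md[1])
  Vr <- Vc_row[rows, , drop = FALSE] * config$U_inlet
  Vc <- Vc_col[rows, , drop = FALSE] * config$U_inlet
  if (domain$transposed) {
    tmp <- t(Vr); Vr2 <- t(Vc); Vc2 <- tmp
    Vr <- Vr2; Vc <- Vc2
  }
  structure(list(Vrow = Vr, Vcol = Vc, div_max = sol$div_max,
                 Q_in = config$U_inlet * w_in, w_inlet = w_in, h_m = h,
                 config = config, domain = domain, no_flow = FALSE),
            class = "flow_field")
}

## MAC staggered-grid Stokes, dimensionless (h = 1, mu = 1, mean inlet
## velocity = 1), flow along rows (top to bottom). Returns full u/v face
## arrays including boundary values.
stokes_mac <- function(F, inlet_cols, penalty = 1e8) {
  nr <- nrow(F); nc <- ncol(F)
  Uact <- matrix(FALSE, nr, nc + 1L)
  if (nc >= 2L) Uact[, 2:nc] <- F[, 1:(nc - 1), drop = FALSE] & F[, 2:nc, drop = FALSE]
  Vact <- matrix(FALSE, nr + 1L, nc)
  Vact[2:nr, ] <- F[1:(nr - 1), , drop = FALSE] & F[2:nr, , drop = FALSE]
  nu <- sum(Uact); nv <- sum(Vact)
  Uidx <- matrix(0L, nr, nc + 1L); Uidx[Uact] <- seq_len(nu)
  Vidx <- matrix(0L, nr + 1L, nc); Vidx[Vact] <- nu + seq_len(nv)
  n <- nu + nv
  if (n == 0L) stop("flow solve on a degenerate (zero-face) domain")

  w <- length(inlet_cols)
  xi <- (seq_len(w) - 0.5) / w
  vin <- numeric(nc)
  vin[inlet_cols] <- 6 * xi * (1 - xi)          # parabolic, mean 1

  ti <- list(); tj <- list(); tx <- list(); blk <- 0L
  add <- function(i, j, x) {
    blk <<- blk + 1L
    ti[[blk]] <<- i; tj[[blk]] <<- j; tx[[blk]] <<- x
  }
  rhs <- numeric(n)

  ## ---- u momentum (tangential ghosts fold -1 into the diagonal) ----
  uw <- which(Uact, arr.ind = TRUE)
  if (nu > 0L) {
    pid <- Uidx[Uact]
    diagc <- rep(-4, nu)
    for (dj in c(-1L, 1L)) {
      jj <- uw[, 2] + dj
      ok <- jj >= 1L & jj <= nc + 1L
      nbi <- rep(0L, nu)
      nbi[ok] <- Uidx[cbind(uw[ok, 1], jj[ok])]
      has <- nbi > 0L
      if (any(has)) add(pid[has], nbi[has], rep(1, sum(has)))
      ## inactive u neighbour in the normal direction lies on a wall: u = 0
    }
    for (di in c(-1L, 1L)) {
      ii <- uw[, 1] + di
      inside <- ii >= 1L & ii <= nr
      nbi <- rep(0L, nu)
      nbi[inside] <- Uidx[cbind(ii[inside], uw[inside, 2])]
      has <- nbi > 0L
      if (any(has)) add(pid[has], nbi[has], rep(1, sum(has)))
      ghost_wall <- (inside & nbi == 0L) | (!inside & ii == 0L)  # no-slip / inlet line
      ghost_out <- !inside & ii == nr + 1L                       # outlet: du/dn = 0
      diagc[ghost_wall] <- diagc[ghost_wall] - 1
      diagc[ghost_out] <- diagc[ghost_out] + 1
    }
    add(pid, pid, diagc)
  }

  ## ---- v momentum ----
  vw <- which(Vact, arr.ind = TRUE)
  pidv <- Vidx[Vact]
  diagv <- rep(-4, nv)
  for (di in c(-1L, 1L)) {
    ii <- vw[, 1] + di
    inside <- ii >= 2L & ii <= nr
    nbi <- rep(0L, nv)
    nbi[inside] <- Vidx[cbind(ii[inside], vw[inside, 2])]
    has <- nbi > 0L
    if (any(has)) add(pidv[has], nbi[has], rep(1, sum(has)))
    isin <- ii == 1L                              # prescribed inlet face
    if (any(isin)) rhs[pidv[isin]] <- rhs[pidv[isin]] - vin[vw[isin, 2]]
    isout <- ii == nr + 1L & F[cbind(pmin(vw[, 1], nr), vw[, 2])] & ii == nr + 1L
    diagv[isout] <- diagv[isout] + 1              # outlet ghost: dv/dn = 0
  }
  for (dj in c(-1L, 1L)) {
    jj <- vw[, 2] + dj
    inside <- jj >= 1L & jj <= nc
    nbi <- rep(0L, nv)
    nbi[inside] <- Vidx[cbind(vw[inside, 1], jj[inside])]
    has <- nbi > 0L
    if (any(has)) add(pidv[has], nbi[has], rep(1, sum(has)))
    ghost <- nbi == 0L
    diagv[ghost] <- diagv[ghost] - 1
  }
  add(pidv, pidv, diagv)

  L <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n))

  ## ---- divergence rows: all fluid cells except the outlet port row ----
  cw <- which(F & row(F) < nr, arr.ind = TRUE)
  m <- nrow(cw)
  rid <- seq_len(m)
  di_ <- list(); dj_ <- list(); dx_ <- list(); dblk <- 0L
  addD <- function(i, j, x) {
    dblk <<- dblk + 1L
    di_[[dblk]] <<- i; dj_[[dblk]] <<- j; dx_[[dblk]] <<- x
  }
  d0 <- numeric(m)
  ue <- Uidx[cbind(cw[, 1], cw[, 2] + 1L)]
  has <- ue > 0L; if (any(has)) addD(rid[has], ue[has], rep(1, sum(has)))
  uw_ <- Uidx[cbind(cw[, 1], cw[, 2])]
  has <- uw_ > 0L; if (any(has)) addD(rid[has], uw_[has], rep(-1, sum(has)))
  vs <- Vidx[cbind(cw[, 1] + 1L, cw[, 2])]
  has <- vs > 0L; if (any(has)) addD(rid[has], vs[has], rep(1, sum(has)))
  vn <- Vidx[cbind(cw[, 1], cw[, 2])]
  has <- vn > 0L; if (any(has)) addD(rid[has], vn[has], rep(-1, sum(has)))
  isrow1 <- cw[, 1] == 1L
  d0[isrow1] <- d0[isrow1] - vin[cw[isrow1, 2]]
  D <- Matrix::sparseMatrix(i = unlist(di_), j = unlist(dj_), x = unlist(dx_),
                            dims = c(m, n))

  A <- Matrix::forceSymmetric(-L + penalty * Matrix::crossprod(D))
  b <- -rhs - penalty * as.vector(Matrix::crossprod(D, d0))
  x <- as.vector(Matrix::solve(A, b))

  Ufull <- matrix(0, nr, nc + 1L); Ufull[Uact] <- x[seq_len(nu)]
  Vfull <- matrix(0, nr + 1L, nc); Vfull[Vact] <- x[nu + seq_len(nv)]
  Vfull[1, ] <- vin * F[1, ]                        # prescribed inlet faces
  Vfull[nr + 1L, F[nr, ]] <- Vfull[nr, F[nr, ]]     # outlet ghost
  div_max <- max(abs(as.vector(D %*% x) + d0))
  list(Ufull = Ufull, Vfull = Vfull, div_max = div_max)
}

#' Wall shear stress along the lumen walls
#'
#' For each wall pixel (lumen pixel with a background 4-neighbour) the
#' inward unit normal is taken from the distance-map gradient, and the
#' tangential velocity is sampled at the pixel centre and one pixel further
#' along the normal. With the no-slip surface half a pixel outside the wall
#' pixel centre, a two-point fit of `u_t = a y + b y^2` through the wall
#' (exact for a parabolic profile) gives the wall-normal velocity gradient
#' `a`, and `tau = mu * |a|`.
#'
#' @param field a [solve_flow()] result.
#' @param mask the [lumen_mask()] the field was solved on.
#' @return Object of class `wall_shear_map`: data.frame `wall`
#'   (`row`, `col`, `tau` (Pa), `nr_`, `nc_` unit normal, `flagged`), plus
#'   `tau_img` matrix for region masking.
#' @export
compute_wss <- function(field, mask) {
  stopifnot(inherits(field, "flow_field"), inherits(mask, "lumen_mask"))
  px <- mask$pixels
  open_axis <- field$config$flow_axis
  dm <- distance_map(px, open_axis)
  w <- which(wall_pixels(px, open_axis), arr.ind = TRUE)
  h <- field$h_m
  mu <- field$config$mu
  n <- nrow(w)
  tau <- numeric(n); nr_ <- numeric(n); nc_ <- numeric(n)
  flagged <- logical(n)
  if (n > 0L) {
    gr <- (nb_shift(dm, 1, 0) - nb_shift(dm, -1, 0)) / 2
    gc <- (nb_shift(dm, 0, 1) - nb_shift(dm, 0, -1)) / 2
    g1 <- gr[w]; g2 <- gc[w]
    nrm <- sqrt(g1^2 + g2^2)
    flagged <- nrm < 1e-9
    g1[flagged] <- 0; g2[flagged] <- 0
    nrm[flagged] <- 1
    nr_ <- g1 / nrm; nc_ <- g2 / nrm
    ## samples at the wall pixel centre (y1 = 0.5 px from the wall) and one
    ## pixel inward (y2 = 1.5 px)
    ut <- function(r, c) {
      vr <- interp2(field$Vrow, r, c)
      vc <- interp2(field$Vcol, r, c)
      dot <- vr * nr_ + vc * nc_
      tr <- vr - dot * nr_
      tc <- vc - dot * nc_
      sqrt(tr^2 + tc^2)
    }
    u1 <- ut(w[, 1], w[, 2])
    u2 <- ut(w[, 1] + nr_, w[, 2] + nc_)
    a <- (9 * u1 - u2) / (3 * h)
    tau <- mu * abs(a)
    tau[flagged] <- 0
  }
  tau_img <- matrix(0, nrow(px), ncol(px))
  tau_img[w] <- tau
  structure(list(wall = data.frame(row = w[, 1], col = w[, 2], tau = tau,
                                   nr_ = nr_, nc_ = nc_, flagged = flagged),
                 tau_img = tau_img),
            class = "wall_shear_map")
}

#' Volumetric flux through a cross-section
#'
#' Integrates the velocity component along `tangent` across the local lumen
#' width, walking from `center_rc` in both directions perpendicular to
#' `tangent` in half-pixel steps until leaving the lumen. Returns the signed
#' flux in m^2/s per unit depth (sign relative to `tangent`).
#'
#' @param field a [solve_flow()] result.
#' @param mask the [lumen_mask()].
#' @param center_rc numeric `(row, col)` on the vessel centreline.
#' @param tangent numeric `(drow, dcol)` local vessel direction (any length).
#' @return Signed flux (m^2/s).
#' @export
edge_flux <- function(field, mask, center_rc, tangent) {
  stopifnot(inherits(field, "flow_field"))
  t_ <- tangent / sqrt(sum(tangent^2))
  n_ <- c(-t_[2], t_[1])
  px <- mask$pixels
  inside <- function(p) {
    r <- round(p[1]); c <- round(p[2])
    r >= 1 && r <= nrow(px) && c >= 1 && c <= ncol(px) && px[r, c]
  }
  if (!inside(center_rc)) stop("cross-section centre is outside the lumen")
  step <- 0.5
  samp <- function(p) {
    interp2(field$Vrow, p[1], p[2]) * t_[1] +
      interp2(field$Vcol, p[1], p[2]) * t_[2]
  }
  total <- samp(center_rc)
  for (sgn in c(-1, 1)) {
    s <- step
    repeat {
      p <- center_rc + sgn * s * n_
      if (!inside(p)) break
      total <- total + samp(p)
      s <- s + step
    }
  }
  total * step * field$h_m
}
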