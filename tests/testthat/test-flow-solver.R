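# Poiseuille fixtures reused across several checks
poiseuille_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                                   c(64L, 256L), 1.5625))
      cfg <- flow_config(mu = 1e-3, U_inlet = 1e-4, flow_axis = "cols")
      f <- solve_flow(build_domain(m, cfg), cfg)
      cache <<- list(m = m, cfg = cfg, f = f)
    }
    cache
  }
})

test_that("plane Poiseuille: centerline velocity and wall shear match closed form", {
  s <- poiseuille_setup()
  vc <- s$f$Vcol[, 128]
  expect_lt(abs(max(vc) / (1.5 * 1e-4) - 1), 0.03)
  wss <- compute_wss(s$f, s$m)
  mid <- wss$wall[wss$wall$col > 60 & wss$wall$col < 200, ]
  tau_exact <- 6 * 1e-3 * 1e-4 / 1e-4        # 6 mu U / w = 6e-3 Pa
  expect_lt(abs(mean(mid$tau) / tau_exact - 1), 0.05)
  expect_true(all(wss$wall$tau >= 0))
})

test_that("mass is conserved globally and along the channel", {
  s <- poiseuille_setup()
  Q_in <- s$f$Q_in
  q25 <- edge_flux(s$f, s$m, c(32.5, 64), c(0, 1))
  q75 <- edge_flux(s$f, s$m, c(32.5, 192), c(0, 1))
  expect_lt(abs(q25 / Q_in - 1), 0.01)
  expect_lt(abs(q75 / Q_in - 1), 0.01)
  expect_lt(abs(q25 - q75) / abs(Q_in), 0.01)
  expect_lt(s$f$div_max, 1e-6)
})

test_that("mirror-symmetric y-branch splits flow 50/50 and balances the junction", {
  m <- generate_toy_geometry(toy_geometry_spec("y_branch", 40,
                                               c(128L, 256L), 1.5625))
  cfg <- flow_config(flow_axis = "cols")
  a <- analyze_mask(m, cfg)
  rq <- vapply(a$wgraph$edges, function(e) e$R_Q, numeric(1))
  qs <- vapply(a$wgraph$edges, function(e) abs(e$Q_signed), numeric(1))
  parent <- which.max(qs)
  daughters <- setdiff(seq_along(qs), parent)
  expect_lt(abs(qs[daughters[1]] / qs[daughters[2]] - 1), 0.02)
  expect_lt(abs((qs[daughters[1]] + qs[daughters[2]]) / qs[parent] - 1), 0.01)
  expect_lt(abs(rq[parent] - 1), 0.02)
  expect_true(all(abs(rq[daughters] - 0.5) < 0.01))
})

test_that("velocity, flux and shear scale linearly with the inlet velocity", {
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 128L), 1.5625))
  cfg1 <- flow_config(U_inlet = 1e-4, flow_axis = "cols")
  cfg3 <- flow_config(U_inlet = 3e-4, flow_axis = "cols")
  f1 <- solve_flow(build_domain(m, cfg1), cfg1)
  f3 <- solve_flow(build_domain(m, cfg3), cfg3)
  expect_equal(f3$Vcol, 3 * f1$Vcol, tolerance = 1e-9)
  t1 <- compute_wss(f1, m)$wall$tau
  t3 <- compute_wss(f3, m)$wall$tau
  expect_equal(t3, 3 * t1, tolerance = 1e-9)
})

test_that("doubling viscosity doubles wall shear stress at fixed velocities", {
  m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                               c(64L, 128L), 1.5625))
  cfg1 <- flow_config(mu = 1e-3, flow_axis = "cols")
  cfg2 <- flow_config(mu = 2e-3, flow_axis = "cols")
  f1 <- solve_flow(build_domain(m, cfg1), cfg1)
  f2 <- solve_flow(build_domain(m, cfg2), cfg2)
  ## creeping flow with velocity BCs: the velocity field is mu-independent
  expect_equal(f2$Vcol, f1$Vcol, tolerance = 1e-9)
  expect_equal(compute_wss(f2, m)$wall$tau, 2 * compute_wss(f1, m)$wall$tau,
               tolerance = 1e-9)
})

test_that("wall shear error shrinks monotonically under grid refinement", {
  errs <- vapply(c(16L, 32L, 64L), function(wpx) {
    pu <- 100 / wpx
    m <- generate_toy_geometry(toy_geometry_spec("straight_channel", 100,
                                                 c(wpx, 4L * wpx), pu))
    cfg <- flow_config(flow_axis = "cols")
    f <- solve_flow(build_domain(m, cfg), cfg)
    wss <- compute_wss(f, m)
    mid <- wss$wall[wss$wall$col > wpx & wss$wall$col < 3L * wpx, ]
    abs(mean(mid$tau) / 6e-3 - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("degenerate domains are flagged rather than solved", {
  ## lumen touching neither border
  island <- matrix(FALSE, 64, 64)
  island[20:40, 20:40] <- TRUE
  mi <- lumen_mask(island, 7.8125)
  expect_error(build_domain(mi, flow_config()), "no perfusion path")
  dom <- build_domain(mi, flow_config(), require_path = FALSE)
  expect_false(dom$flow_ok)
  f <- solve_flow(dom, flow_config())
  expect_true(f$no_flow)
  expect_true(all(f$Vrow == 0))
  expect_true(all(compute_wss(f, mi)$wall$tau == 0))

  ## an isolated island next to a perfused channel is excluded from the flow
  both <- matrix(FALSE, 64, 64)
  both[, 5:12] <- TRUE
  both[25:35, 40:50] <- TRUE
  mb <- lumen_mask(both, 7.8125)
  domb <- build_domain(mb, flow_config())
  expect_true(domb$flow_ok)
  fb <- solve_flow(domb, flow_config())
  expect_true(all(abs(fb$Vrow[25:35, 40:50]) == 0))
  expect_gt(max(abs(fb$Vrow[, 5:12])), 0)
})
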