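test_that("the unloaded reference state is an exact equilibrium", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  s <- solve_equilibrium(m, f$vec, NULL, p_lv = 0)
  expect_lt(max(abs(s$u)), 1e-12)
})

test_that("a uniform stretch patch solution is reproduced to machine precision", {
  tb <- mesh_tube(r_in = 10, r_out = 14, len = 4, nr = 1, nl = 1)
  n <- nrow(tb$plane$nodes)
  fib <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  lam_r <- 1.05; lam_z <- 0.97
  u_exact <- numeric(3 * n)
  u_exact[seq(1, 3 * n, 3)] <- (lam_r - 1) * tb$plane$nodes[, 1]
  u_exact[seq(3, 3 * n, 3)] <- (lam_z - 1) * tb$plane$nodes[, 2]
  centre <- 5L  # interior node of the single biquadratic element
  bound <- setdiff(seq_len(n), centre)
  idx <- sort(c(3 * (bound - 1) + 1, 3 * (bound - 1) + 2,
                3 * (bound - 1) + 3, 3 * (centre - 1) + 2))
  fixed <- list(idx = idx, val = c(u_exact[idx]))
  cfg <- solver_config(tol_force = 1e-9, stall_tol = 1e-7)
  s <- solve_equilibrium(tb, fib, NULL, p_lv = 0, u0 = u_exact * 0.9,
                         fixed = fixed, cfg = cfg)
  expect_lt(max(abs(s$u - u_exact)), 1e-8)
})

test_that("thick-walled cylinder inflation matches the closed-form solution", {
  tb <- mesh_tube(r_in = 10, r_out = 15, len = 10, nr = 4, nl = 2)
  n <- nrow(tb$plane$nodes)
  fib <- matrix(rep(c(0, 0, 1), each = n), n, 3)  # axial: inert in plane strain
  # plane strain without torsion: all u_z and phi fixed
  fixed <- list(idx = sort(c(seq(2, 3 * n, 3), seq(3, 3 * n, 3))),
                val = numeric(2 * n))
  pas <- passive_params(af0 = 1e-8)
  a0 <- pas[["a0"]]; a1 <- pas[["a1"]]
  W_l <- function(lam) {
    Et <- (lam^2 - 1) / 2; Er <- (lam^-2 - 1) / 2
    a0 * (exp(a1 * (Et^2 + Er^2)) - 1)
  }
  p_analytic <- function(lam_in) {
    rin <- lam_in * 10
    dW <- function(l) (W_l(l + 1e-6) - W_l(l - 1e-6)) / 2e-6
    stats::integrate(function(r) {
      R <- sqrt(r^2 - (rin^2 - 100))
      dW(r / R) * (r / R) / r
    }, rin, sqrt(225 + rin^2 - 100), rel.tol = 1e-10)$value
  }
  u <- NULL; p_prev <- 0
  for (p in c(0.5, 1.0, 2.0)) {
    s <- solve_equilibrium(tb, fib, NULL, p, u, fixed, pas,
                           p_from = p_prev)
    u <- s$u; p_prev <- p
    lam_in <- (10 + u[1]) / 10
    expect_lt(abs(p_analytic(lam_in) - p) / p, 0.01)
  }
})

test_that("the epicardium is traction free and the cavity operator is accurate", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  expect_lt(abs(cavity_volume(m) - m$geom$cavity_volume) /
              m$geom$cavity_volume, 0.005)
  s <- solve_equilibrium(m, f$vec, NULL, p_lv = 1.0)
  arr <- lvfiber:::solver_arrays(m)
  act <- lvfiber:::act_expand(NULL, arr$nel)
  asm <- lvfiber:::cpp_assemble(arr$nodes, arr$conn0, s$u, f$vec, act$amp,
                                act$lc, act$actv, passive_params(), 1.0,
                                arr$endo0, FALSE)
  L <- lvfiber:::cpp_pressure_load(arr$nodes, s$u, arr$endo0)
  # free epicardial dofs only: the basal corner node carries the (fixed)
  # axial support reaction
  epi_dofs <- setdiff(as.vector(outer(1:3, 3 * (m$plane$tags$epi - 1), "+")),
                      lv_fixed_dofs(m)$idx)
  expect_lt(max(abs(asm$res[epi_dofs])), 1e-6 * max(abs(L)))
})

test_that("the constant-volume solve is a fixed point and monotone in volume", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  s <- solve_equilibrium(m, f$vec, NULL, p_lv = 1.0)
  V1 <- cavity_volume(m, s$u)
  iso <- solve_isovolumic(m, f$vec, NULL, V_target = V1, u0 = s$u, p0 = 1.0)
  expect_lt(abs(iso$p_lv - 1.0), 2e-3)
  expect_lt(abs(iso$V - V1), 0.01)
  # passive pressure-volume relation is strictly increasing
  ps <- numeric(3)
  u <- s$u; p0 <- 1.0
  targets <- V1 + c(2, 6, 10)
  for (i in 1:3) {
    iso <- solve_isovolumic(m, f$vec, NULL, targets[i], u, p0)
    ps[i] <- iso$p_lv; u <- iso$u; p0 <- iso$p_lv
  }
  expect_true(all(diff(c(1.0, ps)) > 0))
})

test_that("pressure rises monotonically during isovolumic contraction", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  act <- active_params()
  sim <- cycle_init(m, f)
  u <- sim$u; sar <- sim$sarcomere; sar$t_a <- 0
  V0 <- cavity_volume(m, u)
  gp <- lvfiber:::gp_state(m, f$vec, NULL, u, passive_params())
  lam <- gp$lambda_f
  p_seq <- sim$p_lv
  for (k in 1:6) {
    stp <- active_stress_step(sar, lam, 4, act)
    sar <- stp$state
    drv <- active_drive(sar, lam, act)
    iso <- solve_isovolumic(m, f$vec, drv, V0, u, p_seq[length(p_seq)])
    u <- iso$u
    p_seq <- c(p_seq, iso$p_lv)
    gp <- lvfiber:::gp_state(m, f$vec, drv, u, passive_params())
    lam <- gp$lambda_f
    expect_lt(abs(iso$V - V0), 0.01)
  }
  expect_true(all(diff(p_seq) > 0))
})

test_that("without active stress no ejection occurs", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  act <- active_params(T0 = 1e-9)
  sim <- cycle_init(m, f, act = act)
  sim <- run_cardiac_cycle(m, f, sim, act = act, cfg = solver_config(dt = 8))
  expect_false("ej" %in% sim$cycle$phase)
  expect_equal(sum(sim$cycle$q_aortic), 0)
})

test_that("stroke-volume bookkeeping agrees between flow and geometry routes", {
  res <- acc_run("ss")
  hemo <- utils::read.csv(file.path(res, "hemodynamics.csv"))
  dt <- diff(hemo$t[1:2])
  sv_flow <- sum(hemo$q_aortic) * dt
  ej <- which(hemo$phase == "ej")
  sv_geom <- hemo$V_lv[min(ej) - 1] - hemo$V_lv[max(ej)]
  expect_lt(abs(sv_flow - sv_geom) / sv_flow, 0.001 + 0.03 / sv_flow)
  # converged cycle closes on itself
  expect_lt(abs(hemo$V_lv[nrow(hemo)] - hemo$V_lv[1]) / hemo$V_lv[1], 0.005)
})

test_that("the stroke volume converges under time-step refinement", {
  # the operator splitting (explicit contractile-element dynamics, phase
  # boundaries quantized to dt) is first-order accurate, so successive
  # halvings shrink the stroke-volume difference roughly in half
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  sv <- c()
  for (dt in c(4, 2, 1)) {
    cfg <- solver_config(dt = dt)
    sim <- cycle_init(m, f, cfg = cfg)
    for (i in 1:2) sim <- run_cardiac_cycle(m, f, sim, cfg = cfg)
    sv <- c(sv, sum(sim$cycle$q_aortic) * sim$cycle$dt)
  }
  d1 <- abs(sv[2] - sv[1]) / sv[3]
  d2 <- abs(sv[3] - sv[2]) / sv[3]
  expect_lt(d2, 0.025)
  expect_lt(d2, 0.8 * d1)
})
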