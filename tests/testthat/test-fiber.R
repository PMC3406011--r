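test_that("local cardiac basis is orthonormal, right-handed and outward", {
  g <- fx_geom()
  m <- fx_mesh_small()
  b <- lvfiber:::mesh_basis(m)
  for (i in seq_len(nrow(b$e_c0))) {
    M <- cbind(b$e_c0[i, ], b$e_l0[i, ], b$e_t0[i, ])
    expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
  # equatorial epicardial point: transmural normal horizontal, outward
  s_eq <- (pi / 2) / lvfiber:::chart_psi_base(g, 1)
  be <- local_basis(g, lvfiber:::chart_point(g, s_eq, 1))
  expect_equal(as.numeric(be$e_t0), c(1, 0, 0), tolerance = 1e-9)
  # longitudinal direction points apex-to-base (positive z away from apex)
  expect_true(all(b$e_l0[m$plane$uv[, 1] > -0.9, 3] > 0))
})

test_that("angle/vector conversion round-trips and handles special cases", {
  set.seed(42)
  for (rep in 1:5) {
    b <- random_basis()
    ah <- runif(200, -pi / 2 + 0.01, pi / 2 - 0.01)
    at <- runif(200, -pi / 2 + 0.01, pi / 2 - 0.01)
    v <- angles_to_vector(ah, at, b)
    expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-12)
    ang <- vector_to_angles(v, b)
    expect_lt(max(abs(ang$alpha_h - ah)), 1e-10)
    expect_lt(max(abs(ang$alpha_t - at)), 1e-10)
    # directionless canonicalization: flipping the vector changes nothing
    ang2 <- vector_to_angles(-v, b)
    expect_lt(max(abs(ang2$alpha_h - ah)), 1e-10)
  }
  b <- random_basis()
  expect_equal(as.numeric(angles_to_vector(0, 0, b)), as.numeric(b$e_c0),
               tolerance = 1e-12)
  expect_equal(as.numeric(angles_to_vector(pi / 2, 0, b)),
               as.numeric(b$e_l0), tolerance = 1e-12)
  expect_error(angles_to_vector(pi / 2, 0.3, b), "alpha_t")
})

test_that("the normal helix field is right-handed endo, left-handed epi, monotone", {
  uu <- seq(-1, 1, length.out = 21)
  expect_true(all(helix_ss(uu, -1) > 0))
  expect_true(all(helix_ss(uu, 1) < 0))
  vv <- seq(-1, 1, length.out = 101)
  expect_true(all(diff(helix_ss(0, vv)) < 0))
  # default endpoints of the transmural course: +50 deg endo, -70 deg epi
  expect_equal(helix_ss(0.3, -1), 50 * pi / 180, tolerance = 1e-12)
  expect_equal(helix_ss(0.3, 1), -70 * pi / 180, tolerance = 1e-12)
})

test_that("the initial transverse angle is zero and fibers lie in-surface", {
  m <- fx_mesh_small()
  expect_true(all(transverse_initial(runif(10), runif(10)) == 0))
  f <- fx_field_ss_small()
  expect_equal(stats::sd(f$alpha_t), 0)
  b <- lvfiber:::mesh_basis(m)
  expect_lt(max(abs(rowSums(f$vec * b$e_t0))), 1e-12)
})

test_that("the mirror-image field blends per the transition-zone geometry", {
  tp <- transition_params(u_t = 0, slope = 0.2, height = 0.3)
  # below the zone: normal; above: inverted; at the centre: zero
  for (v in c(-0.8, 0, 0.7)) {
    ctr <- tp$u_t + tp$slope * v
    expect_equal(helix_sit_initial(ctr - 0.5, v, tp = tp),
                 helix_ss(ctr - 0.5, v))
    expect_equal(helix_sit_initial(ctr + 0.5, v, tp = tp),
                 -helix_ss(ctr + 0.5, v))
    expect_equal(helix_sit_initial(ctr, v, tp = tp), 0, tolerance = 1e-12)
    # antisymmetry about the zone centre at equal v
    for (d in c(0.05, 0.1, 0.2))
      expect_equal(helix_sit_initial(ctr + d, v, tp = tp),
                   -helix_sit_initial(ctr - d, v, tp = tp),
                   tolerance = 1e-12)
  }
  # inverting twice restores the normal field exactly
  u <- runif(50, -1, 1); v <- runif(50, -1, 1)
  expect_equal(-(-helix_ss(u, v)), helix_ss(u, v))
  # sharp transition (height 0) is a step through zero
  tp0 <- transition_params(u_t = 0, slope = 0, height = 0)
  expect_equal(helix_sit_initial(0.01, 0, tp = tp0), -helix_ss(0.01, 0))
  expect_equal(helix_sit_initial(-0.01, 0, tp = tp0), helix_ss(-0.01, 0))
  expect_error(transition_params(u_t = 0.8, slope = 0.3, height = 0.3),
               "exits the wall")
})

test_that("the initial SIT field is continuous across the mesh", {
  m <- fx_mesh()
  f <- fiber_field(m, "sit")
  # along every transmural node line, angular jumps between longitudinally
  # adjacent nodes stay bounded by the analytic blend slope x nodal spacing
  ni <- 2 * m$plane$nr + 1; nj <- 2 * m$plane$nl + 1
  tp <- transition_params()
  max_slope <- 2 * max(abs(helix_ss(0, c(-1, 1)))) / tp$height
  for (i in seq_len(ni)) {
    ids <- (seq_len(nj) - 1) * ni + i
    du <- diff(m$plane$uv[ids, 1])
    dang <- acos(pmin(1, abs(rowSums(f$vec[ids[-nj], , drop = FALSE] *
                                       f$vec[ids[-1], , drop = FALSE]))))
    expect_true(all(dang <= 1.2 * max_slope * du + 0.05))
  }
})

test_that("fiber paths follow the field with fixed arc steps", {
  g <- fx_geom()
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  # uniform circumferential field: closed circular path at constant (r, z)
  fc <- f
  fc$vec <- matrix(rep(c(0, 1, 0), each = nrow(f$vec)), ncol = 3)
  p0 <- lvfiber:::chart_point(g, 0.5, 0)
  seed <- cbind(p0[1], 0, p0[2])
  pl <- trace_fiber_paths(m, fc, seed, step = 2, max_steps = 120)[[1]]
  rr <- sqrt(pl[, 1]^2 + pl[, 2]^2)
  expect_lt(max(abs(rr - rr[1])), 1e-4)
  expect_lt(max(abs(pl[, 3] - pl[1, 3])), 1e-12)
  seg <- sqrt(rowSums(diff(pl)^2))
  expect_lt(max(seg) - min(seg), 1e-6)
  # RK4 vs Euler at 100x smaller step on the real field
  p1 <- trace_fiber_paths(m, f, seed, step = 1, max_steps = 80)[[1]]
  p2 <- trace_fiber_paths(m, f, seed, step = 0.01, max_steps = 8000,
                          method = "euler")[[1]]
  L <- sum(sqrt(rowSums(diff(p1)^2)))
  k2 <- (nrow(p1) - 1) * 100 + 1
  expect_lt(sqrt(sum((p1[nrow(p1), ] - p2[min(nrow(p2), k2), ])^2)) / L,
            0.01)
  # seeds outside the wall are rejected
  expect_error(trace_fiber_paths(m, f, cbind(0, 0, 0), step = 1), "outside")
})
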