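test_that("natural strain follows the logarithmic definition and is additive", {
  # constant stretch over a phase -> zero strain
  cyc <- list(phase = c("ic", "ic", "ej", "ej", "ej"),
              lam0 = c(1.1, 1.2),
              lambda_hist = cbind(c(1.1, 1.2), c(1.1, 1.2),
                                  c(1.05, 1.1), c(1.0, 1.05),
                                  c(1.1 * exp(-1), 1.0)))
  expect_equal(natural_fiber_strain(cyc, "ic"), c(0, 0))
  # lambda 1.0 -> e^-1 over ejection gives exactly -1
  expect_equal(natural_fiber_strain(cyc, "ej")[1], -1)
  expect_error(natural_fiber_strain(cyc, "ir"), "missing")
  # additivity over adjacent subintervals
  lam <- c(1.0, 1.07, 1.13, 1.21)
  e_tot <- log(lam[4] / lam[1])
  e_parts <- log(lam[2] / lam[1]) + log(lam[3] / lam[2]) +
    log(lam[4] / lam[3])
  expect_equal(e_parts, e_tot, tolerance = 1e-12)
})

test_that("loop areas reproduce rectangle and ellipse oracles", {
  # constant stress: zero area
  eps <- seq(0, -0.1, length.out = 50)
  expect_equal(stroke_work_density(rep(5, 50), c(eps, rev(eps))[1:50]), 0,
               tolerance = 1e-12)
  # rectangle sigma in [10, 20] kPa, eps in [-0.1, 0], work-producing
  eps_r <- c(0, -0.1, -0.1, 0)
  sig_r <- c(20, 20, 10, 10)
  expect_equal(stroke_work_density(sig_r, eps_r), 1.0, tolerance = 1e-12)
  # discretized ellipse: area pi a b within 0.1%
  a <- 0.07; b <- 12
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  eps_e <- a * cos(th)
  sig_e <- 30 + b * sin(th)   # counterclockwise in (eps, sigma)
  expect_lt(abs(stroke_work_density(sig_e, eps_e) - pi * a * b) /
              (pi * a * b), 0.001)
  # open loop triggers a warning and is closed
  expect_warning(stroke_work_density(sig_e[1:600], eps_e[1:600]), "open")
})

test_that("torsion is zero for rigid rotation and at the reference time", {
  m <- fx_mesh_small()
  mot <- make_motion("rigid_rotation", m, amplitude = 0.2, n_steps = 12)
  tor <- torsion(m, mot$u_hist, ref = 3, normalize = "rotation")
  expect_lt(max(abs(tor$torsion)), 1e-13)
  mot2 <- make_motion("twist", m, amplitude = 0.002, n_steps = 12)
  tor2 <- torsion(m, mot2$u_hist, ref = 3)
  expect_equal(unique(tor2$torsion[tor2$time == tor2$time[3]]), 0)
})

test_that("a prescribed twist field yields the analytic torsion", {
  m <- fx_mesh_small()
  mot <- make_motion("twist", m, amplitude = 0.003, n_steps = 10)
  tor <- torsion(m, mot$u_hist, ref = 10, normalize = "rotation")
  # phi = c(t) (z - z_ref): radially averaged rotation at a section is
  # c(t) (z_bar - z_ref); relative to base and the reference instant
  # (profile = 0 there): c(t) (z_bar_i - z_bar_base)
  zbar <- function(lv) lvfiber:::interp_level(m, m$plane$nodes[, 2], lv)
  zb_base <- mean(m$plane$nodes[m$plane$tags$base, 2])
  for (is in 1:4) {
    lv <- unique(tor$level)[is]
    expected <- mot$profile * (zbar(lv) - zb_base)
    got <- tor$torsion[tor$section == is]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("uniform twist per length reads the same at every section in shear mode", {
  m <- fx_mesh()
  mot <- make_motion("twist", m, amplitude = 0.002, n_steps = 8)
  tor <- torsion(m, mot$u_hist, ref = 8, normalize = "shear")
  peak <- tapply(abs(tor$torsion), tor$section, max)
  expect_lt((max(peak) - min(peak)) / max(peak), 0.25)
})

test_that("region statistics are volume-weighted", {
  expect_equal(region_stats(c(5, 5, 5))$sd, 0)
  rs <- region_stats(c(0, 2))
  expect_equal(rs$mean, 1)
  expect_equal(rs$sd, 1)
  # doubling one weight shifts the mean per the weighted-moment formula
  rw <- region_stats(c(0, 2), weights = c(2, 1))
  expect_equal(rw$mean, 2 / 3)
  expect_error(region_stats(numeric(0)), "empty")
  # the default mask excludes the apical and basal element layers
  m <- fx_mesh_small()
  msk <- region_mask(m)
  expect_equal(sum(msk), (m$plane$nl - 2) * m$plane$nr * 9)
})

test_that("circumferential-radial shear matches rigid and simple-shear oracles", {
  m <- fx_mesh_small()
  mot <- make_motion("rigid_rotation", m, amplitude = 0.3, n_steps = 4)
  ecr <- circumferential_radial_shear(m, mot$u_hist[, 2])
  expect_lt(max(abs(ecr)), 1e-12)
  # simple shear of amount gamma at R0: E_cr = gamma / 2 there
  tb <- mesh_tube(r_in = 20, r_out = 24, len = 4, nr = 6, nl = 1)
  tb$geom <- fx_geom()  # basis evaluation is not used for the tube directly
  gpd <- lvfiber:::mesh_gp_data(tb)
  k0 <- which.min(abs(gpd$pos[, 1] - 22))
  R0 <- gpd$pos[k0, 1]
  gam <- 0.04
  n <- nrow(tb$plane$nodes)
  u <- numeric(3 * n)
  u[seq(2, 3 * n, 3)] <- gam * (tb$plane$nodes[, 1] - R0) /
    tb$plane$nodes[, 1]
  arr <- lvfiber:::solver_arrays(tb)
  gp <- lvfiber:::cpp_gp_state(arr$nodes, arr$conn0, u,
                               matrix(rep(c(0, 1, 0), each = n), ncol = 3),
                               matrix(0, arr$nel, 9), matrix(0, arr$nel, 9),
                               c(1, 1), passive_params())
  e <- (k0 - 1) %/% 9 + 1; q <- (k0 - 1) %% 9 + 1
  F <- matrix(gp$F[e, ((q - 1) * 9 + 1):(q * 9)], 3, 3, byrow = TRUE)
  E <- 0.5 * (t(F) %*% F - diag(3))
  # basis at the tube GP: e_c = e_theta, e_t = e_r.  The nodal field is a
  # non-polynomial function of R, so the interpolated value carries a few
  # percent of discretization error at this resolution ...
  expect_equal(E[2, 1], gam / 2, tolerance = 0.03)
  # ... while the closed-form deformation gradient gives gamma/2 exactly
  mot_sh <- make_motion("simple_shear", tb, amplitude = gam, n_steps = 4)
  k_peak <- which.max(abs(mot_sh$profile))
  Fc <- mot_sh$F_closed(c(mot_sh$R0, 2), k_peak)
  Ec <- 0.5 * (t(Fc) %*% Fc - diag(3))
  expect_equal(Ec[2, 1], mot_sh$profile[k_peak] / 2, tolerance = 1e-12)
  # FD oracle on a smooth field: FE-evaluated F matches the closed form
  mot3 <- make_motion("twist", fx_mesh_small(), amplitude = 0.004,
                      n_steps = 6)
  Fn <- lvfiber:::F_at_nodes(fx_mesh_small(), mot3$u_hist[, 3])
  nodes <- fx_mesh_small()$plane$nodes
  for (i in c(5, 40, 70)) {
    Fc <- mot3$F_closed(nodes[i, ], 3)
    expect_equal(matrix(Fn[i, ], 3, 3, byrow = TRUE), Fc,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("torsion CSV round-trips through the exchange format", {
  tr <- make_torsion_set("sit", amplitude = 0.08, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_torsion_csv(tr, f)
  tr2 <- read_torsion_csv(f)
  expect_equal(tr2$torsion, tr$torsion, tolerance = 1e-12)
  expect_equal(tr2$section, tr$section)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_torsion_csv(bad), "columns")
})
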