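test_that("default mesh honours the 6x1x10 element layout with 27-node hexahedra", {
  m <- fx_mesh()
  expect_equal(m$n_elements, 60L)
  expect_equal(ncol(m$hex3d$conn), 27L)
  expect_equal(nrow(m$hex3d$conn), 60L)
  expect_equal(m$subdivisions, c(6L, 1L, 10L))
  # every element has 27 distinct nodes
  expect_true(all(apply(m$hex3d$conn, 1, function(x) length(unique(x))) == 27))
})

test_that("quadrature volumes match the closed-form truncated-ellipsoid shell", {
  g <- fx_geom()
  m <- fx_mesh()
  # independent oracle: integrate the disk areas of each truncated ellipsoid
  vol_seg <- function(a, c, zb)
    stats::integrate(function(z) pi * a^2 * (1 - z^2 / c^2), -c, zb,
                     rel.tol = 1e-12)$value
  V_epi <- vol_seg(g$a_epi, g$c_epi, g$z_base)
  V_endo <- vol_seg(g$a_endo, g$c_endo, g$z_base)
  expect_lt(abs(m$wall_volume_quad - (V_epi - V_endo)) / (V_epi - V_endo),
            0.005)
  expect_lt(abs(m$cavity_volume_quad - V_endo) / V_endo, 0.005)
  # and the requested volumes were realized by the geometry solve
  expect_lt(abs(m$wall_volume_quad / 1000 - g$wall_volume) / g$wall_volume,
            0.005)
})

test_that("element volumes sum to the wall volume and Jacobians are positive", {
  m <- fx_mesh()
  expect_equal(sum(m$element_volumes), m$wall_volume_quad, tolerance = 1e-12)
  J <- lvfiber:::hex_jacobians(m)
  expect_true(all(J > 0))
})

test_that("volumes are stable under mesh refinement", {
  g <- fx_geom()
  m1 <- fx_mesh()
  m2 <- build_mesh(g, c(12, 1, 20))
  expect_lt(abs(m2$wall_volume_quad - m1$wall_volume_quad) /
              m1$wall_volume_quad, 0.001)
  expect_lt(abs(m2$cavity_volume_quad - m1$cavity_volume_quad) /
              m1$cavity_volume_quad, 0.001)
})

test_that("wall coordinates hit their conventional endpoints", {
  g <- fx_geom()
  # endocardial surface point -> v = -1; epicardial -> +1
  p_en <- lvfiber:::chart_point(g, 0.45, -1)
  p_ep <- lvfiber:::chart_point(g, 0.45, 1)
  expect_equal(wall_coords(g, p_en)$v, -1, tolerance = 1e-9)
  expect_equal(wall_coords(g, p_ep)$v, 1, tolerance = 1e-9)
  # equatorial point -> u = 0
  s_eq <- (pi / 2) / lvfiber:::chart_psi_base(g, 0)
  expect_equal(wall_coords(g, lvfiber:::chart_point(g, s_eq, 0))$u, 0,
               tolerance = 1e-9)
  # base plane -> u = +1; near-apex -> u near -1
  expect_equal(wall_coords(g, lvfiber:::chart_point(g, 1, 0.3))$u, 1,
               tolerance = 1e-9)
  expect_equal(wall_coords(g, lvfiber:::chart_point(g, 1e-4, 0.3))$u, -1,
               tolerance = 1e-3)
})

test_that("midwall by transmural arc length maps to v = 0", {
  g <- fx_geom()
  s0 <- 0.55
  # independent bisection: cumulative chord length along the transmural line
  ws <- seq(-1, 1, length.out = 2001)
  pts <- lvfiber:::chart_point(g, s0, ws)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg))
  w_half <- ws[which.min(abs(cum - cum[length(cum)] / 2))]
  v <- wall_coords(g, lvfiber:::chart_point(g, s0, w_half))$v
  expect_lt(abs(v), 2e-3)
})

test_that("points outside the wall and degenerate geometries are rejected", {
  g <- fx_geom()
  expect_error(wall_coords(g, cbind(0.1, 0.1)), "outside")
  expect_error(wall_coords(g, cbind(2 * g$a_epi, 0)), "outside")
  expect_error(lv_geometry(wall_volume = 1, cavity_volume = 500),
               "degenerate")
})

test_that("the single circumferential element closes periodically", {
  m <- fx_mesh()
  pp <- m$hex3d$periodic_pairs
  # identified nodes agree in (r, z) and differ by a full turn in theta
  expect_equal(m$hex3d$nodes[pp[, 1], c(1, 3)],
               m$hex3d$nodes[pp[, 2], c(1, 3)])
  expect_true(all(abs(m$hex3d$nodes[pp[, 2], 2] -
                        m$hex3d$nodes[pp[, 1], 2] - 2 * pi) < 1e-12))
})

test_that("mesh export writes a VTK unstructured grid with wall coordinates", {
  m <- fx_mesh_small()
  f <- tempfile(fileext = ".vtu")
  write_vtu_plane(m, f)
  txt <- readLines(f)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl('Name="u"', txt)))
  expect_true(any(grepl('Name="v"', txt)))
})
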