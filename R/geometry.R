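# Geometry: truncated-ellipsoid LV wall, hexahedral mesh, wall-coordinate chart.

#' Left-ventricular wall geometry
#'
#' Defines the unloaded (passive stress-free) LV wall as the region between
#' two truncated, coaxial prolate ellipsoids of revolution, cut by a flat
#' basal plane.  Semi-axes are solved from the prescribed wall and cavity
#' volumes, the base truncation height and the two axis ratios.
#'
#' Default volumes (136 mL wall, 44 mL cavity) and the truncation at half the
#' epicardial long semi-axis above the equator are representative of a small
#' human (or large dog) heart; they are modelling choices of this package,
#' not measured values.
#'
#' @param wall_volume Wall (muscle) volume in mL.
#' @param cavity_volume Unloaded cavity volume in mL.
#' @param truncation Height of the basal plane above the equator, as a
#'   fraction of the epicardial long semi-axis (0 < truncation < 1).
#' @param shape_endo,shape_epi Long-to-short axis ratios c/a of the
#'   endocardial and epicardial ellipsoids.
#' @return An object of class `lv_geometry` with semi-axes `a_endo`, `c_endo`,
#'   `a_epi`, `c_epi` and base height `z_base` in mm, plus the inputs.
#' @examples
#' geom <- lv_geometry()
#' geom$z_base / geom$c_epi   # 0.5 by construction
#' @export
lv_geometry <- function(wall_volume = 136, cavity_volume = 44,
                        truncation = 0.5, shape_endo = 2.0, shape_epi = 1.4) {
  stopifnot(wall_volume > 0, cavity_volume > 0,
            truncation > 0, truncation < 1,
            shape_endo > 0, shape_epi > 0)
  V_wall <- wall_volume * 1000   # mm^3
  V_cav  <- cavity_volume * 1000

  # Outer ellipsoid: truncated volume is proportional to a^3 when z_base is a
  # fixed fraction f of c = k a:  V = pi a^3 k (f - f^3/3 + 2/3).
  f <- truncation
  k <- shape_epi
  a_epi <- ((V_wall + V_cav) / (pi * k * (f - f^3 / 3 + 2 / 3)))^(1 / 3)
  c_epi <- k * a_epi
  z_base <- f * c_epi

  # Inner ellipsoid: truncated volume at the same absolute plane height.
  k_en <- shape_endo
  fcav <- function(a) ellipsoid_segment_volume(a, k_en * a, z_base) - V_cav
  if (z_base >= k_en * a_epi || fcav(a_epi) < 0)
    stop("degenerate geometry: cavity cannot fit inside the epicardial ",
         "ellipsoid with these volumes/shape parameters")
  a_endo <- stats::uniroot(fcav, c(1e-6, a_epi), tol = 1e-10)$root
  c_endo <- k_en * a_endo

  if (!(a_epi > a_endo && c_epi > c_endo))
    stop("degenerate geometry: epicardial ellipsoid does not strictly ",
         "enclose the endocardial ellipsoid")
  if (z_base >= c_endo)
    stop("degenerate geometry: basal plane does not intersect the ",
         "endocardial surface")

  structure(list(wall_volume = wall_volume, cavity_volume = cavity_volume,
                 truncation = truncation, shape_endo = shape_endo,
                 shape_epi = shape_epi,
                 a_endo = a_endo, c_endo = c_endo,
                 a_epi = a_epi, c_epi = c_epi, z_base = z_base),
            class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("LV truncated-ellipsoid geometry\n")
  cat(sprintf("  wall volume   : %.1f mL\n", x$wall_volume))
  cat(sprintf("  cavity volume : %.1f mL\n", x$cavity_volume))
  cat(sprintf("  endocardium   : a = %.2f mm, c = %.2f mm\n", x$a_endo, x$c_endo))
  cat(sprintf("  epicardium    : a = %.2f mm, c = %.2f mm\n", x$a_epi, x$c_epi))
  cat(sprintf("  base plane    : z = %.2f mm above equator\n", x$z_base))
  invisible(x)
}

#' Volume of a truncated ellipsoid of revolution
#'
#' Closed-form volume of the solid of revolution r^2/a^2 + z^2/c^2 <= 1
#' below the plane z = z_base (apex at z = -c).
#'
#' @param a,c Short and long semi-axes (mm).
#' @param z_base Truncation plane height (mm), -c < z_base <= c.
#' @return Volume in mm^3.
#' @export
ellipsoid_segment_volume <- function(a, c, z_base) {
  stopifnot(z_base > -c)
  if (z_base >= c) return(4 / 3 * pi * a^2 * c)
  pi * a^2 * (z_base - z_base^3 / (3 * c^2) + 2 * c / 3)
}

# ---------------------------------------------------------------------------
# Chart (s, w): w in [-1, 1] transmural (endo -> epi), s in [0, 1] apex -> base.
# Each w is a nested ellipsoid with linearly interpolated semi-axes; positions
# follow the elliptic angle psi = s * psi_base(w), z = -c cos(psi), r = a sin(psi).

chart_axes <- function(geom, w) {
  t <- (w + 1) / 2
  list(a = geom$a_endo + t * (geom$a_epi - geom$a_endo),
       c = geom$c_endo + t * (geom$c_epi - geom$c_endo))
}

chart_psi_base <- function(geom, w) {
  ax <- chart_axes(geom, w)
  acos(pmin(1, pmax(-1, -geom$z_base / ax$c)))
}

chart_point <- function(geom, s, w) {
  ax <- chart_axes(geom, w)
  psi <- s * chart_psi_base(geom, w)
  cbind(r = ax$a * sin(psi), z = -ax$c * cos(psi))
}

# Gauss-Legendre nodes/weights on [-1,1] (Golub-Welsch), used for the
# arc-length quadratures of the wall-coordinate chart.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

.lv_cache <- new.env(parent = emptyenv())
gl20 <- function() {
  if (is.null(.lv_cache$gl20)) .lv_cache$gl20 <- gauss_legendre(20)
  .lv_cache$gl20
}

# Arc length along the meridian ellipse of level w, between elliptic angles.
meridian_arc <- function(geom, w, psi0, psi1) {
  ax <- chart_axes(geom, w)
  g <- gl20()
  mid <- (psi0 + psi1) / 2; half <- (psi1 - psi0) / 2
  psi <- mid + half * g$x
  sum(g$w * sqrt(ax$a^2 * cos(psi)^2 + ax$c^2 * sin(psi)^2)) * half
}

# Arc length along the transmural coordinate line s = const, from w0 to w1.
transmural_arc <- function(geom, s, w0, w1) {
  g <- gl20()
  mid <- (w0 + w1) / 2; half <- (w1 - w0) / 2
  ww <- mid + half * g$x
  da <- (geom$a_epi - geom$a_endo) / 2   # d a / d w
  dc <- (geom$c_epi - geom$c_endo) / 2
  ax <- chart_axes(geom, ww)
  psib <- chart_psi_base(geom, ww)
  # d psi_base / d w via derivative of acos(-z_base/c)
  u0 <- -geom$z_base / ax$c
  dpsib <- -(geom$z_base * dc / ax$c^2) / sqrt(pmax(1e-14, 1 - u0^2))
  psi <- s * psib
  dpsi <- s * dpsib
  drdw <- da * sin(psi) + ax$a * cos(psi) * dpsi
  dzdw <- -dc * cos(psi) + ax$c * sin(psi) * dpsi
  sum(g$w * sqrt(drdw^2 + dzdw^2)) * half
}

# Normalized longitudinal coordinate u at chart point (s, w):
# piecewise-linear in geodesic distance from the equator along the meridian,
# u = -1 at the apex, 0 at the equator, +1 on the basal plane.
chart_u <- function(geom, s, w) {
  psi <- s * chart_psi_base(geom, w)
  psi_eq <- pi / 2
  if (psi >= psi_eq) {
    meridian_arc(geom, w, psi_eq, psi) /
      meridian_arc(geom, w, psi_eq, chart_psi_base(geom, w))
  } else {
    -meridian_arc(geom, w, psi, psi_eq) / meridian_arc(geom, w, 0, psi_eq)
  }
}

# Normalized transmural coordinate v at chart point (s, w): linear in arc
# length along the s = const coordinate line, -1 at endo, +1 at epi.
chart_v <- function(geom, s, w) {
  if (abs(w + 1) < 1e-14) return(-1)
  if (abs(w - 1) < 1e-14) return(1)
  2 * transmural_arc(geom, s, -1, w) / transmural_arc(geom, s, -1, 1) - 1
}

#' Normalized wall coordinates of points in the LV wall
#'
#' Maps points to the normalized chart (u, v): u is piecewise-linear in the
#' geodesic distance from the equatorial plane along the local meridian
#' (u = -1 at the apex, 0 at the equator, +1 on the basal plane); v is linear
#' in arc length along the local transmural coordinate line (v = -1 on the
#' endocardium, +1 on the epicardium).
#'
#' @param geom An [lv_geometry()] object.
#' @param points Numeric matrix with columns (r, z) (meridional coordinates)
#'   or (x, y, z) (Cartesian; r is recovered as sqrt(x^2 + y^2)).
#' @param tol Relative tolerance for the inside-wall test.
#' @return Data frame with columns `u` and `v`, one row per point.
#' @export
wall_coords <- function(geom, points, tol = 1e-8) {
  points <- rbind(points)
  if (ncol(points) == 3) points <- cbind(sqrt(points[, 1]^2 + points[, 2]^2),
                                         points[, 3])
  stopifnot(ncol(points) == 2)
  out <- matrix(NA_real_, nrow(points), 2)
  for (ip in seq_len(nrow(points))) {
    loc <- chart_locate(geom, points[ip, 1], points[ip, 2], tol)
    out[ip, ] <- c(chart_u(geom, loc$s, loc$w), chart_v(geom, loc$s, loc$w))
  }
  data.frame(u = out[, 1], v = out[, 2])
}

# Invert the chart: meridional point (r, z) -> (s, w).  Errors outside wall.
chart_locate <- function(geom, r, z, tol = 1e-8) {
  gfun <- function(w) {
    ax <- chart_axes(geom, w)
    r^2 / ax$a^2 + z^2 / ax$c^2 - 1
  }
  if (gfun(-1) < -tol || gfun(1) > tol || z > geom$z_base + tol * geom$c_epi)
    stop(sprintf("point (r=%.3f, z=%.3f) lies outside the LV wall", r, z))
  if (gfun(-1) < 0) {
    w <- -1
  } else if (gfun(1) > 0) {
    w <- 1
  } else {
    w <- stats::uniroot(gfun, c(-1, 1), tol = 1e-13)$root
  }
  ax <- chart_axes(geom, w)
  psi <- atan2(r / ax$a, -z / ax$c)
  s <- min(1, psi / chart_psi_base(geom, w))
  list(s = s, w = w)
}

# ---------------------------------------------------------------------------
# Meshing

# 1D quadratic Lagrange shape functions on [-1,1] at nodes (-1, 0, 1)
shape1 <- function(x) cbind(x * (x - 1) / 2, 1 - x^2, x * (x + 1) / 2)
dshape1 <- function(x) cbind(x - 0.5, -2 * x, x + 0.5)

# 9-node biquadratic shape functions; local node order: xi fastest
# (transmural), then eta (longitudinal).
shape2 <- function(xi, eta) {
  as.vector(outer(shape1(xi)[1, ], shape1(eta)[1, ]))
}
dshape2 <- function(xi, eta) {
  nx <- shape1(xi)[1, ]; ny <- shape1(eta)[1, ]
  dx <- dshape1(xi)[1, ]; dy <- dshape1(eta)[1, ]
  cbind(as.vector(outer(dx, ny)), as.vector(outer(nx, dy)))
}

#' Build the LV wall mesh
#'
#' Discretizes the truncated-ellipsoid wall with 27-node hexahedral elements
#' (tri-quadratic interpolation).  The model is rotationally symmetric, so a
#' single circumferential element spans the full circumference; node
#' coordinates are stored in cylindrical components (r, theta, z) and the
#' theta = 0 meridional plane carries the equivalent 9-node biquadratic quad
#' mesh on which the solver operates.
#'
#' @param geom An [lv_geometry()] object.
#' @param subdivisions Integer vector `c(n_radial, n_circumferential,
#'   n_longitudinal)`; the default `c(6, 1, 10)` gives 60 elements.
#' @return An object of class `lv_mesh`; see Details.
#' @details The returned object contains `hex3d` (3D connectivity, 27 nodes
#'   per element, cylindrical node coordinates, surface tags, periodic pairs
#'   identifying theta = 2*pi with theta = 0), `plane` (meridional 9-node quad
#'   mesh with per-node wall coordinates u, v and boundary tags) and
#'   quadrature wall/cavity volumes in mm^3.
#' @export
build_mesh <- function(geom, subdivisions = c(6, 1, 10)) {
  stopifnot(inherits(geom, "lv_geometry"),
            length(subdivisions) == 3, all(subdivisions >= 1))
  nr <- as.integer(subdivisions[1])
  nc <- as.integer(subdivisions[2])
  nl <- as.integer(subdivisions[3])
  if (nc != 1)
    stop("the rotationally symmetric formulation uses exactly 1 ",
         "circumferential element")

  ni <- 2 * nr + 1   # transmural node stations
  nj <- 2 * nl + 1   # longitudinal node stations
  ws <- seq(-1, 1, length.out = ni)
  ss <- seq(0, 1, length.out = nj)

  nodes <- matrix(0, ni * nj, 2)
  uv <- matrix(0, ni * nj, 2)
  for (j in seq_len(nj)) for (i in seq_len(ni)) {
    id <- (j - 1) * ni + i
    nodes[id, ] <- chart_point(geom, ss[j], ws[i])
    uv[id, ] <- c(chart_u(geom, ss[j], ws[i]), chart_v(geom, ss[j], ws[i]))
  }
  colnames(nodes) <- c("r", "z"); colnames(uv) <- c("u", "v")

  conn <- matrix(0L, nr * nl, 9)
  el <- 0L
  for (jl in seq_len(nl)) for (ir in seq_len(nr)) {
    el <- el + 1L
    i0 <- 2L * (ir - 1L); j0 <- 2L * (jl - 1L)
    loc <- integer(9); m <- 0L
    for (jj in 0:2) for (ii in 0:2) {
      m <- m + 1L
      loc[m] <- (j0 + jj) * ni + (i0 + ii) + 1L
    }
    conn[el, ] <- loc
  }

  grid_id <- function(i, j) (j - 1L) * ni + i
  tags <- list(
    endo  = grid_id(1L, seq_len(nj)),
    epi   = grid_id(ni, seq_len(nj)),
    base  = grid_id(seq_len(ni), nj),
    axis  = grid_id(seq_len(ni), 1L),
    endo_base_ring = grid_id(1L, nj)
  )

  # Edge lists (element id, local edge nodes in order) for surface integrals.
  # Endocardial edge of element (ir = 1): local nodes 1, 4, 7 (xi = -1),
  # ordered apex -> base with increasing element index.
  endo_els <- which((seq_len(nr * nl) - 1L) %% nr == 0L)
  endo_edges <- cbind(el = endo_els,
                      n1 = conn[endo_els, 1], n2 = conn[endo_els, 4],
                      n3 = conn[endo_els, 7])
  epi_els <- which(seq_len(nr * nl) %% nr == 0L)
  epi_edges <- cbind(el = epi_els,
                     n1 = conn[epi_els, 3], n2 = conn[epi_els, 6],
                     n3 = conn[epi_els, 9])

  plane <- list(nodes = nodes, conn = conn, uv = uv, nr = nr, nl = nl,
                tags = tags, endo_edges = endo_edges, epi_edges = epi_edges)

  # Quadrature volumes (3x3 Gauss, axisymmetric measure 2*pi*R)
  g3 <- gauss_legendre(3)
  wall_q <- 0
  elvol <- numeric(nr * nl)
  for (e in seq_len(nr * nl)) {
    xy <- nodes[conn[e, ], , drop = FALSE]
    ve <- 0
    for (q1 in 1:3) for (q2 in 1:3) {
      dN <- dshape2(g3$x[q1], g3$x[q2])
      J <- t(xy) %*% dN
      detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      R <- sum(shape2(g3$x[q1], g3$x[q2]) * xy[, 1])
      ve <- ve + g3$w[q1] * g3$w[q2] * 2 * pi * R * detJ
    }
    elvol[e] <- ve
    wall_q <- wall_q + ve
  }

  # Cavity volume: V = pi * integral r^2 dz along the deformed endocardial
  # curve, apex -> base (here evaluated on the reference mesh).
  cav_q <- cavity_volume_plane(nodes, endo_edges)

  # ---- 3D hexahedral mesh: tensor product with theta stations {0, pi, 2pi}
  thetas <- c(0, pi, 2 * pi)
  n3 <- ni * nj * 3
  nodes3 <- matrix(0, n3, 3); colnames(nodes3) <- c("r", "theta", "z")
  uv3 <- matrix(0, n3, 2); colnames(uv3) <- c("u", "v")
  id3 <- function(i, k, j) (j - 1L) * 3L * ni + (k - 1L) * ni + i
  for (j in seq_len(nj)) for (k in 1:3) for (i in seq_len(ni)) {
    nodes3[id3(i, k, j), ] <- c(nodes[grid_id(i, j), 1], thetas[k],
                                nodes[grid_id(i, j), 2])
    uv3[id3(i, k, j), ] <- uv[grid_id(i, j), ]
  }
  conn3 <- matrix(0L, nr * nl, 27)
  el <- 0L
  for (jl in seq_len(nl)) for (ir in seq_len(nr)) {
    el <- el + 1L
    i0 <- 2L * (ir - 1L); j0 <- 2L * (jl - 1L)
    loc <- integer(27); m <- 0L
    for (jj in 0:2) for (kk in 1:3) for (ii in 0:2) {
      m <- m + 1L
      loc[m] <- id3(i0 + ii + 1L, kk, j0 + jj + 1L)
    }
    conn3[el, ] <- loc
  }
  periodic_pairs <- cbind(master = as.vector(outer(seq_len(ni), (seq_len(nj) - 1L) * 3L * ni,
                                                   function(i, o) i + o)),
                          slave = as.vector(outer(seq_len(ni), (seq_len(nj) - 1L) * 3L * ni,
                                                  function(i, o) i + o + 2L * ni)))
  tags3 <- list(
    endocardium = which(rep(rep(seq_len(ni), 3), nj) == 1L),
    epicardium  = which(rep(rep(seq_len(ni), 3), nj) == ni),
    base        = (n3 - 3L * ni + 1L):n3,
    basal_endocardial_ring = id3(1L, 1:3, nj)
  )

  structure(list(geom = geom, plane = plane,
                 hex3d = list(nodes = nodes3, conn = conn3, uv = uv3,
                              tags = tags3, periodic_pairs = periodic_pairs),
                 subdivisions = c(nr, nc, nl),
                 n_elements = nr * nc * nl,
                 element_volumes = unname(elvol),
                 wall_volume_quad = unname(wall_q),
                 cavity_volume_quad = unname(cav_q)),
            class = "lv_mesh")
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV mesh: %d elements (%d radial x %d circumferential x %d longitudinal)\n",
              x$n_elements, x$subdivisions[1], x$subdivisions[2], x$subdivisions[3]))
  cat(sprintf("  27-node hexahedra; %d 3D nodes, %d meridional nodes\n",
              nrow(x$hex3d$nodes), nrow(x$plane$nodes)))
  cat(sprintf("  quadrature wall volume   : %.2f mL (target %.2f)\n",
              x$wall_volume_quad / 1000, x$geom$wall_volume))
  cat(sprintf("  quadrature cavity volume : %.2f mL (target %.2f)\n",
              x$cavity_volume_quad / 1000, x$geom$cavity_volume))
  invisible(x)
}

# Cavity volume from a meridional node table and the endocardial edge list:
# pi * integral r^2 dz from apex to base (positive when z increases basally).
cavity_volume_plane <- function(nodes, endo_edges) {
  g3 <- gauss_legendre(3)
  V <- 0
  for (ie in seq_len(nrow(endo_edges))) {
    ids <- endo_edges[ie, 2:4]
    rr <- nodes[ids, 1]; zz <- nodes[ids, 2]
    for (q in 1:3) {
      N <- shape1(g3$x[q])[1, ]; dN <- dshape1(g3$x[q])[1, ]
      V <- V + g3$w[q] * pi * sum(N * rr)^2 * sum(dN * zz)
    }
  }
  V
}

# Jacobian determinants of the 3D hex elements at their Gauss points,
# in the cylindrical coordinate map (r, theta, z) with volume measure r dr dtheta dz.
hex_jacobians <- function(mesh) {
  g3 <- gauss_legendre(3)
  nodes <- mesh$hex3d$nodes; conn <- mesh$hex3d$conn
  out <- matrix(0, nrow(conn), 27)
  for (e in seq_len(nrow(conn))) {
    xyz <- nodes[conn[e, ], , drop = FALSE]
    q <- 0
    for (q3 in 1:3) for (q2 in 1:3) for (q1 in 1:3) {
      q <- q + 1
      n1 <- shape1(g3$x[q1])[1, ]; d1 <- dshape1(g3$x[q1])[1, ]
      n2 <- shape1(g3$x[q2])[1, ]; d2 <- dshape1(g3$x[q2])[1, ]
      n3v <- shape1(g3$x[q3])[1, ]; d3 <- dshape1(g3$x[q3])[1, ]
      # local order: i (transmural) fastest, then k (theta), then j (longitudinal)
      Nxi  <- as.vector(outer(outer(d1, n2), n3v))
      Neta <- as.vector(outer(outer(n1, d2), n3v))
      Nze  <- as.vector(outer(outer(n1, n2), d3))
      J <- rbind(colSums(Nxi * xyz), colSums(Neta * xyz), colSums(Nze * xyz))
      R <- sum(as.vector(outer(outer(n1, n2), n3v)) * xyz[, 1])
      out[e, q] <- det(J) * R
    }
  }
  out
}
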