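# Myofiber orientation fields: local cardiac basis, helix/transverse angles,
# the normal (SS) transmural distribution, the mirror-image (SIT) field with
# its apex-to-base transition zone, and fiber-path tracing.

#' Local cardiac basis at points in the wall
#'
#' At each material point the basis is {e_c0, e_l0, e_t0}: e_t0 is the
#' outward transmural normal (normal to the nested ellipsoidal surface
#' through the point), e_l0 is the in-surface meridional direction pointing
#' from apex to base, and e_c0 is the circumferential direction, clockwise
#' when viewing the LV in apex-to-base direction.  The triplet is orthonormal
#' and right-handed.  At the apical pole the basis is taken as the limit
#' along the meridian (e_t0 -> -e_z, e_l0 -> e_r).
#'
#' Vectors are returned in cylindrical components (r, c, z), where the c
#' (circumferential) component multiplies the local e_theta direction; this
#' representation is theta-independent under rotational symmetry.
#'
#' @param geom An [lv_geometry()] object.
#' @param points Matrix with columns (r, z).
#' @return List of three n x 3 matrices `e_c0`, `e_l0`, `e_t0`.
#' @export
local_basis <- function(geom, points) {
  points <- rbind(points)
  n <- nrow(points)
  e_c <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  e_l <- matrix(0, n, 3)
  e_t <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    loc <- chart_locate(geom, points[i, 1], points[i, 2])
    ax <- chart_axes(geom, loc$w)
    psi <- loc$s * chart_psi_base(geom, loc$w)
    # meridian tangent (apex -> base) and outward ellipse normal
    tl <- c(ax$a * cos(psi), 0, ax$c * sin(psi))
    tl <- tl / sqrt(sum(tl^2))
    tn <- c(sin(psi) / ax$a, 0, -cos(psi) / ax$c)
    tn <- tn / sqrt(sum(tn^2))
    e_l[i, ] <- tl
    e_t[i, ] <- tn
  }
  list(e_c0 = e_c, e_l0 = e_l, e_t0 = e_t)
}

#' Convert fiber angles to a unit fiber vector
#'
#' The helix angle `alpha_h` is the angle between e_c0 and the projection of
#' the fiber on the circumferential-longitudinal plane; the transverse angle
#' `alpha_t` is the angle between e_c0 and the projection on the
#' circumferential-transmural plane.
#'
#' @param alpha_h Helix angle(s), rad, in (-pi/2, pi/2].
#' @param alpha_t Transverse angle(s), rad, in (-pi/2, pi/2).
#' @param basis A basis as returned by [local_basis()] (matrices recycled
#'   row-wise against the angles).
#' @return n x 3 matrix of unit fiber vectors (same components as the basis).
#' @export
angles_to_vector <- function(alpha_h, alpha_t, basis) {
  n <- max(length(alpha_h), length(alpha_t), nrow(basis$e_c0))
  alpha_h <- rep_len(alpha_h, n); alpha_t <- rep_len(alpha_t, n)
  bc <- basis$e_c0[rep_len(seq_len(nrow(basis$e_c0)), n), , drop = FALSE]
  bl <- basis$e_l0[rep_len(seq_len(nrow(basis$e_l0)), n), , drop = FALSE]
  bt <- basis$e_t0[rep_len(seq_len(nrow(basis$e_t0)), n), , drop = FALSE]
  if (any(alpha_h <= -pi / 2 - 1e-12 | alpha_h > pi / 2 + 1e-12))
    stop("alpha_h out of range (-pi/2, pi/2]")
  if (any(abs(alpha_t) >= pi / 2 - 1e-12 & abs(abs(alpha_h) - pi / 2) < 1e-12))
    stop("alpha_t must be in (-pi/2, pi/2)")
  out <- matrix(0, n, 3)
  longit <- abs(abs(alpha_h) - pi / 2) < 1e-12
  if (any(longit)) {
    if (any(abs(alpha_t[longit]) > 1e-12))
      stop("zero-length circumferential projection: alpha_h = +/-pi/2 ",
           "requires alpha_t = 0")
    out[longit, ] <- sign(alpha_h[longit]) * bl[longit, , drop = FALSE]
  }
  k <- !longit
  if (any(k)) {
    v <- bc[k, , drop = FALSE] +
      tan(alpha_h[k]) * bl[k, , drop = FALSE] +
      tan(alpha_t[k]) * bt[k, , drop = FALSE]
    out[k, ] <- v / sqrt(rowSums(v^2))
  }
  out
}

#' Recover fiber angles from a fiber vector
#'
#' Fibers are directionless; the vector is first canonicalized to a positive
#' circumferential component (tie-broken by a positive longitudinal
#' component), then the helix and transverse angles are extracted.
#'
#' @param vec n x 3 matrix of fiber vectors (components in the basis frame).
#' @param basis A basis as returned by [local_basis()].
#' @return Data frame with columns `alpha_h`, `alpha_t` (rad).
#' @export
vector_to_angles <- function(vec, basis) {
  vec <- rbind(vec)
  n <- nrow(vec)
  fc <- rowSums(vec * basis$e_c0[rep_len(seq_len(nrow(basis$e_c0)), n), , drop = FALSE])
  fl <- rowSums(vec * basis$e_l0[rep_len(seq_len(nrow(basis$e_l0)), n), , drop = FALSE])
  ft <- rowSums(vec * basis$e_t0[rep_len(seq_len(nrow(basis$e_t0)), n), , drop = FALSE])
  flip <- fc < 0 | (abs(fc) < 1e-14 & fl < 0)
  fc[flip] <- -fc[flip]; fl[flip] <- -fl[flip]; ft[flip] <- -ft[flip]
  alpha_h <- ifelse(abs(fc) < 1e-14, pi / 2, atan2(fl, fc))
  alpha_t <- ifelse(abs(fc) < 1e-14, 0, atan2(ft, fc))
  data.frame(alpha_h = alpha_h, alpha_t = alpha_t)
}

#' Default parameters of the normal (SS) helix-angle distribution
#'
#' The transmural course is the cubic `alpha_h(v) = h0 + h1 v + h3 v^3`,
#' optionally modulated longitudinally by `(1 + bu * u^2)`.  The defaults
#' give +50 deg at the endocardium through -10 deg at midwall to -70 deg at
#' the epicardium, decreasing strictly monotonically across the wall: a
#' right-handed subendocardial helix turning left-handed subepicardially,
#' with a mild epicardial dominance consistent with the observed net
#' counterclockwise apical rotation.  These coefficients are package
#' defaults chosen to reproduce the qualitative normal pattern; they are
#' configuration, not measured values.
#'
#' @param h0,h1,h3 Cubic coefficients (rad).
#' @param bu Longitudinal modulation coefficient (dimensionless).
#' @export
ss_params <- function(h0 = -10 * pi / 180, h1 = -55 * pi / 180,
                      h3 = -5 * pi / 180, bu = 0) {
  list(h0 = h0, h1 = h1, h3 = h3, bu = bu)
}

#' Normal (SS) helix angle
#' @param u,v Normalized wall coordinates.
#' @param par Parameters from [ss_params()].
#' @return Helix angle(s), rad.
#' @export
helix_ss <- function(u, v, par = ss_params()) {
  (par$h0 + par$h1 * v + par$h3 * v^3) * (1 + par$bu * u^2)
}

#' Initial transverse angle
#'
#' The initial transmural distribution of the transverse angle is zero, in
#' both the SS and SIT configurations; a non-zero transverse angle only
#' develops through reorientation.
#' @param u,v Normalized wall coordinates.
#' @export
transverse_initial <- function(u, v) {
  rep(0, max(length(u), length(v)))
}

#' Transition-zone parameters for the SIT helix field
#'
#' The mirror-image (SIT) field equals the normal field below (apical side
#' of) the transition zone and its inversion, -alpha_h, above it.  The zone
#' centre lies at u = u_t + slope * v, so a positive slope places the
#' transition more apically at the endocardium than at the epicardium; the
#' zone has longitudinal extent `height` (u-units) and the blend across it is
#' linear in u.
#'
#' @param u_t Midwall transition location (u-units).
#' @param slope Endo-to-epi tilt of the transition surface (u per v).
#' @param height Longitudinal extent of the blending zone (u-units).
#' @export
transition_params <- function(u_t = 0, slope = 0.2, height = 0.3) {
  stopifnot(height >= 0)
  tp <- list(u_t = u_t, slope = slope, height = height)
  if (abs(u_t) + abs(slope) + height / 2 > 1 + 1e-9)
    stop("transition zone exits the wall: require |u_t| + |slope| + ",
         "height/2 <= 1")
  tp
}

#' Initial SIT helix angle
#'
#' @param u,v Normalized wall coordinates.
#' @param par SS distribution parameters ([ss_params()]).
#' @param tp Transition parameters ([transition_params()]).
#' @return Helix angle(s), rad.
#' @export
helix_sit_initial <- function(u, v, par = ss_params(), tp = transition_params()) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  a_ss <- helix_ss(u, v, par)
  centre <- tp$u_t + tp$slope * v
  if (tp$height == 0) {
    frac <- as.numeric(u > centre)
    frac[u == centre] <- 0.5
  } else {
    frac <- pmin(1, pmax(0, (u - (centre - tp$height / 2)) / tp$height))
  }
  (1 - 2 * frac) * a_ss
}

#' Construct a nodal fiber field on a mesh
#'
#' Evaluates the chosen helix-angle distribution (transverse angle zero) at
#' every meridional node and converts to unit fiber vectors in the local
#' cardiac basis.  The field is stored per node, so it is single-valued and
#' continuous across element boundaries.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param type `"ss"` or `"sit"`.
#' @param par SS helix parameters ([ss_params()]).
#' @param tp Transition parameters ([transition_params()]), used for
#'   `type = "sit"`.
#' @return Object of class `lv_fiber_field`: n x 3 matrix `vec` of unit
#'   vectors in cylindrical components, the nodal basis, angles, and a
#'   provenance tag.
#' @export
fiber_field <- function(mesh, type = c("ss", "sit"), par = ss_params(),
                        tp = transition_params()) {
  type <- match.arg(type)
  uv <- mesh$plane$uv
  alpha_h <- switch(type,
                    ss = helix_ss(uv[, 1], uv[, 2], par),
                    sit = helix_sit_initial(uv[, 1], uv[, 2], par, tp))
  alpha_t <- transverse_initial(uv[, 1], uv[, 2])
  basis <- mesh_basis(mesh)
  vec <- angles_to_vector(alpha_h, alpha_t, basis)
  structure(list(vec = vec, basis = basis, alpha_h = alpha_h,
                 alpha_t = alpha_t, provenance = "parameterized-initial",
                 type = type),
            class = "lv_fiber_field")
}

# Local basis at all meridional nodes (cached on the mesh contents).
mesh_basis <- function(mesh) {
  local_basis(mesh$geom, mesh$plane$nodes)
}

#' Recompute angles of a fiber field against its nodal basis
#' @param field An `lv_fiber_field`.
#' @return The field with `alpha_h`, `alpha_t` refreshed from `vec`.
#' @export
refresh_angles <- function(field) {
  ang <- vector_to_angles(field$vec, field$basis)
  field$alpha_h <- ang$alpha_h
  field$alpha_t <- ang$alpha_t
  field
}

#' Write a fiber field to CSV
#'
#' Columns: node_id, r, z, u, v, alpha_h, alpha_t, fr, fc, fz.
#' @param field An `lv_fiber_field`.
#' @param mesh The mesh it lives on.
#' @param path Output file.
#' @export
write_fiber_csv <- function(field, mesh, path) {
  df <- data.frame(node_id = seq_len(nrow(field$vec)),
                   r = mesh$plane$nodes[, 1], z = mesh$plane$nodes[, 2],
                   u = mesh$plane$uv[, 1], v = mesh$plane$uv[, 2],
                   alpha_h = field$alpha_h, alpha_t = field$alpha_t,
                   fr = field$vec[, 1], fc = field$vec[, 2],
                   fz = field$vec[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Interpolate a nodal (r,c,z)-component field at an arbitrary meridional
# point, using the element shape functions of the structured mesh.
interp_plane_field <- function(mesh, values, r, z) {
  loc <- chart_locate(mesh$geom, r, z)
  nr <- mesh$plane$nr; nl <- mesh$plane$nl
  # element indices from the uniform (s, w) stations
  ir <- min(nr, floor((loc$w + 1) / 2 * nr) + 1)
  jl <- min(nl, floor(loc$s * nl) + 1)
  xi <- ((loc$w + 1) / 2 * nr - (ir - 1)) * 2 - 1
  eta <- (loc$s * nl - (jl - 1)) * 2 - 1
  e <- (jl - 1) * nr + ir
  ids <- mesh$plane$conn[e, ]
  N <- shape2(xi, eta)
  colSums(N * rbind(values)[ids, , drop = FALSE])
}

#' Trace myofiber paths through the wall
#'
#' Integrates streamlines of the unloaded fiber field in 3D Cartesian space
#' with fixed arc-length steps.  Tracing stops when the path leaves the wall
#' or after `max_steps` steps.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param field An `lv_fiber_field` on that mesh.
#' @param seeds Matrix of seed points, columns (x, y, z).
#' @param step Arc-length step (mm).
#' @param max_steps Maximum number of steps per path.
#' @param method `"rk4"` (default) or `"euler"`.
#' @return List of polylines (matrices with columns x, y, z).
#' @export
trace_fiber_paths <- function(mesh, field, seeds, step = 1, max_steps = 2000,
                              method = c("rk4", "euler")) {
  method <- match.arg(method)
  seeds <- rbind(seeds)
  velocity <- function(p) {
    r <- sqrt(p[1]^2 + p[2]^2); th <- atan2(p[2], p[1])
    fcyl <- interp_plane_field(mesh, field$vec, r, p[3])
    fcyl <- fcyl / sqrt(sum(fcyl^2))
    c(cos(th) * fcyl[1] - sin(th) * fcyl[2],
      sin(th) * fcyl[1] + cos(th) * fcyl[2],
      fcyl[3])
  }
  lapply(seq_len(nrow(seeds)), function(is) {
    p <- seeds[is, ]
    # seed must be inside the wall
    chart_locate(mesh$geom, sqrt(p[1]^2 + p[2]^2), p[3])
    path <- matrix(p, 1, 3)
    for (k in seq_len(max_steps)) {
      ok <- TRUE
      pn <- tryCatch({
        if (method == "euler") {
          p + step * velocity(p)
        } else {
          k1 <- velocity(p)
          k2 <- velocity(p + step / 2 * k1)
          k3 <- velocity(p + step / 2 * k2)
          k4 <- velocity(p + step * k3)
          p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }, error = function(e) { ok <<- FALSE; p })
      if (!ok) break
      # stop if the endpoint has left the wall
      inside <- tryCatch({
        chart_locate(mesh$geom, sqrt(pn[1]^2 + pn[2]^2), pn[3]); TRUE
      }, error = function(e) FALSE)
      if (!inside) break
      p <- pn
      path <- rbind(path, p)
    }
    colnames(path) <- c("x", "y", "z")
    path
  })
}
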