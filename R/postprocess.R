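# Function and deformation metrics: phase-wise natural myofiber strains,
# stroke work density, torsion, region statistics, and the
# circumferential-radial shear strain.

#' Natural (logarithmic) fiber strain over a phase
#'
#' `eps = ln(lambda_end / lambda_begin)` with lambda the fiber stretch at
#' the end and begin of the phase.
#'
#' @param cycle A cycle record from [run_cardiac_cycle()].
#' @param phase One of `"ic"`, `"ej"`, `"ir"`, `"fill"`.
#' @return Vector of strains, one per quadrature point.
#' @export
natural_fiber_strain <- function(cycle, phase = c("ic", "ej", "ir", "fill")) {
  phase <- match.arg(phase)
  idx <- which(cycle$phase == phase)
  if (length(idx) == 0) stop("phase '", phase, "' missing from the cycle")
  lam_beg <- if (min(idx) == 1) cycle$lam0 else cycle$lambda_hist[, min(idx) - 1]
  lam_end <- cycle$lambda_hist[, max(idx)]
  log(lam_end / lam_beg)
}

#' Stroke work density from a closed stress-strain loop
#'
#' The area enclosed by the myofiber Cauchy stress versus natural fiber
#' strain loop over one cycle, by trapezoidal integration with explicit
#' closure of the final segment: `W_f = -loop_integral(sigma_f d eps_f)`,
#' positive when the loop is traversed counterclockwise in the
#' (strain, stress) plane, i.e. when the fiber produces work.
#'
#' @param sigma_f Fiber Cauchy stress samples over the cycle (kPa).
#' @param eps_f Natural fiber strain samples at the same instants.
#' @param tol Relative endpoint mismatch above which the loop is considered
#'   open (a warning is issued and the loop is force-closed).
#' @return Work density (kPa = kJ/m^3).
#' @export
stroke_work_density <- function(sigma_f, eps_f, tol = 0.05) {
  stopifnot(length(sigma_f) == length(eps_f), length(sigma_f) >= 3)
  rng <- max(eps_f) - min(eps_f)
  if (rng > 0 && abs(eps_f[length(eps_f)] - eps_f[1]) > tol * rng)
    warning("stress-strain loop is open (endpoint mismatch ",
            signif(abs(eps_f[length(eps_f)] - eps_f[1]), 3),
            "); closing it explicitly")
  s <- c(sigma_f, sigma_f[1])
  e <- c(eps_f, eps_f[1])
  -sum((s[-1] + s[-length(s)]) / 2 * diff(e))
}

#' Stroke work density field over a cycle
#'
#' Applies [stroke_work_density()] at every quadrature point of a cycle
#' record, using the pre-cycle state to close the loop.
#'
#' @param cycle A cycle record from [run_cardiac_cycle()].
#' @return Vector of work densities, one per quadrature point.
#' @export
stroke_work_field <- function(cycle) {
  lam <- cbind(cycle$lam0, cycle$lambda_hist)
  sig <- cbind(cycle$sigf0, cycle$sigf_hist)
  eps <- log(lam / cycle$lam0)
  vapply(seq_len(nrow(lam)),
         function(i) stroke_work_density(sig[i, ], eps[i, ]),
         numeric(1))
}

#' Default analysis region
#'
#' Quadrature points used for mean/SD statistics of the local function
#' parameters: the basal-most and apical-most element layers are excluded
#' (boundary effects of the basal support and the apical pole).
#'
#' @param mesh Mesh.
#' @return Logical vector over quadrature points (element-major, 9 per
#'   element).
#' @export
region_mask <- function(mesh) {
  nr <- mesh$plane$nr; nl <- mesh$plane$nl
  jl <- rep(rep(seq_len(nl), each = nr), each = 9)
  jl > 1 & jl < nl
}

#' Volume-weighted region statistics
#'
#' @param values Field values at quadrature points.
#' @param mask Logical (or index) vector selecting the analysis region.
#' @param weights Quadrature volume weights (from the mesh); equal weights
#'   if omitted.
#' @return List with `mean` and `sd` (volume-weighted).
#' @export
region_stats <- function(values, mask = NULL, weights = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  v <- values[mask]
  if (length(v) == 0) stop("empty region mask")
  w <- if (is.null(weights)) rep(1, length(v)) else weights[mask]
  m <- sum(w * v) / sum(w)
  list(mean = m, sd = sqrt(sum(w * (v - m)^2) / sum(w)))
}

# Interpolate a nodal quantity at a longitudinal level u0 along each
# transmural node line, then average radially.  `vals` is (n_nodes x nt).
interp_level <- function(mesh, vals, u0) {
  ni <- 2 * mesh$plane$nr + 1
  nj <- 2 * mesh$plane$nl + 1
  uu <- matrix(mesh$plane$uv[, 1], ni, nj)   # u per (i, j)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  nt <- ncol(vals)
  acc <- matrix(0, ni, nt)
  for (i in seq_len(ni)) {
    uline <- uu[i, ]
    j1 <- max(which(uline <= u0))
    if (j1 == nj) { j1 <- nj - 1 }
    w <- (u0 - uline[j1]) / (uline[j1 + 1] - uline[j1])
    id1 <- (j1 - 1) * ni + i
    id2 <- j1 * ni + i
    acc[i, ] <- (1 - w) * vals[id1, , drop = FALSE] +
      w * vals[id2, , drop = FALSE]
  }
  colMeans(acc)
}

#' Torsion traces over the cardiac cycle
#'
#' Torsion quantifies the base-to-apex gradient of rotation about the LV
#' long axis.  At each section level the azimuthal rotation of material
#' points is radially averaged and referenced to its value at begin-ejection;
#' the rotation of the basal plane (treated the same way) is subtracted.
#' With `normalize = "rotation"` the trace is this net rotation in rad;
#' with `normalize = "shear"` (the tagging-study convention) it is converted
#' to the circumferential-longitudinal shear angle by multiplying with the
#' mean radius over the axial distance to the base, which makes a uniform
#' twist per unit length read the same at every section.
#'
#' @param mesh Mesh.
#' @param u_hist Displacement history (ndof x nt).
#' @param ref Index of the reference instant (begin-ejection).
#' @param levels Section levels in u (apex-to-base order).
#' @param normalize `"shear"` or `"rotation"`.
#' @param time Optional time vector (ms) attached to the output.
#' @return Data frame (long format): `time`, `section`, `level`, `torsion`
#'   (rad).
#' @export
torsion <- function(mesh, u_hist, ref, levels = c(-0.6, -0.2, 0.2, 0.6),
                    normalize = c("shear", "rotation"), time = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(ref >= 1, ref <= ncol(u_hist))
  if (any(levels <= -1 | levels >= 1))
    stop("section levels must lie strictly inside the wall (-1, 1)")
  n <- nrow(mesh$plane$nodes)
  phi <- u_hist[seq(2, 3 * n, 3), , drop = FALSE]
  nt <- ncol(u_hist)
  if (is.null(time)) time <- seq_len(nt)
  # basal-plane rotation (radially averaged at u = +1, the basal node row)
  ni <- 2 * mesh$plane$nr + 1
  nj <- 2 * mesh$plane$nl + 1
  base_ids <- ((nj - 1) * ni + 1):(nj * ni)
  phi_base <- colMeans(phi[base_ids, , drop = FALSE])
  r_base <- mean(mesh$plane$nodes[base_ids, 1])
  z_base <- mean(mesh$plane$nodes[base_ids, 2])
  out <- NULL
  for (is in seq_along(levels)) {
    ph_i <- interp_level(mesh, phi, levels[is])
    r_i <- interp_level(mesh, mesh$plane$nodes[, 1], levels[is])
    z_i <- interp_level(mesh, mesh$plane$nodes[, 2], levels[is])
    tor <- (ph_i - ph_i[ref]) - (phi_base - phi_base[ref])
    if (normalize == "shear")
      tor <- tor * (r_i + r_base) / 2 / (z_base - z_i)
    out <- rbind(out, data.frame(time = time, section = is,
                                 level = levels[is], torsion = tor))
  }
  attr(out, "normalize") <- normalize
  attr(out, "ref") <- ref
  out
}

#' Circumferential-radial shear strain
#'
#' Green-Lagrange strain component E_cr (circumferential-transmural) in the
#' local cardiac basis, at every quadrature point, for a single displacement
#' state; provided for inspection of the deformation mode.
#'
#' @param mesh Mesh.
#' @param u Displacement vector.
#' @return Vector of E_cr values per quadrature point (element-major).
#' @export
circumferential_radial_shear <- function(mesh, u) {
  arr <- solver_arrays(mesh)
  gp <- cpp_gp_state(arr$nodes, arr$conn0, u,
                     matrix(rep(c(0, 1, 0), each = nrow(arr$nodes)), ncol = 3),
                     matrix(0, arr$nel, 9), matrix(0, arr$nel, 9),
                     c(1, 1), passive_params())
  gpd <- mesh_gp_data(mesh)
  basis <- local_basis(mesh$geom, gpd$pos)
  ngp <- nrow(gpd$pos)
  out <- numeric(ngp)
  for (k in seq_len(ngp)) {
    e <- (k - 1) %/% 9 + 1; q <- (k - 1) %% 9 + 1
    F <- matrix(gp$F[e, ((q - 1) * 9 + 1):(q * 9)], 3, 3, byrow = TRUE)
    E <- 0.5 * (t(F) %*% F - diag(3))
    # basis components (r, c, z) live in the same frame as E's (r, theta, z)
    out[k] <- as.numeric(t(basis$e_c0[k, ]) %*% E %*% basis$e_t0[k, ])
  }
  out
}

#' Phase-wise local function summary of a cycle
#'
#' @param mesh Mesh.
#' @param cycle Cycle record.
#' @return One-row data frame: mean and SD (over the analysis region,
#'   volume-weighted) of the natural fiber strains per phase and the stroke
#'   work density, plus maximum LV pressure (kPa) and stroke volume (mL).
#' @export
cycle_metrics <- function(mesh, cycle) {
  mask <- region_mask(mesh)
  wgt <- mesh_gp_data(mesh)$wgt
  st <- function(v) region_stats(v, mask, wgt)
  e_ic <- st(natural_fiber_strain(cycle, "ic"))
  e_ej <- st(natural_fiber_strain(cycle, "ej"))
  e_ir <- st(natural_fiber_strain(cycle, "ir"))
  wf <- st(stroke_work_field(cycle))
  data.frame(eps_ic_mean = e_ic$mean, eps_ic_sd = e_ic$sd,
             eps_ej_mean = e_ej$mean, eps_ej_sd = e_ej$sd,
             eps_ir_mean = e_ir$mean, eps_ir_sd = e_ir$sd,
             Wf_mean = wf$mean, Wf_sd = wf$sd,
             p_max = max(cycle$p_lv),
             SV = sum(cycle$q_aortic) * cycle$dt)
}

#' Read a torsion-trace CSV
#'
#' Simple exchange format for externally (e.g. tagging-) derived torsion
#' traces: columns `time_ms`, `section_id`, `torsion_rad`.
#'
#' @param path CSV file.
#' @return Data frame with columns `time`, `section`, `torsion`.
#' @export
read_torsion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "section_id", "torsion_rad")
  if (!all(need %in% names(df)))
    stop("torsion CSV must have columns ", paste(need, collapse = ", "))
  data.frame(time = df$time_ms, section = df$section_id,
             torsion = df$torsion_rad)
}

#' Write a torsion trace in the exchange CSV format
#' @param trace Data frame with `time`, `section`, `torsion`.
#' @param path Output file.
#' @export
write_torsion_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time,
                              section_id = trace$section,
                              torsion_rad = trace$torsion),
                   path, row.names = FALSE)
  invisible(path)
}
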