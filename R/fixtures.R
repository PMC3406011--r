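# Synthetic inputs for testing every stage without external data: analytic
# motion fields with closed-form deformation gradients, a tube mesh for the
# classical inflation benchmark, and MRT-like torsion traces.

#' Analytic motion fields on a mesh
#'
#' Generates nodal displacement histories for motions with a closed-form
#' deformation gradient, used as oracles for the kinematics, postprocessing
#' and solver machinery.  Kinds (axisymmetric representation, DOF order
#' (u_r, phi, u_z) per node):
#' * `rigid_rotation`: phi = c(t); in the co-rotating cylindrical frame the
#'   closed-form F is the identity.
#' * `twist`: phi = c(t) (z - z_ref); F = I + c r (e_c x e_z).
#' * `radial_inflation`: r = sqrt(R^2 + a(t)), volume-preserving;
#'   F = diag(R/r, r/R, 1).
#' * `simple_shear`: physical circumferential displacement
#'   u_c = gamma(t) (R - R0); F = I + gamma R0 / R (e_c x e_r), so the
#'   shear amount is exactly gamma at R = R0.
#'
#' @param kind Motion kind.
#' @param mesh Mesh providing the nodes.
#' @param amplitude Peak value of the time profile.
#' @param n_steps Number of time samples over one cycle.
#' @param t_cycle Cycle duration (ms).
#' @param z_ref,R0 Geometric references for `twist` / `simple_shear`.
#' @return List with `u_hist` (ndof x n_steps), `time` (ms), `profile`
#'   (c(t)), and `F_closed(point_rz, k)` returning the closed-form F at a
#'   meridional point for time index k.
#' @export
make_motion <- function(kind = c("rigid_rotation", "twist",
                                 "radial_inflation", "simple_shear"),
                        mesh, amplitude = 0.1, n_steps = 20, t_cycle = 800,
                        z_ref = NULL, R0 = NULL) {
  kind <- match.arg(kind)
  nodes <- mesh$plane$nodes
  n <- nrow(nodes)
  time <- seq_len(n_steps) / n_steps * t_cycle
  prof <- amplitude * sin(2 * pi * time / t_cycle)
  if (is.null(z_ref)) z_ref <- max(nodes[, 2])
  if (is.null(R0)) R0 <- stats::median(nodes[, 1])
  u_hist <- matrix(0, 3 * n, n_steps)
  for (k in seq_len(n_steps)) {
    c_t <- prof[k]
    u <- numeric(3 * n)
    if (kind == "rigid_rotation") {
      u[seq(2, 3 * n, 3)] <- c_t
    } else if (kind == "twist") {
      u[seq(2, 3 * n, 3)] <- c_t * (nodes[, 2] - z_ref)
    } else if (kind == "radial_inflation") {
      r_new <- sqrt(pmax(nodes[, 1]^2 + c_t * 100, 0))
      u[seq(1, 3 * n, 3)] <- r_new - nodes[, 1]
    } else {
      u[seq(2, 3 * n, 3)] <- c_t * (nodes[, 1] - R0) / pmax(nodes[, 1], 1e-9)
    }
    u_hist[, k] <- u
  }
  F_closed <- function(point_rz, k) {
    c_t <- prof[k]
    R <- point_rz[1]
    F <- diag(3)
    if (kind == "twist") {
      F[2, 3] <- c_t * R
    } else if (kind == "radial_inflation") {
      r <- sqrt(R^2 + c_t * 100)
      F[1, 1] <- R / r; F[2, 2] <- r / R
    } else if (kind == "simple_shear") {
      F[2, 1] <- c_t * R0 / R
    }
    F
  }
  list(kind = kind, u_hist = u_hist, time = time, profile = prof,
       F_closed = F_closed, z_ref = z_ref, R0 = R0)
}

#' Rectangular tube mesh for solver benchmarks
#'
#' A thick-walled cylinder segment in the same meridional representation as
#' the LV mesh (9-node biquadratic quads, inner surface tagged like the
#' endocardium so the pressure load applies there).  Used for the classical
#' incompressible inflation benchmark.
#'
#' @param r_in,r_out Inner and outer radii (mm).
#' @param len Axial length (mm).
#' @param nr,nl Element subdivisions (radial, axial).
#' @return Mesh-like list with the `plane` component.
#' @export
mesh_tube <- function(r_in = 10, r_out = 15, len = 10, nr = 4, nl = 2) {
  stopifnot(r_in > 0, r_out > r_in, nr >= 1, nl >= 1)
  ni <- 2L * nr + 1L; nj <- 2L * nl + 1L
  Rs <- seq(r_in, r_out, length.out = ni)
  Zs <- seq(0, len, length.out = nj)
  nodes <- cbind(r = rep(Rs, nj), z = rep(Zs, each = ni))
  conn <- matrix(0L, nr * nl, 9); el <- 0L
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
  endo_els <- which((seq_len(nr * nl) - 1L) %% nr == 0L)
  endo_edges <- cbind(el = endo_els, n1 = conn[endo_els, 1],
                      n2 = conn[endo_els, 4], n3 = conn[endo_els, 7])
  epi_els <- which(seq_len(nr * nl) %% nr == 0L)
  epi_edges <- cbind(el = epi_els, n1 = conn[epi_els, 3],
                     n2 = conn[epi_els, 6], n3 = conn[epi_els, 9])
  grid_id <- function(i, j) (j - 1L) * ni + i
  tags <- list(endo = grid_id(1L, seq_len(nj)),
               epi = grid_id(ni, seq_len(nj)),
               base = grid_id(seq_len(ni), nj),
               bottom = grid_id(seq_len(ni), 1L),
               axis = integer(0),
               endo_base_ring = grid_id(1L, nj))
  list(plane = list(nodes = nodes, conn = conn, uv = NULL, nr = nr, nl = nl,
                    tags = tags, endo_edges = endo_edges,
                    epi_edges = epi_edges))
}

#' Synthetic MRT-like torsion traces
#'
#' Four-section torsion traces over one cycle in the exchange CSV format,
#' mimicking the structure of tagging-derived measurements: a smooth cyclic
#' base pattern per section, additive Gaussian noise, and an optional
#' end-of-cycle drift emulating the loss of tag signal towards the end of
#' the cycle (without drift and noise the traces return exactly to zero at
#' the cycle end).  `template = "ss"` gives homogeneous (equal) section
#' amplitudes; `template = "sit"` grades the amplitude from a normal sign at
#' the apical sections to an inverted sign at the basal ones.
#'
#' @param template `"ss"` or `"sit"`.
#' @param amplitude Peak torsion magnitude (rad).
#' @param noise_sd Additive noise SD (rad).
#' @param drift End-of-cycle drift amplitude (rad).
#' @param n_steps Samples per cycle.
#' @param t_cycle Cycle duration (ms).
#' @param seed RNG seed (required; recorded in the attributes).
#' @return Data frame `time`, `section`, `torsion` with attributes `seed`,
#'   `template`, `params`.
#' @export
make_torsion_set <- function(template = c("ss", "sit"), amplitude = 0.1,
                             noise_sd = 0, drift = 0, n_steps = 40,
                             t_cycle = 800, seed) {
  template <- match.arg(template)
  if (missing(seed)) stop("a seed is required for reproducible fixtures")
  set.seed(seed)
  time <- seq_len(n_steps) / n_steps * t_cycle
  amps <- switch(template,
                 ss = -amplitude * c(1, 1, 1, 1),
                 sit = amplitude * c(-1, -0.5, 0.4, 1))
  g <- sin(pi * time / t_cycle)^2
  out <- NULL
  for (s in 1:4) {
    tor <- amps[s] * g + drift * (time / t_cycle)^2 +
      stats::rnorm(n_steps, sd = noise_sd)
    out <- rbind(out, data.frame(time = time, section = s, torsion = tor))
  }
  attr(out, "seed") <- seed
  attr(out, "template") <- template
  attr(out, "params") <- list(amplitude = amplitude, noise_sd = noise_sd,
                              drift = drift, n_steps = n_steps,
                              t_cycle = t_cycle)
  out
}
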