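# Quasi-static equilibrium solver for the axisymmetric LV model and the
# cardiac-cycle driver coupling it to the circulation.
#
# DOF layout: per meridional node (u_r, phi, u_z) -> dof ids 3n-2, 3n-1, 3n.
# u_r, u_z in mm; phi is the azimuthal rotation angle (rad), whose physical
# displacement is r*phi, so it remains regular on the axis.

#' Solver configuration
#'
#' @param tol_force Absolute Newton tolerance on the residual force
#'   (mN, infinity norm); an additional relative criterion of `tol_rel`
#'   times the initial residual of the step also applies.
#' @param tol_rel Relative residual reduction accepted as converged.
#' @param stall_tol Residual level (mN) below which a stagnating iteration
#'   (no further progress, typically at the finite-difference noise floor
#'   of the tangent) is accepted as converged.
#' @param maxit Maximum Newton iterations per solve.
#' @param max_bisect Maximum load-bisection levels when Newton fails.
#' @param dt Time step of the cardiac-cycle driver (ms).
#' @param vol_tol Isovolumic volume tolerance (mL).
#' @param p_tol Isovolumic pressure tolerance (kPa).
#' @export
solver_config <- function(tol_force = 0.02, tol_rel = 1e-9, stall_tol = 2,
                          maxit = 30, max_bisect = 6, dt = 2,
                          vol_tol = 0.01, p_tol = 1e-3) {
  list(tol_force = tol_force, tol_rel = tol_rel, stall_tol = stall_tol,
       maxit = maxit, max_bisect = max_bisect, dt = dt, vol_tol = vol_tol,
       p_tol = p_tol)
}

# 0-based arrays for the C++ kernels, cached on the mesh object contents
solver_arrays <- function(mesh) {
  list(nodes = mesh$plane$nodes,
       conn0 = mesh$plane$conn - 1L,
       endo0 = mesh$plane$endo_edges[, 2:4, drop = FALSE] - 1L,
       ndof = 3L * nrow(mesh$plane$nodes),
       nel = nrow(mesh$plane$conn))
}

#' Essential boundary conditions of the LV problem
#'
#' Axial displacement is suppressed on the whole basal surface and
#' circumferential displacement on the endocardial basal ring only; on the
#' axis (apical pole segment) radial and circumferential displacements
#' vanish by symmetry.  The epicardium is traction free and the endocardium
#' carries the uniform cavity pressure.
#'
#' @param mesh An [build_mesh()] mesh.
#' @return List with integer `idx` (fixed dof ids) and numeric `val`.
#' @export
lv_fixed_dofs <- function(mesh) {
  tg <- mesh$plane$tags
  idx <- c(3L * (tg$base - 1L) + 3L,          # u_z = 0 on base
           3L * (tg$endo_base_ring - 1L) + 2L, # phi = 0 on endocardial ring
           3L * (tg$axis - 1L) + 1L,          # u_r = 0 on axis
           3L * (tg$axis - 1L) + 2L)          # phi = 0 on axis
  idx <- sort(unique(idx))
  list(idx = idx, val = rep(0, length(idx)))
}

# Expand/normalize the active-drive argument (NULL means fully passive).
act_expand <- function(active, nel) {
  if (is.null(active))
    return(list(amp = matrix(0, nel, 9), lc = matrix(0, nel, 9),
                actv = c(1, 1)))
  amp <- active$amp; lc <- active$lc
  if (length(amp) == 1) amp <- matrix(amp, nel, 9)
  if (length(lc) == 1) lc <- matrix(lc, nel, 9)
  list(amp = amp, lc = lc, actv = active$actv)
}

# One Newton solve at fixed load (p_lv, active drive).  Returns list(u,
# converged, iters, resnorm).
newton_solve <- function(arr, u, fib, act, pas, p_lv, fixed, cfg) {
  free <- setdiff(seq_len(arr$ndof), fixed$idx)
  u[fixed$idx] <- fixed$val
  res0 <- NA_real_
  best <- Inf; stalled <- 0L
  for (it in seq_len(cfg$maxit)) {
    asm <- cpp_assemble(arr$nodes, arr$conn0, u, fib, act$amp, act$lc,
                        act$actv, pas, p_lv, arr$endo0, TRUE)
    if (!asm$ok) return(list(u = u, converged = FALSE, iters = it,
                             resnorm = Inf))
    r <- asm$res[free]
    rn <- max(abs(r))
    if (it == 1) res0 <- max(rn, cfg$tol_force)
    if (rn < best * 0.99) { best <- rn; stalled <- 0L } else
      stalled <- stalled + 1L
    if (rn < max(cfg$tol_force, cfg$tol_rel * res0) ||
        (stalled >= 6L && rn < cfg$stall_tol))
      return(list(u = u, converged = TRUE, iters = it - 1L, resnorm = rn))
    K <- Matrix::sparseMatrix(i = asm$Ki + 1L, j = asm$Kj + 1L, x = asm$Kx,
                              dims = c(arr$ndof, arr$ndof))
    du <- tryCatch(as.numeric(Matrix::solve(K[free, free, drop = FALSE], r)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(u = u, converged = FALSE, iters = it, resnorm = rn))
    # nonmonotone safeguard: Newton residuals may transiently grow on this
    # problem class, so only damp the step on element inversion / blow-up
    step <- 1
    for (ls in 1:10) {
      u_try <- u
      u_try[free] <- u[free] - step * du
      asm2 <- cpp_assemble(arr$nodes, arr$conn0, u_try, fib, act$amp,
                           act$lc, act$actv, pas, p_lv, arr$endo0, FALSE)
      if (asm2$ok && is.finite(max(abs(asm2$res[free]))) &&
          max(abs(asm2$res[free])) < 1e3 * rn) break
      if (ls == 10) return(list(u = u, converged = FALSE, iters = it,
                                resnorm = rn))
      step <- step / 2
    }
    u <- u_try
  }
  asm <- cpp_assemble(arr$nodes, arr$conn0, u, fib, act$amp, act$lc,
                      act$actv, pas, p_lv, arr$endo0, FALSE)
  rn <- if (asm$ok) max(abs(asm$res[free])) else Inf
  list(u = u, converged = rn < max(cfg$tol_force, cfg$tol_rel * res0),
       iters = cfg$maxit, resnorm = rn)
}

#' Solve quasi-static mechanical equilibrium
#'
#' Newton iteration on the total-Lagrangian residual with a consistent
#' (finite-difference) tangent, backtracking line search and, on failure,
#' automatic bisection of the load increment from the last converged state.
#'
#' @param mesh Mesh (LV or any compatible meridional mesh).
#' @param fib n x 3 nodal fiber vectors (cylindrical components).
#' @param active Active drive from [active_drive()], or `NULL` for a fully
#'   passive solve.
#' @param p_lv Cavity pressure (kPa) applied to the endocardial surface.
#' @param u0 Starting displacement vector (3 dofs/node), default zeros.
#' @param fixed Essential BCs, default [lv_fixed_dofs()].
#' @param pas Passive parameters ([passive_params()]).
#' @param cfg [solver_config()].
#' @param p_from Load level associated with `u0` (used when bisecting).
#' @return List with `u`, `iters`, `resnorm`.
#' @export
solve_equilibrium <- function(mesh, fib, active = NULL, p_lv = 0, u0 = NULL,
                              fixed = lv_fixed_dofs(mesh),
                              pas = passive_params(),
                              cfg = solver_config(), p_from = 0) {
  stopifnot(p_lv >= 0)
  arr <- solver_arrays(mesh)
  act <- act_expand(active, arr$nel)
  if (is.null(u0)) u0 <- numeric(arr$ndof)
  sol <- newton_solve(arr, u0, fib, act, pas, p_lv, fixed, cfg)
  if (!sol$converged) {
    # subdivide the pressure increment from the last converged level,
    # doubling the number of substeps until the whole ramp converges
    nsub <- 2L
    for (lev in seq_len(cfg$max_bisect)) {
      ps <- seq(p_from, p_lv, length.out = nsub + 1)[-1]
      u <- u0; ok <- TRUE
      for (p in ps) {
        s <- newton_solve(arr, u, fib, act, pas, p, fixed, cfg)
        if (!s$converged) { ok <- FALSE; break }
        u <- s$u
      }
      if (ok) { sol <- s; break }
      nsub <- 2L * nsub
    }
    if (!sol$converged)
      stop(sprintf(paste0("Newton failed to converge (p_lv = %.4f kPa, ",
                          "residual %.3e mN) despite load substepping"),
                   p_lv, sol$resnorm))
  }
  sol
}

#' Deformed cavity volume
#' @param mesh Mesh.
#' @param u Displacement vector.
#' @return Volume in mL.
#' @export
cavity_volume <- function(mesh, u = NULL) {
  arr <- solver_arrays(mesh)
  if (is.null(u)) u <- numeric(arr$ndof)
  cpp_cavity_volume(arr$nodes, u, arr$endo0) / 1000
}

#' Solve equilibrium at prescribed cavity volume
#'
#' Used during the isovolumic phases (and, with a volume target coming from
#' the circulation flows, during filling and ejection): the cavity pressure
#' is the scalar unknown determined such that mechanical equilibrium holds
#' at the prescribed volume.  Implemented as a bordered Newton iteration on
#' (u, p) with the volume constraint as the extra equation, which is much
#' more robust than nesting a scalar root find around fixed-pressure solves
#' while active stress rises.
#'
#' With `flow` given, the same bordered iteration instead enforces the
#' implicit valve-flow relation `V(u) = V_target - dt (p - p_ext)/R`, which
#' couples the LV to the circulation unconditionally stably during filling
#' and ejection (an explicit flow update becomes unstable as soon as the
#' chamber stiffens so that `R dV/dp < dt`).
#'
#' @inheritParams solve_equilibrium
#' @param V_target Target cavity volume (mL); with `flow`, the start-of-step
#'   volume.
#' @param p0 Initial pressure guess (kPa).
#' @param flow Optional list `(R, p_ext, dt)`: valve resistance
#'   (kPa ms/mL), external compartment pressure (kPa) and time step (ms).
#' @return List `u`, `p_lv`, `V` (mL), `iters`.
#' @export
solve_isovolumic <- function(mesh, fib, active = NULL, V_target, u0 = NULL,
                             p0 = 1, fixed = lv_fixed_dofs(mesh),
                             pas = passive_params(), cfg = solver_config(),
                             flow = NULL) {
  arr <- solver_arrays(mesh)
  act <- act_expand(active, arr$nel)
  if (is.null(u0)) u0 <- numeric(arr$ndof)
  free <- setdiff(seq_len(arr$ndof), fixed$idx)
  u <- u0; u[fixed$idx] <- fixed$val
  p <- p0
  Vt_mm3 <- V_target * 1000
  beta <- 0; p_ext <- 0
  if (!is.null(flow)) {
    beta <- 1000 * flow$dt / flow$R   # mm^3 per kPa over the step
    p_ext <- flow$p_ext
  }
  res0 <- NA_real_
  best <- Inf; stalled <- 0L
  for (it in seq_len(2L * cfg$maxit)) {
    # cheap convergence check before paying for the tangent
    asm <- cpp_assemble(arr$nodes, arr$conn0, u, fib, act$amp, act$lc,
                        act$actv, pas, p, arr$endo0, FALSE)
    if (!asm$ok)
      stop("inverted element during constant-volume solve (p = ",
           signif(p, 4), " kPa)")
    r <- asm$res[free]
    cvol <- cpp_cavity_volume(arr$nodes, u, arr$endo0) - Vt_mm3 +
      beta * (p - p_ext)
    rn <- max(abs(r))
    if (it == 1) res0 <- max(rn, cfg$tol_force)
    if (rn < best * 0.99) { best <- rn; stalled <- 0L } else
      stalled <- stalled + 1L
    if (stalled >= 6L && rn < cfg$stall_tol && abs(cvol) < cfg$vol_tol * 1000)
      return(list(u = u, p_lv = p,
                  V = cpp_cavity_volume(arr$nodes, u, arr$endo0) / 1000,
                  iters = it - 1L))
    if (rn < max(cfg$tol_force, cfg$tol_rel * res0) &&
        abs(cvol) < cfg$vol_tol * 1000)
      return(list(u = u, p_lv = p,
                  V = cpp_cavity_volume(arr$nodes, u, arr$endo0) / 1000,
                  iters = it - 1L))
    asm <- cpp_assemble(arr$nodes, arr$conn0, u, fib, act$amp, act$lc,
                        act$actv, pas, p, arr$endo0, TRUE)
    K <- Matrix::sparseMatrix(i = asm$Ki + 1L, j = asm$Kj + 1L,
                              x = asm$Kx, dims = c(arr$ndof, arr$ndof))
    Kfac <- tryCatch(Matrix::lu(K[free, free, drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(Kfac)) stop("singular tangent in constant-volume solve")
    L <- cpp_pressure_load(arr$nodes, u, arr$endo0)[free]
    gv <- cpp_cavity_gradient(arr$nodes, u, arr$endo0)[free]
    X <- tryCatch(as.matrix(Matrix::solve(Kfac, cbind(r, L))),
                  error = function(e) NULL)
    if (is.null(X) || any(!is.finite(X)))
      stop("singular tangent in constant-volume solve")
    # bordered elimination:
    #   K du - L dp = -r ;  gv . du + beta dp = -cvol
    dp <- (sum(gv * X[, 1]) - cvol) / (sum(gv * X[, 2]) + beta)
    du <- dp * X[, 2] - X[, 1]
    # damped update with a simple backtracking on the merit norm
    merit <- function(uu, pp) {
      a2 <- cpp_assemble(arr$nodes, arr$conn0, uu, fib, act$amp, act$lc,
                         act$actv, pas, pp, arr$endo0, FALSE)
      if (!a2$ok) return(Inf)
      cv <- cpp_cavity_volume(arr$nodes, uu, arr$endo0) - Vt_mm3 +
        beta * (pp - p_ext)
      m <- max(abs(a2$res[free])) + abs(cv)  # mN and mm^3: comparable scales
      if (!is.finite(m)) Inf else m
    }
    m0 <- rn + abs(cvol)
    step <- 1
    accepted <- FALSE
    for (ls in 1:12) {
      u_try <- u; u_try[free] <- u[free] + step * du
      p_try <- p + step * dp
      mv <- merit(u_try, p_try)
      if (is.finite(mv) && (mv < 1e3 * m0 || ls >= 10)) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted)
      stop("constant-volume solve: no admissible step (element inversion)")
    u <- u_try; p <- p_try
  }
  stop(sprintf(paste0("constant-volume solve failed to converge: V_target ",
                      "= %.3f mL, p = %.4f kPa, residual %.3e mN"),
               V_target, p, max(abs(r))))
}

# Per-quadrature-point state wrapper
gp_state <- function(mesh, fib, active, u, pas) {
  arr <- solver_arrays(mesh)
  act <- act_expand(active, arr$nel)
  cpp_gp_state(arr$nodes, arr$conn0, u, fib, act$amp, act$lc, act$actv, pas)
}

# Deformation gradient averaged at nodes
F_at_nodes <- function(mesh, u) {
  arr <- solver_arrays(mesh)
  cpp_F_at_nodes(arr$nodes, arr$conn0, u)
}

# Quadrature-point reference data: positions (r, z), volume weights (mm^3),
# and wall coordinates; used for region statistics and the cardiac basis.
mesh_gp_data <- function(mesh) {
  g3 <- gauss_legendre(3)
  nodes <- mesh$plane$nodes; conn <- mesh$plane$conn
  nel <- nrow(conn)
  pos <- matrix(0, nel * 9, 2); wgt <- numeric(nel * 9)
  k <- 0
  for (e in seq_len(nel)) {
    xy <- nodes[conn[e, ], , drop = FALSE]
    for (q2 in 1:3) for (q1 in 1:3) {
      k <- k + 1
      N <- shape2(g3$x[q1], g3$x[q2])
      dN <- dshape2(g3$x[q1], g3$x[q2])
      J <- t(xy) %*% dN
      detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      R <- sum(N * xy[, 1])
      pos[k, ] <- c(R, sum(N * xy[, 2]))
      wgt[k] <- g3$w[q1] * g3$w[q2] * detJ * 2 * pi * R
    }
  }
  list(pos = pos, wgt = wgt, el = rep(seq_len(nel), each = 9))
}

#' Run one cardiac cycle
#'
#' Advances the coupled LV-circulation system over one cycle of duration
#' `t_cycle`, starting at the onset of activation (begin of isovolumic
#' contraction).  Within each time step the sarcomere state is advanced
#' explicitly, the circulation supplies the volume change during filling and
#' ejection, and mechanical equilibrium is re-solved at the resulting cavity
#' volume (isovolumic phases keep the volume fixed instead).
#'
#' @param mesh Mesh.
#' @param field Fiber field (`lv_fiber_field`).
#' @param sim State list from a previous call (or from [cycle_init()]).
#' @param pas,act,circ Parameter sets.
#' @param cfg [solver_config()].
#' @param record_F Number of instants, spread uniformly over the whole
#'   cycle, at which nodal deformation gradients are recorded for the
#'   reorientation update (end-diastole is always included).
#' @return Updated `sim` with an attached `cycle` record (time series and
#'   per-quadrature-point histories).
#' @export
run_cardiac_cycle <- function(mesh, field, sim, pas = passive_params(),
                              act = active_params(),
                              circ = circulation_params(),
                              cfg = solver_config(), record_F = 12) {
  arr <- solver_arrays(mesh)
  fib <- field$vec
  nt <- ceiling(act$t_cycle / cfg$dt)
  dt <- act$t_cycle / nt
  fixed <- lv_fixed_dofs(mesh)

  u <- sim$u
  cstate <- sim$circ_state
  sar <- sim$sarcomere
  sar$t_a <- 0                      # activation onset at cycle start
  p_lv <- sim$p_lv
  V_lv <- cavity_volume(mesh, u)

  time <- numeric(nt); P <- numeric(nt); V <- numeric(nt)
  Part <- numeric(nt); Pven <- numeric(nt)
  Qm <- numeric(nt); Qa <- numeric(nt); phase <- character(nt)
  lam_h <- matrix(0, arr$nel * 9, nt); sig_h <- matrix(0, arr$nel * 9, nt)
  u_h <- matrix(0, arr$ndof, nt)
  ph <- "ic"
  Fsamp <- list(ed = F_at_nodes(mesh, u))   # end-diastolic sample
  gp <- gp_state(mesh, fib, NULL, u, pas)
  lam <- gp$lambda_f
  lam0 <- as.vector(t(lam)); sigf0 <- as.vector(t(gp$sigma_f)); u_start <- u

  V_book <- V_lv   # circulation-side LV volume (exact flow bookkeeping)
  ej_steps <- integer(0)
  for (k in seq_len(nt)) {
    t <- k * dt
    stp <- active_stress_step(sar, lam, dt, act)
    sar <- stp$state
    drv <- active_drive(sar, lam, act)

    iso_phase <- ph %in% c("ic", "ir")
    cstate <- circulation_pressures(cstate, circ)
    flow <- switch(ph,
                   ej = list(R = circ$R_art, p_ext = cstate$p_art, dt = dt),
                   fill = list(R = circ$R_ven, p_ext = cstate$p_ven,
                               dt = dt),
                   NULL)
    iso <- solve_isovolumic(mesh, fib, drv, V_book, u,
                            max(p_lv, 0.01), fixed, pas, cfg, flow = flow)
    # implied valve flow from the realized volume change; an adverse flow
    # closes the valve for this step (ideal diode: no regurgitation)
    q_m <- 0; q_a <- 0
    if (!iso_phase) {
      dV <- iso$V - V_book
      if ((ph == "ej" && dV > 0) || (ph == "fill" && dV < 0)) {
        iso <- solve_isovolumic(mesh, fib, drv, V_book, u,
                                max(p_lv, 0.01), fixed, pas, cfg)
      } else if (ph == "ej") {
        q_a <- -dV / dt
      } else {
        q_m <- dV / dt
      }
      V_book <- iso$V
    }
    u <- iso$u; p_lv <- iso$p_lv; V_lv <- iso$V
    cstate <- circulation_advance(cstate, q_m, q_a, dt, circ)

    gp <- gp_state(mesh, fib, drv, u, pas)
    lam <- gp$lambda_f
    time[k] <- t; P[k] <- p_lv; V[k] <- V_lv
    Part[k] <- cstate$p_art; Pven[k] <- cstate$p_ven
    Qm[k] <- q_m; Qa[k] <- q_a; phase[k] <- ph
    lam_h[, k] <- as.vector(t(lam)); sig_h[, k] <- as.vector(t(gp$sigma_f))
    u_h[, k] <- u
    if (ph == "ej") ej_steps <- c(ej_steps, k)

    # phase transitions for the next step
    ph <- detect_phase(ph, p_lv, cstate$p_art, cstate$p_ven,
                       activation = FALSE)
  }

  # nodal deformation-gradient samples spread uniformly over the cycle
  # (the continuous reorientation law integrates the stimulus over both the
  # diastolic and the systolic phase); end-diastole is already included
  pick <- unique(round(seq(1, nt, length.out = record_F + 1))[-1])
  for (i in seq_along(pick))
    Fsamp[[paste0("t", pick[i])]] <- F_at_nodes(mesh, u_h[, pick[i]])

  sim$u <- u; sim$circ_state <- cstate; sim$sarcomere <- sar; sim$p_lv <- p_lv
  sim$cycle <- list(time = time, p_lv = P, V_lv = V, p_art = Part,
                    p_ven = Pven, q_mitral = Qm, q_aortic = Qa,
                    phase = phase, lambda_hist = lam_h, sigf_hist = sig_h,
                    u_hist = u_h, lam0 = lam0, sigf0 = sigf0,
                    u_start = u_start, F_samples = Fsamp, dt = dt,
                    ej_steps = ej_steps)
  sim
}

#' Initialize the coupled simulation state
#'
#' Performs the passive preload: the unloaded LV is inflated quasi-statically
#' to the initial venous pressure, defining the end-diastolic state from
#' which the first activation starts.
#'
#' @inheritParams run_cardiac_cycle
#' @return A `sim` state list (`u`, `p_lv`, `circ_state`, `sarcomere`).
#' @export
cycle_init <- function(mesh, field, pas = passive_params(),
                       act = active_params(), circ = circulation_params(),
                       cfg = solver_config()) {
  arr <- solver_arrays(mesh)
  u <- numeric(arr$ndof)
  p_ed <- circ$p_ven_init
  # ramp in a few steps for robustness
  last_p <- 0
  for (p in seq(0.25, 1, by = 0.25) * p_ed) {
    sol <- solve_equilibrium(mesh, field$vec, NULL, p, u, lv_fixed_dofs(mesh),
                             pas, cfg, p_from = last_p)
    u <- sol$u; last_p <- p
  }
  V_lv <- cavity_volume(mesh, u)
  gp <- gp_state(mesh, field$vec, NULL, u, pas)
  list(u = u, p_lv = p_ed,
       circ_state = circulation_init(circ, V_lv),
       sarcomere = sarcomere_init(gp$lambda_f, act))
}
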