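# Shear-induced adaptive myofiber reorientation: the unloaded fiber
# direction evolves towards the deformed fiber direction corrected for
# rigid-body rotation, one update per cardiac cycle.

#' Adaptation configuration
#'
#' @param kappa Adaptation time constant in cycles: each cycle the angular
#'   gap between the unloaded fiber direction and its (cycle-aggregated)
#'   target is reduced by the fraction `min(1, 1/kappa)`.
#' @param n_cycles Number of adaptation cycles to run.
#' @param threshold Steady state is flagged when every tracked function
#'   metric changes by less than this relative amount per cycle.
#' @param weighting `"uniform"` (default) averages the per-instant targets
#'   with equal weights, the discrete analogue of a reorientation rate that
#'   acts continuously throughout the cycle; `"gap"` weights each instant
#'   by its angular gap, emphasizing the high-shear systolic instants.
#' @export
adaptation_config <- function(kappa = 5, n_cycles = 15, threshold = 0.01,
                              weighting = c("uniform", "gap")) {
  stopifnot(kappa > 0, threshold > 0)
  list(kappa = kappa, n_cycles = n_cycles, threshold = threshold,
       weighting = match.arg(weighting))
}

#' Reorientation target direction
#'
#' The deformed fiber direction corrected for rigid-body rotation: with the
#' right polar decomposition F = R U, the target is `U e_f0 / |U e_f0|`,
#' a unit vector in the unloaded frame.  For a pure rotation (U = I), or
#' whenever e_f0 is an eigenvector of U (no fiber/cross-fiber shear), the
#' target equals e_f0 and there is no reorientation drive.
#'
#' @param F Deformation gradient (3 x 3), det F > 0.
#' @param e_f0 Unit fiber vector in the unloaded state.
#' @return Unit target vector.
#' @export
target_direction <- function(F, e_f0) {
  if (det(F) <= 0) stop("polar decomposition requires det F > 0")
  C <- t(F) %*% F
  ee <- eigen((C + t(C)) / 2, symmetric = TRUE)
  U <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  v <- as.numeric(U %*% e_f0)
  v / sqrt(sum(v^2))
}

# Vectorized targets for all nodes: Fn is n x 9 (row-major F per node),
# vec is n x 3.  Returns n x 3 unit targets.
node_targets <- function(Fn, vec) {
  n <- nrow(Fn)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    F <- matrix(Fn[i, ], 3, 3, byrow = TRUE)
    out[i, ] <- target_direction(F, vec[i, ])
  }
  out
}

#' One reorientation update of a fiber field
#'
#' For every node, targets are computed at each sampled instant of the
#' cycle (end-diastole plus instants spread uniformly over the whole cycle,
#' covering the diastolic and systolic phases), sign-aligned with the
#' current direction (fibers are directionless), averaged (uniformly by
#' default, see [adaptation_config()]), and the nodal direction is rotated
#' towards the aggregate target along the geodesic by the fraction
#' `min(1, 1/kappa)` of the gap.
#'
#' @param field `lv_fiber_field`.
#' @param F_samples List of n x 9 nodal deformation-gradient samples (from
#'   a cycle record's `F_samples`).
#' @param cfg [adaptation_config()].
#' @return The updated field (provenance `"adapted"`), with attribute
#'   `max_gap` (rad), the largest nodal angular gap before the update.
#' @export
adapt_fibers <- function(field, F_samples, cfg = adaptation_config()) {
  stopifnot(length(F_samples) >= 1)
  vec <- field$vec
  n <- nrow(vec)
  tsum <- matrix(0, n, 3)
  wsum <- numeric(n)
  use_gap <- identical(cfg$weighting, "gap")
  for (Fs in F_samples) {
    tg <- node_targets(Fs, vec)
    # canonicalize sign against the current direction
    sgn <- sign(rowSums(tg * vec)); sgn[sgn == 0] <- 1
    tg <- tg * sgn
    if (use_gap) {
      dotp <- pmin(1, pmax(-1, rowSums(tg * vec)))
      w <- acos(dotp)
    } else {
      w <- rep(1, n)
    }
    tsum <- tsum + w * tg
    wsum <- wsum + w
  }
  active <- wsum > 1e-14
  newvec <- vec
  max_gap <- 0
  if (any(active)) {
    tbar <- tsum[active, , drop = FALSE] /
      sqrt(rowSums(tsum[active, , drop = FALSE]^2))
    v0 <- vec[active, , drop = FALSE]
    dotp <- pmin(1, pmax(-1, rowSums(tbar * v0)))
    gap <- acos(dotp)
    max_gap <- max(gap)
    f <- min(1, 1 / cfg$kappa)
    # geodesic rotation (slerp) by the fraction f of the gap
    ok <- gap > 1e-14
    th <- gap[ok]
    a <- sin((1 - f) * th) / sin(th)
    b <- sin(f * th) / sin(th)
    nv <- v0
    nv[ok, ] <- a * v0[ok, , drop = FALSE] + b * tbar[ok, , drop = FALSE]
    nv <- nv / sqrt(rowSums(nv^2))
    newvec[active, ] <- nv
  }
  field$vec <- newvec
  field$provenance <- "adapted"
  field <- refresh_angles(field)
  attr(field, "max_gap") <- max_gap
  field
}

#' Run the adaptation loop
#'
#' Alternates cardiac-cycle simulation and fiber reorientation, one update
#' per cycle, recording the local and global function metrics of every
#' cycle.  Cycle 0 is the pre-adaptation cycle (fibers as given).  If the
#' solver fails mid-loop, the history up to the failure is returned with the
#' error attached.
#'
#' @param mesh Mesh.
#' @param field Initial fiber field.
#' @param sim Simulation state (from [cycle_init()] or previous cycles, i.e.
#'   at hemodynamic steady state).
#' @param cfg [adaptation_config()].
#' @param pas,act,circ,scfg Parameter sets ([passive_params()],
#'   [active_params()], [circulation_params()], [solver_config()]).
#' @param keep_fields Record a copy of the fiber field at every cycle.
#' @return List of class `lv_adaptation`: `history` (data frame, one row per
#'   cycle incl. cycle 0), `field` (final), `sim` (final state), `fields`
#'   (optional per-cycle snapshots), `steady_at` (first cycle at which all
#'   metrics changed less than the threshold), `cycles` (list with the first
#'   and last full cycle records), and `error` if the loop was interrupted.
#' @export
run_adaptation <- function(mesh, field, sim, cfg = adaptation_config(),
                           pas = passive_params(), act = active_params(),
                           circ = circulation_params(),
                           scfg = solver_config(), keep_fields = FALSE) {
  history <- NULL
  fields <- if (keep_fields) list() else NULL
  steady_at <- NA_integer_
  err <- NULL
  cycles <- list()
  prev <- NULL
  for (cyc in 0:cfg$n_cycles) {
    res <- tryCatch(
      run_cardiac_cycle(mesh, field, sim, pas, act, circ, scfg),
      error = function(e) e)
    if (inherits(res, "error")) { err <- res; break }
    sim <- res
    met <- cbind(cycle = cyc, cycle_metrics(mesh, sim$cycle))
    history <- rbind(history, met)
    if (cyc == 0) cycles$first <- sim$cycle
    cycles$last <- sim$cycle
    if (keep_fields) fields[[cyc + 1]] <- field
    if (!is.null(prev) && is.na(steady_at)) {
      # per-metric floors keep near-zero strains from dominating the
      # relative-change criterion
      floors <- c(rep(0.005, 6), 0.05, 0.05, 0.1, 0.5)
      rel <- abs(unlist(met[-1]) - unlist(prev[-1])) /
        pmax(abs(unlist(prev[-1])), floors)
      if (all(rel < cfg$threshold)) steady_at <- cyc
    }
    prev <- met
    if (cyc < cfg$n_cycles)
      field <- adapt_fibers(field, sim$cycle$F_samples, cfg)
  }
  structure(list(history = history, field = field, sim = sim,
                 fields = fields, steady_at = steady_at, cycles = cycles,
                 error = err),
            class = "lv_adaptation")
}

#' @export
print.lv_adaptation <- function(x, ...) {
  cat("Myofiber reorientation run:", nrow(x$history), "recorded cycles\n")
  if (!is.null(x$error))
    cat("  interrupted by error:", conditionMessage(x$error), "\n")
  if (!is.na(x$steady_at))
    cat("  steady state reached at cycle", x$steady_at, "\n")
  print(utils::tail(x$history, 3))
  invisible(x)
}
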