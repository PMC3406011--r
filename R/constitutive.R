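# Constitutive behaviour: passive transversely isotropic hyperelasticity and
# an active sarcomere model with a contractile/series-elastic arrangement.
# All coefficients are package defaults from the classical cardiac-mechanics
# model family, exposed through the parameter constructors; they are
# configuration values, not measured quantities.

#' Passive material parameters
#'
#' Strain energy density
#' `W = a0 (exp(a1 tr(E E)) - 1) + af0 (exp(af1 E_f^2) - 1) + kappa/2 (J-1)^2`
#' with E the Green-Lagrange strain, `E_f = e_f0 . E e_f0` the fiber strain
#' and J = det F: a Fung-type exponential of an isotropic quadratic strain
#' invariant, an exponential fiber reinforcement, and a quadratic volumetric
#' penalty enforcing near-incompressibility.
#'
#' @param a0 Isotropic stiffness scale (kPa).
#' @param a1 Isotropic exponential shape coefficient (dimensionless).
#' @param af0 Fiber reinforcement scale (kPa).
#' @param af1 Fiber exponential shape coefficient (dimensionless).
#' @param kappa Bulk penalty modulus (kPa).
#' @param vol_stab Fraction of the penalty integrated at the full 3x3
#'   quadrature rule.  The bulk of the penalty uses a reduced 2x2 rule to
#'   avoid volumetric locking of the biquadratic element; the small full-rule
#'   fraction stabilizes the volumetric hourglass modes the reduced rule
#'   cannot see.
#' @export
passive_params <- function(a0 = 0.4, a1 = 3, af0 = 0.02, af1 = 20,
                           kappa = 2500, vol_stab = 0.2) {
  p <- c(a0 = a0, a1 = a1, af0 = af0, af1 = af1, kappa = kappa,
         vol_stab = vol_stab)
  stopifnot(all(p[1:5] > 0), vol_stab >= 0, vol_stab <= 1)
  p
}

#' Passive Cauchy stress
#'
#' @param F Deformation gradient (3 x 3), det F > 0.
#' @param e_f0 Unit fiber vector in the reference configuration.
#' @param par Parameters from [passive_params()].
#' @return Symmetric Cauchy stress tensor (kPa).
#' @export
passive_stress <- function(F, e_f0, par = passive_params()) {
  stopifnot(abs(sum(e_f0^2) - 1) < 1e-8)
  if (det(F) <= 0) stop("inverted deformation state: det F <= 0")
  cpp_cauchy(F, e_f0, par, 0)
}

#' Total Cauchy stress
#'
#' `sigma = sigma_p(F) + sigma_a * (ef x ef)` with
#' `ef = F e_f0 / |F e_f0|` the current fiber direction.
#'
#' @inheritParams passive_stress
#' @param sigma_a Active fiber Cauchy stress (kPa, scalar >= 0).
#' @export
total_stress <- function(F, e_f0, sigma_a, par = passive_params()) {
  stopifnot(abs(sum(e_f0^2) - 1) < 1e-8, sigma_a >= 0)
  if (det(F) <= 0) stop("inverted deformation state: det F <= 0")
  cpp_cauchy(F, e_f0, par, sigma_a)
}

#' Passive strain-energy density
#' @param E Green-Lagrange strain tensor (3 x 3).
#' @inheritParams passive_stress
#' @return Energy density (kPa = kJ/m^3).
#' @export
strain_energy <- function(E, e_f0, par = passive_params()) {
  cpp_passive_energy(E, e_f0, par)
}

#' Active material parameters
#'
#' Two-element sarcomere model: a contractile element (CE, length `l_c`) in
#' series with a linear series-elastic element (SE).  The active fiber
#' Cauchy stress is
#' `sigma_a = T0 * f_iso(l_c) * f_twitch(t_a, l_s) * (l_s - l_c)/l_se0`
#' (clamped at zero), and the CE evolves by the linearized force-velocity law
#' `dl_c/dt = v0 * ((l_s - l_c)/l_se0 - 1)`.
#' `f_iso = tanh^2(a_iso (l_c - l_c0))` for `l_c > l_c0` expresses the
#' length dependence; the twitch
#' `f_twitch = tanh^2(t_a/tau_r) tanh^2((t_max - t_a)/tau_d)` for
#' `0 < t_a < t_max(l_s)` expresses the time course, with duration
#' `t_max = t_max_ref + b_len (l_s - 2.0)` increasing with sarcomere length.
#' Activation is initiated simultaneously at every point in the wall.
#'
#' @param T0 Stress scale (kPa).
#' @param ls0 Unloaded sarcomere length (um); `l_s = lambda_f * ls0`.
#' @param lse0 SE extension at unit normalized force (um).
#' @param a_iso Length-dependence steepness (1/um).
#' @param lc0 Minimum force-generating CE length (um).
#' @param tau_r,tau_d Twitch rise and decay times (ms).
#' @param t_max_ref Twitch duration at l_s = 2.0 um (ms).
#' @param b_len Twitch-duration length sensitivity (ms/um).
#' @param v0 Unloaded CE velocity scale (um/ms).
#' @param t_cycle Cycle time (ms); the twitch must end within it.
#' @param ls_min,ls_max Admissible sarcomere-length bounds (um).  The lower
#'   bound is generous because material points in the apical pole region of
#'   the axisymmetric chart, where fibers are nearly circumferential at a
#'   very small radius, transiently shorten far below the physiological
#'   working range while bearing no active stress (slack series element).
#' @export
active_params <- function(T0 = 320, ls0 = 1.9, lse0 = 0.04, a_iso = 2.0,
                          lc0 = 1.35, tau_r = 60, tau_d = 220,
                          t_max_ref = 400, b_len = 150, v0 = 0.012,
                          t_cycle = 800, ls_min = 0.7, ls_max = 3.4) {
  stopifnot(T0 > 0, t_max_ref + b_len * 0.4 < t_cycle, ls_min < ls0,
            ls_max > ls0)
  list(T0 = T0, ls0 = ls0, lse0 = lse0, a_iso = a_iso, lc0 = lc0,
       tau_r = tau_r, tau_d = tau_d, t_max_ref = t_max_ref, b_len = b_len,
       v0 = v0, t_cycle = t_cycle, ls_min = ls_min, ls_max = ls_max)
}

# twitch duration as a function of sarcomere length (ms)
active_tmax <- function(l_s, par) par$t_max_ref + par$b_len * (l_s - 2.0)

# scalar/vectorized active Cauchy stress from state
active_sigma <- function(l_c, l_s, t_a, par) {
  fiso <- ifelse(l_c > par$lc0, tanh(par$a_iso * (l_c - par$lc0))^2, 0)
  tmax <- active_tmax(l_s, par)
  ftw <- ifelse(t_a > 0 & t_a < tmax,
                tanh(t_a / par$tau_r)^2 * tanh((tmax - t_a) / par$tau_d)^2, 0)
  s <- par$T0 * fiso * ftw * (l_s - l_c) / par$lse0
  s[s < 0] <- 0
  s
}

#' Advance the sarcomere state by one time step
#'
#' Explicitly integrates the contractile-element length with 1-ms sub-steps
#' and returns the active fiber stress at the end of the step.  Works
#' elementwise on arrays, so a whole field of quadrature points can be
#' advanced in one call.
#'
#' @param state List with `l_c` (um, any numeric shape) and `t_a` (ms, time
#'   since activation at the *start* of the step; `t_a <= 0` means not yet
#'   activated).
#' @param lambda_f Fiber stretch(es), same shape as `state$l_c`.
#' @param dt Time step (ms), > 0.
#' @param par Parameters from [active_params()].
#' @return List with `sigma_a` (kPa, same shape), and the updated `state`.
#' @export
active_stress_step <- function(state, lambda_f, dt, par = active_params()) {
  stopifnot(dt > 0)
  l_s <- lambda_f * par$ls0
  bad <- !is.finite(l_s) | l_s < par$ls_min | l_s > par$ls_max
  if (any(bad))
    stop("sarcomere length out of admissible bounds at index ",
         which(bad)[1], " (l_s = ", signif(l_s[which(bad)[1]], 4), " um)")
  l_c <- state$l_c
  n_sub <- max(1L, ceiling(dt / 1))
  h <- dt / n_sub
  for (k in seq_len(n_sub))
    l_c <- l_c + h * par$v0 * ((l_s - l_c) / par$lse0 - 1)
  t_a <- state$t_a + dt
  sigma_a <- active_sigma(l_c, l_s, t_a, par)
  list(sigma_a = sigma_a, state = list(l_c = l_c, t_a = t_a))
}

#' Active drive for the implicit solver coupling
#'
#' Within a quasi-static solve the contractile-element length and the twitch
#' factor are held fixed while the series-elastic stress follows the current
#' fiber stretch: `sigma_a = max(0, amp * (lambda_f ls0 - l_c)/lse0)` with
#' `amp = T0 f_iso(l_c) f_twitch(t_a, l_s)`.  This function packages the
#' frozen quantities for [solve_equilibrium()]/[solve_isovolumic()].
#'
#' @param state Sarcomere state (after [active_stress_step()]).
#' @param lambda_f Fiber stretches used to freeze the twitch duration.
#' @param par [active_params()].
#' @return List with matrices `amp`, `lc` and the vector `actv = c(ls0, lse0)`.
#' @export
active_drive <- function(state, lambda_f, par = active_params()) {
  l_s <- lambda_f * par$ls0
  l_c <- state$l_c
  t_a <- state$t_a
  fiso <- ifelse(l_c > par$lc0, tanh(par$a_iso * (l_c - par$lc0))^2, 0)
  tmax <- active_tmax(l_s, par)
  ftw <- ifelse(t_a > 0 & t_a < tmax,
                tanh(t_a / par$tau_r)^2 * tanh((tmax - t_a) / par$tau_d)^2, 0)
  list(amp = par$T0 * fiso * ftw, lc = l_c, actv = c(par$ls0, par$lse0))
}

#' Initial sarcomere state at passive equilibrium
#' @param lambda_f Fiber stretch(es).
#' @param par Parameters from [active_params()].
#' @param t_a Initial time since activation (ms), default -Inf-like inactive.
#' @export
sarcomere_init <- function(lambda_f, par = active_params(), t_a = 0) {
  list(l_c = lambda_f * par$ls0 - par$lse0, t_a = t_a)
}
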