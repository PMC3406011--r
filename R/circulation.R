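# Lumped-parameter systemic circulation: the LV fills from a venous
# compartment through the mitral valve and ejects into an arterial
# compartment through the aortic valve; a peripheral resistance returns
# blood from arteries to veins.  Valves are ideal diodes.

#' Circulation parameters
#'
#' Defaults are tuned to the human systemic circulation scale (mean arterial
#' pressure near 12 kPa and cardiac output in the 5 L/min class at a cycle
#' time of 800 ms); they are configuration values of this package.
#'
#' @param R_art Aortic (characteristic) resistance, kPa ms/mL.
#' @param R_per Peripheral resistance, kPa ms/mL.
#' @param R_ven Venous (mitral inflow) resistance, kPa ms/mL.
#' @param C_art Arterial compliance, mL/kPa.
#' @param C_ven Venous compliance, mL/kPa.
#' @param V_art0,V_ven0 Zero-pressure compartment volumes, mL.
#' @param p_art_init,p_ven_init Initial compartment pressures, kPa.
#' @export
circulation_params <- function(R_art = 6, R_per = 150, R_ven = 4,
                               C_art = 10, C_ven = 600,
                               V_art0 = 500, V_ven0 = 2500,
                               p_art_init = 11.5, p_ven_init = 1.4) {
  p <- list(R_art = R_art, R_per = R_per, R_ven = R_ven,
            C_art = C_art, C_ven = C_ven,
            V_art0 = V_art0, V_ven0 = V_ven0,
            p_art_init = p_art_init, p_ven_init = p_ven_init)
  stopifnot(all(unlist(p) > 0))
  p
}

#' Initial circulation state
#'
#' @param par [circulation_params()].
#' @param V_lv Initial LV cavity volume (mL), used only to fix the conserved
#'   total blood volume.
#' @return List with compartment volumes, derived pressures, valve states
#'   and the total blood volume.
#' @export
circulation_init <- function(par, V_lv) {
  V_art <- par$V_art0 + par$C_art * par$p_art_init
  V_ven <- par$V_ven0 + par$C_ven * par$p_ven_init
  state <- list(V_art = V_art, V_ven = V_ven,
                mitral = FALSE, aortic = FALSE,
                V_total = V_art + V_ven + V_lv)
  circulation_pressures(state, par)
}

circulation_pressures <- function(state, par) {
  state$p_art <- (state$V_art - par$V_art0) / par$C_art
  state$p_ven <- (state$V_ven - par$V_ven0) / par$C_ven
  state
}

#' Advance the circulation by one time step
#'
#' Valve logic: the mitral valve conducts iff `p_ven > p_lv`, the aortic
#' valve iff `p_lv > p_art`.  Compartment volumes are updated conservatively
#' (every flow leaves one volume and enters another); pressures follow from
#' the linear compliances, with the peripheral flow integrated
#' backward-Euler in the arterial/venous pair.
#'
#' @param state Circulation state (see [circulation_init()]).
#' @param p_lv LV pressure (kPa) held during the step.
#' @param dt Time step (ms).
#' @param par [circulation_params()].
#' @param allow_mitral,allow_aortic Set `FALSE` to hold a valve shut
#'   regardless of the pressure gradient (used by the cycle driver during
#'   the isovolumic phases, where both valves are closed by definition).
#' @return List `state` (advanced), `q_mitral`, `q_aortic` (mL/ms, >= 0).
#' @export
circulation_step <- function(state, p_lv, dt, par, allow_mitral = TRUE,
                             allow_aortic = TRUE) {
  stopifnot(dt > 0)
  state <- circulation_pressures(state, par)
  q_mit <- if (allow_mitral && state$p_ven > p_lv)
    (state$p_ven - p_lv) / par$R_ven else 0
  q_ao <- if (allow_aortic && p_lv > state$p_art)
    (p_lv - state$p_art) / par$R_art else 0
  state <- circulation_advance(state, q_mit, q_ao, dt, par)
  list(state = state, q_mitral = q_mit, q_aortic = q_ao)
}

# Advance the arterial/venous compartments by one step given the LV valve
# flows (mL/ms): conservative transfer plus the peripheral exchange through
# R_per, integrated backward-Euler on the compartment pair.
circulation_advance <- function(state, q_mit, q_ao, dt, par) {
  state <- circulation_pressures(state, par)
  tau <- par$R_per * par$C_art * par$C_ven / (par$C_art + par$C_ven)
  dp0 <- state$p_art - state$p_ven
  dp1 <- dp0 / (1 + dt / tau)
  q_per_mean <- (dp0 - dp1) * tau / (par$R_per * dt)   # average flow over dt

  V_art <- state$V_art + dt * (q_ao - q_per_mean)
  V_ven <- state$V_ven + dt * (q_per_mean - q_mit)
  if (V_art <= 0 || V_ven <= 0)
    stop("negative compartment volume in circulation step; state: ",
         paste(sprintf("%s=%.3f", c("V_art", "V_ven"),
                       c(V_art, V_ven)), collapse = ", "))
  state$V_art <- V_art
  state$V_ven <- V_ven
  state$mitral <- q_mit > 0
  state$aortic <- q_ao > 0
  circulation_pressures(state, par)
}

#' Phase detection over the cardiac cycle
#'
#' Deterministic transitions in the canonical order
#' isovolumic contraction (ic) -> ejection (ej) -> isovolumic relaxation
#' (ir) -> filling (fill): ic ends when the aortic valve opens
#' (`p_lv >= p_art`), ejection ends when it closes (aortic forward flow
#' ceases), ir ends when the mitral valve opens (`p_lv <= p_ven`), and
#' filling ends at the onset of activation (start of the next cycle).
#'
#' @param prev Previous phase label, one of `"ic"`, `"ej"`, `"ir"`, `"fill"`.
#' @param p_lv,p_art,p_ven Current pressures (kPa).
#' @param activation `TRUE` at the time step where activation (re)starts.
#' @return The new phase label.
#' @export
detect_phase <- function(prev, p_lv, p_art, p_ven, activation = FALSE) {
  next_of <- c(ic = "ej", ej = "ir", ir = "fill", fill = "ic")
  cand <- switch(prev,
                 ic = if (p_lv >= p_art) "ej" else "ic",
                 ej = if (p_lv < p_art) "ir" else "ej",
                 ir = if (p_lv <= p_ven) "fill" else "ir",
                 fill = if (activation) "ic" else "fill",
                 stop("unknown phase label: ", prev))
  if (cand != prev && cand != unname(next_of[prev]))
    stop("out-of-order phase transition ", prev, " -> ", cand)
  cand
}
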