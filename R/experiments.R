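# Reproducible experiment layer: named presets for the normal (SS) and the
# three mirror-image (SIT) configurations (transition at base / mid / apex),
# plus the transition-shape variants; a run driver that executes the whole
# protocol (mesh -> fibers -> spin-up cycles at frozen fibers -> adaptation
# cycles -> postprocessing) into a run directory with manifest and CSV/VTK
# outputs; and a run comparison table.

#' Experiment presets
#'
#' The four headline configurations differ only in the fiber block: `ss`
#' uses the normal helix field; `base`, `mid`, `apex` use the mirror-image
#' field with the transition zone centred at u_t = +0.4, 0, -0.4.  The
#' additional variants modify the transition shape of `mid`: `mid_s0`
#' (slope 0), `mid_s90` (steepest slope that keeps the zone inside the
#' wall), `mid_h0` (sharp transition, height 0) and `mid_hlarge`
#' (height 0.8).
#'
#' @param name Preset name.
#' @param reduced Use the reduced test resolution (3 x 1 x 5 elements,
#'   dt = 4 ms) instead of the full 6 x 1 x 10, dt = 2 ms.
#' @param n_spinup Hemodynamic spin-up cycles with frozen fibers.
#' @param n_adapt Adaptation cycles.
#' @param seed RNG seed recorded in the manifest.
#' @return A `RunConfig` list.
#' @export
experiment_preset <- function(name = c("ss", "base", "mid", "apex",
                                       "mid_s0", "mid_s90", "mid_h0",
                                       "mid_hlarge"),
                              reduced = FALSE, n_spinup = 10, n_adapt = 15,
                              seed = 1) {
  name <- match.arg(name)
  fiber <- switch(name,
    ss = list(type = "ss", tp = NULL),
    base = list(type = "sit", tp = transition_params(u_t = 0.4)),
    mid = list(type = "sit", tp = transition_params(u_t = 0)),
    apex = list(type = "sit", tp = transition_params(u_t = -0.4)),
    mid_s0 = list(type = "sit", tp = transition_params(u_t = 0, slope = 0)),
    mid_s90 = list(type = "sit", tp = transition_params(u_t = 0, slope = 0.85)),
    mid_h0 = list(type = "sit", tp = transition_params(u_t = 0, height = 0)),
    mid_hlarge = list(type = "sit",
                      tp = transition_params(u_t = 0, height = 0.8)))
  list(name = name,
       geometry = list(wall_volume = 136, cavity_volume = 44,
                       truncation = 0.5, shape_endo = 2.0, shape_epi = 1.4),
       subdivisions = if (reduced) c(3, 1, 5) else c(6, 1, 10),
       fiber = c(fiber, list(ss = ss_params())),
       passive = as.list(passive_params()),
       active = active_params(),
       circulation = circulation_params(),
       solver = list(dt = if (reduced) 4 else 2),
       adaptation = list(kappa = 5, n_spinup = n_spinup, n_adapt = n_adapt,
                         threshold = 0.01),
       postprocess = list(levels = c(-0.6, -0.2, 0.2, 0.6),
                          normalize = "shear"),
       seed = seed)
}

#' Load a run configuration from a YAML file
#'
#' The file may override any subset of an [experiment_preset()]; the `name`
#' key selects the preset providing the remaining defaults.
#'
#' @param path YAML file.
#' @return A `RunConfig` list.
#' @export
read_run_config <- function(path) {
  ov <- yaml::read_yaml(path)
  base <- experiment_preset(if (is.null(ov$name)) "ss" else ov$name,
                            reduced = isTRUE(ov$reduced))
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  ov$reduced <- NULL
  merge_lists(base, ov)
}

config_objects <- function(config) {
  geom <- do.call(lv_geometry, config$geometry)
  mesh <- build_mesh(geom, config$subdivisions)
  ssp <- do.call(ss_params, config$fiber$ss[c("h0", "h1", "h3", "bu")])
  field <- if (config$fiber$type == "ss") {
    fiber_field(mesh, "ss", ssp)
  } else {
    tp <- config$fiber$tp
    fiber_field(mesh, "sit", ssp,
                transition_params(tp$u_t, tp$slope, tp$height))
  }
  pas <- do.call(passive_params, config$passive)
  act <- do.call(active_params, config$active[names(config$active) %in%
                                                names(formals(active_params))])
  circ <- do.call(circulation_params,
                  config$circulation[names(config$circulation) %in%
                                       names(formals(circulation_params))])
  scfg <- solver_config(dt = config$solver$dt)
  list(geom = geom, mesh = mesh, field = field, pas = pas, act = act,
       circ = circ, scfg = scfg)
}

#' Run a full experiment
#'
#' Executes the complete protocol of one configuration: build mesh and
#' initial fiber field, passive preload, `n_spinup` cardiac cycles with
#' frozen fibers to reach a hemodynamic steady state, then `n_adapt`
#' adaptation cycles with one fiber update per cycle, and postprocessing.
#' All outputs are written into `out_dir`: `manifest.json` (full echoed
#' configuration and summary), `hemodynamics.csv` (last cycle),
#' `adaptation.csv` (per-cycle metrics), `spinup.csv`,
#' `torsion_pre.csv` / `torsion_post.csv`, `fiber_initial.csv` /
#' `fiber_final.csv` and `fields/*.vtu`.  A checkpoint is kept per
#' adaptation cycle, so an interrupted run can be resumed with
#' `resume = TRUE`.
#'
#' @param config A `RunConfig` ([experiment_preset()] or
#'   [read_run_config()]).
#' @param out_dir Run directory (created if needed).
#' @param resume Continue from the checkpoint in `out_dir` if present.
#' @param quiet Suppress per-cycle progress lines.
#' @return The run directory, invisibly, with the results attached as
#'   attributes (`history`, `adaptation`).
#' @export
run_experiment <- function(config, out_dir, resume = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "fields"), showWarnings = FALSE)
  set.seed(config$seed)
  ob <- config_objects(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  ckpt_file <- file.path(out_dir, "checkpoint.rds")
  spin_hist <- NULL
  if (resume && file.exists(ckpt_file)) {
    ck <- readRDS(ckpt_file)
    sim <- ck$sim; field <- ck$field; spin_hist <- ck$spin_hist
    say("resuming from checkpoint (after spin-up)")
  } else {
    field <- ob$field
    write_fiber_csv(field, ob$mesh, file.path(out_dir, "fiber_initial.csv"))
    write_vtu_plane(ob$mesh, file.path(out_dir, "fields", "mesh.vtu"),
                    point_data = list(alpha_h = field$alpha_h,
                                      alpha_t = field$alpha_t))
    sim <- cycle_init(ob$mesh, field, ob$pas, ob$act, ob$circ, ob$scfg)
    for (i in seq_len(config$adaptation$n_spinup)) {
      sim <- run_cardiac_cycle(ob$mesh, field, sim, ob$pas, ob$act, ob$circ,
                               ob$scfg)
      met <- cbind(cycle = i, cycle_metrics(ob$mesh, sim$cycle))
      spin_hist <- rbind(spin_hist, met)
      say("spin-up cycle %d/%d: SV %.1f mL, p_max %.1f kPa", i,
          config$adaptation$n_spinup, met$SV, met$p_max)
    }
    utils::write.csv(spin_hist, file.path(out_dir, "spinup.csv"),
                     row.names = FALSE)
    saveRDS(list(sim = sim, field = field, spin_hist = spin_hist), ckpt_file)
  }

  acfg <- adaptation_config(config$adaptation$kappa,
                            config$adaptation$n_adapt,
                            config$adaptation$threshold)
  ad <- run_adaptation(ob$mesh, field, sim, acfg, ob$pas, ob$act, ob$circ,
                       ob$scfg)
  if (!is.null(ad$error))
    warning("adaptation interrupted: ", conditionMessage(ad$error))
  utils::write.csv(ad$history, file.path(out_dir, "adaptation.csv"),
                   row.names = FALSE)
  write_fiber_csv(ad$field, ob$mesh, file.path(out_dir, "fiber_final.csv"))

  # hemodynamics and torsion of the first (pre-adaptation) and last cycle
  for (tag in c("pre", "post")) {
    cy <- if (tag == "pre") ad$cycles$first else ad$cycles$last
    if (is.null(cy)) next
    ej0 <- if (length(cy$ej_steps)) min(cy$ej_steps) else 1L
    tor <- torsion(ob$mesh, cy$u_hist, ej0, config$postprocess$levels,
                   config$postprocess$normalize, time = cy$time)
    write_torsion_csv(tor, file.path(out_dir,
                                     paste0("torsion_", tag, ".csv")))
    if (tag == "post") {
      utils::write.csv(data.frame(t = cy$time, p_lv = cy$p_lv,
                                  V_lv = cy$V_lv, p_art = cy$p_art,
                                  p_ven = cy$p_ven, q_mitral = cy$q_mitral,
                                  q_aortic = cy$q_aortic, phase = cy$phase),
                       file.path(out_dir, "hemodynamics.csv"),
                       row.names = FALSE)
      write_vtu_plane(ob$mesh, file.path(out_dir, "fields",
                                         "final_state.vtu"),
                      point_data = list(alpha_h = ad$field$alpha_h,
                                        alpha_t = ad$field$alpha_t),
                      u = ad$sim$u)
      write_vtu_revolved(ob$mesh, file.path(out_dir, "fields",
                                            "final_state_3d.vtu"),
                         u = ad$sim$u,
                         point_data = list(alpha_h = ad$field$alpha_h,
                                           alpha_t = ad$field$alpha_t))
    }
  }

  manifest <- list(config = config,
                   package_version =
                     as.character(utils::packageVersion("lvfiber")),
                   n_elements = ob$mesh$n_elements,
                   steady_at = ad$steady_at,
                   final = as.list(utils::tail(ad$history, 1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  out <- out_dir
  attr(out, "spinup") <- spin_hist
  attr(out, "adaptation") <- ad
  invisible(out)
}

#' Compare completed runs
#'
#' @param dirs Named character vector of run directories.
#' @return Data frame with one row per run and stage (pre/post adaptation)
#'   and the local/global metric columns; incomplete runs are listed with
#'   `NA` metrics.
#' @export
compare_runs <- function(dirs) {
  if (is.null(names(dirs))) names(dirs) <- basename(dirs)
  out <- NULL
  incomplete <- character(0)
  for (nm in names(dirs)) {
    f <- file.path(dirs[[nm]], "adaptation.csv")
    if (!file.exists(f)) {
      incomplete <- c(incomplete, nm)
      next
    }
    h <- utils::read.csv(f)
    pre <- cbind(run = nm, stage = "pre", h[1, -1, drop = FALSE])
    post <- cbind(run = nm, stage = "post",
                  h[nrow(h), -1, drop = FALSE])
    out <- rbind(out, pre, post)
  }
  if (length(incomplete) > 0)
    for (nm in incomplete) {
      row <- out[NA_integer_, , drop = FALSE][1, , drop = FALSE]
      row$run <- nm; row$stage <- "incomplete"
      out <- rbind(out, row)
    }
  rownames(out) <- NULL
  out
}
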