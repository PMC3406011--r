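tiny_cfg <- function(name, seed = 1) {
  cfg <- experiment_preset(name, reduced = TRUE, n_spinup = 1, n_adapt = 1,
                           seed = seed)
  cfg$solver$dt <- 8
  cfg
}

test_that("presets differ only in the fiber block", {
  ps <- lapply(c("ss", "base", "mid", "apex"), experiment_preset)
  strip <- function(p) p[setdiff(names(p), c("name", "fiber"))]
  for (i in 2:4) expect_equal(strip(ps[[i]]), strip(ps[[1]]))
  # the three SIT presets vary u_t only
  expect_equal(ps[[2]]$fiber$tp$u_t, 0.4)
  expect_equal(ps[[3]]$fiber$tp$u_t, 0)
  expect_equal(ps[[4]]$fiber$tp$u_t, -0.4)
  expect_equal(ps[[2]]$fiber$tp$slope, ps[[4]]$fiber$tp$slope)
  expect_equal(ps[[2]]$fiber$tp$height, ps[[4]]$fiber$tp$height)
  # shape variants
  expect_equal(experiment_preset("mid_s0")$fiber$tp$slope, 0)
  expect_equal(experiment_preset("mid_h0")$fiber$tp$height, 0)
})

test_that("a run directory contains the full provenance and outputs", {
  d <- file.path(tempdir(), "lvfiber_tiny_ss")
  run_experiment(tiny_cfg("ss"), d, quiet = TRUE)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(file.exists(file.path(d, "hemodynamics.csv")))
  expect_true(file.exists(file.path(d, "adaptation.csv")))
  expect_true(file.exists(file.path(d, "torsion_pre.csv")))
  expect_true(file.exists(file.path(d, "fiber_final.csv")))
  expect_true(file.exists(file.path(d, "fields", "mesh.vtu")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$config$name, "ss")
  expect_equal(man$n_elements, 15L)
  expect_true(!is.null(man$config$passive$a0))  # defaults echoed
  h <- utils::read.csv(file.path(d, "adaptation.csv"))
  expect_true(all(c("eps_ic_mean", "eps_ej_mean", "eps_ir_mean", "Wf_mean",
                    "p_max", "SV") %in% names(h)))
})

test_that("zero adaptation cycles yield only the pre-adaptation record", {
  cfg <- tiny_cfg("mid")
  cfg$adaptation$n_adapt <- 0
  d <- file.path(tempdir(), "lvfiber_tiny_mid0")
  run_experiment(cfg, d, quiet = TRUE)
  h <- utils::read.csv(file.path(d, "adaptation.csv"))
  expect_equal(nrow(h), 1L)
  f0 <- utils::read.csv(file.path(d, "fiber_initial.csv"))
  f1 <- utils::read.csv(file.path(d, "fiber_final.csv"))
  expect_equal(f1$alpha_h, f0$alpha_h, tolerance = 1e-12)
})

test_that("reruns with the same config and seed are deterministic", {
  d1 <- file.path(tempdir(), "lvfiber_det_1")
  d2 <- file.path(tempdir(), "lvfiber_det_2")
  run_experiment(tiny_cfg("ss", seed = 7), d1, quiet = TRUE)
  run_experiment(tiny_cfg("ss", seed = 7), d2, quiet = TRUE)
  h1 <- utils::read.csv(file.path(d1, "adaptation.csv"))
  h2 <- utils::read.csv(file.path(d2, "adaptation.csv"))
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_identical(readLines(file.path(d1, "torsion_post.csv")),
                   readLines(file.path(d2, "torsion_post.csv")))
})

test_that("run comparison tabulates pre/post metrics and flags incomplete runs", {
  d <- file.path(tempdir(), "lvfiber_tiny_ss")  # created above
  tab <- compare_runs(c(one = d, two = d))
  expect_true(all(c("run", "stage", "eps_ic_mean", "eps_ej_mean",
                    "eps_ir_mean", "Wf_mean", "p_max", "SV") %in%
                    names(tab)))
  # comparing a run with itself: zero differences
  pre <- tab[tab$stage == "pre", ]
  expect_equal(pre[pre$run == "one", -1], pre[pre$run == "two", -1],
               ignore_attr = TRUE)
  tab2 <- compare_runs(c(good = d, missing = tempfile()))
  expect_true("incomplete" %in% tab2$stage)
})

test_that("YAML configuration overrides merge into presets", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("name: mid", "reduced: yes",
               "adaptation:", "  n_adapt: 3",
               "fiber:", "  tp:", "    u_t: 0.15"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$name, "mid")
  expect_equal(cfg$adaptation$n_adapt, 3)
  expect_equal(cfg$fiber$tp$u_t, 0.15)
  expect_equal(cfg$subdivisions, c(3, 1, 5))
  # untouched blocks keep preset defaults
  expect_equal(cfg$fiber$tp$height, 0.3)
  expect_equal(cfg$adaptation$kappa, 5)
})
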