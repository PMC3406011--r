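test_that("the target direction removes rigid rotation and fixes U-eigenvectors", {
  set.seed(5)
  ef <- c(0.4, 0.8, 0.45); ef <- ef / sqrt(sum(ef^2))
  for (k in 1:20) {
    Q <- random_rotation()
    expect_equal(target_direction(Q, ef), ef, tolerance = 1e-12)
    # eigenvector of U: no fiber/cross-fiber shear, no drive
    U <- diag(c(1.2, 0.9, 1.05))
    ei <- c(1, 0, 0)
    expect_equal(target_direction(Q %*% U, ei), ei, tolerance = 1e-12)
    # superposing a rigid rotation never changes the target
    F <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    if (det(F) <= 0) next
    expect_equal(target_direction(Q %*% F, ef), target_direction(F, ef),
                 tolerance = 1e-10)
  }
  expect_error(target_direction(diag(c(-1, 1, 1)), ef), "det F")
})

test_that("the target matches an SVD-based polar decomposition for simple shear", {
  gam <- 0.3
  F <- diag(3); F[1, 2] <- gam
  ef <- c(0, 1, 0)
  sv <- svd(F)
  U_svd <- sv$v %*% diag(sv$d) %*% t(sv$v)
  expected <- as.numeric(U_svd %*% ef); expected <- expected / sqrt(sum(expected^2))
  expect_equal(target_direction(F, ef), expected, tolerance = 1e-12)
})

test_that("the fiber update is a fixed point at zero gap and a full step at kappa = 1", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  n <- nrow(f$vec)
  # identity deformation everywhere: no change
  F_id <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), n), n, 9, byrow = TRUE)
  f2 <- adapt_fibers(f, list(F_id), adaptation_config(kappa = 5))
  expect_equal(f2$vec, f$vec, tolerance = 1e-12)
  # kappa = 1: the new direction equals the target
  gam <- 0.25
  F_sh <- matrix(rep(c(1, gam, 0, 0, 1, 0, 0, 0, 1), n), n, 9, byrow = TRUE)
  f3 <- adapt_fibers(f, list(F_sh), adaptation_config(kappa = 1))
  Fm <- matrix(c(1, gam, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  for (i in c(1, 17, n)) {
    tg <- target_direction(Fm, f$vec[i, ])
    if (sum(tg * f3$vec[i, ]) < 0) tg <- -tg
    expect_equal(f3$vec[i, ], tg, tolerance = 1e-10)
  }
  # unit norms are preserved
  expect_lt(max(abs(sqrt(rowSums(f3$vec^2)) - 1)), 1e-12)
})

test_that("repeated updates under frozen deformation reach the shear-free state", {
  # with a frozen deformation the fixed points of the update are the
  # eigenvectors of U: iterating drives every node to a direction with no
  # fiber/cross-fiber shear drive left
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  n <- nrow(f$vec)
  gam <- 0.2
  F_sh <- matrix(rep(c(1, 0, 0, 0, 1, gam, 0, 0, 1), n), n, 9, byrow = TRUE)
  Fm <- matrix(c(1, 0, 0, 0, 1, gam, 0, 0, 1), 3, 3, byrow = TRUE)
  cfg <- adaptation_config(kappa = 5)
  f_cur <- f
  for (k in 1:200) {
    f_cur <- adapt_fibers(f_cur, list(F_sh), cfg)
    if (k %% 50 == 0)
      expect_lt(max(abs(sqrt(rowSums(f_cur$vec^2)) - 1)), 1e-12)
  }
  ee <- eigen(t(Fm) %*% Fm, symmetric = TRUE)
  v1 <- ee$vectors[, 1]
  node <- 40
  tg <- target_direction(Fm, f_cur$vec[node, ])
  expect_lt(acos(min(1, abs(sum(tg * f_cur$vec[node, ])))), 5e-3)
  expect_gt(abs(sum(f_cur$vec[node, ] * v1)), 0.999)
})

test_that("a pure scalar recursion decays exactly by (1 - 1/kappa)", {
  kappa <- 5
  theta <- 0.4
  for (k in 1:10) theta <- theta * (1 - 1 / kappa)
  expect_equal(theta, 0.4 * (1 - 1 / kappa)^10, tolerance = 1e-12)
  # and the slerp update reproduces it for a fixed target
  v <- c(1, 0, 0)
  tgt <- c(cos(0.4), sin(0.4), 0)
  f <- 1 / kappa
  for (k in 1:10) {
    th <- acos(min(1, sum(v * tgt)))
    v <- sin((1 - f) * th) / sin(th) * v + sin(f * th) / sin(th) * tgt
    v <- v / sqrt(sum(v^2))
  }
  expect_equal(acos(sum(v * tgt)), 0.4 * (1 - 1 / kappa)^10,
               tolerance = 1e-10)
})

test_that("zero adaptation cycles leave the field untouched and record one cycle", {
  m <- fx_mesh_small()
  f <- fx_field_ss_small()
  sim <- cycle_init(m, f, cfg = solver_config(dt = 8))
  ad <- run_adaptation(m, f, sim, adaptation_config(n_cycles = 0),
                       scfg = solver_config(dt = 8))
  expect_equal(nrow(ad$history), 1L)
  expect_equal(ad$history$cycle, 0)
  expect_equal(ad$field$vec, f$vec)
  expect_equal(ad$field$provenance, "parameterized-initial")
})
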