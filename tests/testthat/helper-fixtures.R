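# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_geom <- function() {
  if (is.null(.fx$geom)) .fx$geom <- lv_geometry()
  .fx$geom
}

fx_mesh <- function() {
  if (is.null(.fx$mesh)) .fx$mesh <- build_mesh(fx_geom())
  .fx$mesh
}

fx_mesh_small <- function() {
  if (is.null(.fx$mesh_small))
    .fx$mesh_small <- build_mesh(fx_geom(), c(3, 1, 5))
  .fx$mesh_small
}

fx_field_ss_small <- function() {
  if (is.null(.fx$field_ss_small))
    .fx$field_ss_small <- fiber_field(fx_mesh_small(), "ss")
  .fx$field_ss_small
}

# A random orthonormal right-handed basis packaged like local_basis output
random_basis <- function() {
  M <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  list(e_c0 = rbind(M[, 1]), e_l0 = rbind(M[, 2]), e_t0 = rbind(M[, 3]))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
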