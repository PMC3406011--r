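# VTK XML (unstructured grid, ASCII) export of meshes and fields.

vtu_header <- function(n_points, n_cells) {
  c('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            n_points, n_cells))
}

vtu_array <- function(name, values, ncomp = 1) {
  c(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
            name, ncomp),
    paste0('          ',
           apply(matrix(format(values, digits = 10), ncol = ncomp), 1, paste,
                 collapse = " ")),
    '        </DataArray>')
}

#' Write the meridional mesh as a VTK XML unstructured grid
#'
#' Nodes are written as (r, z, 0); elements as biquadratic quadrilaterals
#' (VTK cell type 28).  The normalized wall coordinates (u, v) are always
#' attached as point data; further per-node scalar or 3-vector fields can be
#' supplied through `point_data`.
#'
#' @param mesh Mesh from [build_mesh()].
#' @param path Output file (.vtu).
#' @param point_data Named list of per-node vectors (length n) or matrices
#'   (n x 3).
#' @param u Optional displacement vector; if given, deformed coordinates are
#'   written.
#' @return The path, invisibly.
#' @export
write_vtu_plane <- function(mesh, path, point_data = list(), u = NULL) {
  nodes <- mesh$plane$nodes
  n <- nrow(nodes)
  if (!is.null(u)) {
    nodes <- cbind(nodes[, 1] + u[seq(1, 3 * n, 3)],
                   nodes[, 2] + u[seq(3, 3 * n, 3)])
  }
  conn <- mesh$plane$conn
  # tensor (xi fastest) -> VTK biquadratic quad ordering
  vtk_order <- c(1, 3, 9, 7, 2, 6, 8, 4, 5)
  lines <- vtu_header(n, nrow(conn))
  lines <- c(lines, '      <Points>',
             vtu_array("Points", cbind(nodes[, 1], nodes[, 2], 0), 3),
             '      </Points>')
  lines <- c(lines, '      <Cells>',
             '        <DataArray type="Int32" Name="connectivity" format="ascii">',
             paste0('          ',
                    apply(conn[, vtk_order, drop = FALSE] - 1L, 1, paste,
                          collapse = " ")),
             '        </DataArray>',
             '        <DataArray type="Int32" Name="offsets" format="ascii">',
             paste0('          ', paste(seq_len(nrow(conn)) * 9L,
                                        collapse = " ")),
             '        </DataArray>',
             '        <DataArray type="UInt8" Name="types" format="ascii">',
             paste0('          ', paste(rep(28L, nrow(conn)),
                                        collapse = " ")),
             '        </DataArray>',
             '      </Cells>')
  if (!is.null(mesh$plane$uv))
    point_data <- c(list(u = mesh$plane$uv[, 1], v = mesh$plane$uv[, 2]),
                    point_data)
  lines <- c(lines, '      <PointData>')
  for (nm in names(point_data)) {
    val <- point_data[[nm]]
    nc <- if (is.matrix(val)) ncol(val) else 1L
    lines <- c(lines, vtu_array(nm, val, nc))
  }
  lines <- c(lines, '      </PointData>',
             '    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write the 3D hexahedral mesh as a VTK XML unstructured grid
#'
#' The rotationally symmetric solution is revolved into `n_theta` segments
#' of linear hexahedra for visualization; per-node fields from the
#' meridional plane are replicated around the circumference.  The (u, v)
#' wall coordinates are attached as point data.
#'
#' @param mesh Mesh.
#' @param path Output file (.vtu).
#' @param u Optional displacement vector (deforms the geometry, including
#'   the azimuthal rotation phi).
#' @param point_data Named list of per-plane-node scalars.
#' @param n_theta Circumferential segments.
#' @return The path, invisibly.
#' @export
write_vtu_revolved <- function(mesh, path, u = NULL, point_data = list(),
                               n_theta = 24) {
  nodes <- mesh$plane$nodes
  n <- nrow(nodes)
  ni <- 2 * mesh$plane$nr + 1
  nj <- 2 * mesh$plane$nl + 1
  r <- nodes[, 1]; z <- nodes[, 2]; phi <- rep(0, n)
  if (!is.null(u)) {
    r <- r + u[seq(1, 3 * n, 3)]
    z <- z + u[seq(3, 3 * n, 3)]
    phi <- u[seq(2, 3 * n, 3)]
  }
  thetas <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  pts <- NULL
  for (th in thetas)
    pts <- rbind(pts, cbind(r * cos(th + phi), r * sin(th + phi), z))
  # linear hex cells between adjacent grid nodes and theta stations
  cell <- NULL
  gid <- function(i, j, k) (k - 1L) * n + (j - 1L) * ni + i
  for (k in seq_len(n_theta)) {
    k2 <- if (k == n_theta) 1L else k + 1L
    for (j in seq_len(nj - 1)) for (i in seq_len(ni - 1)) {
      cell <- rbind(cell, c(gid(i, j, k), gid(i + 1, j, k),
                            gid(i + 1, j, k2), gid(i, j, k2),
                            gid(i, j + 1, k), gid(i + 1, j + 1, k),
                            gid(i + 1, j + 1, k2), gid(i, j + 1, k2)))
    }
  }
  lines <- vtu_header(nrow(pts), nrow(cell))
  lines <- c(lines, '      <Points>', vtu_array("Points", pts, 3),
             '      </Points>')
  lines <- c(lines, '      <Cells>',
             '        <DataArray type="Int32" Name="connectivity" format="ascii">',
             paste0('          ', apply(cell - 1L, 1, paste, collapse = " ")),
             '        </DataArray>',
             '        <DataArray type="Int32" Name="offsets" format="ascii">',
             paste0('          ', paste(seq_len(nrow(cell)) * 8L,
                                        collapse = " ")),
             '        </DataArray>',
             '        <DataArray type="UInt8" Name="types" format="ascii">',
             paste0('          ', paste(rep(12L, nrow(cell)),
                                        collapse = " ")),
             '        </DataArray>',
             '      </Cells>')
  point_data <- c(list(u = mesh$plane$uv[, 1], v = mesh$plane$uv[, 2]),
                  point_data)
  lines <- c(lines, '      <PointData>')
  for (nm in names(point_data))
    lines <- c(lines, vtu_array(nm, rep(point_data[[nm]], n_theta), 1))
  lines <- c(lines, '      </PointData>',
             '    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}
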