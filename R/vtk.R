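# Legacy ASCII VTK unstructured-grid export of per-element field snapshots
# (conductivity, poration level, field magnitude, current density), for
# inspection in ParaView-style viewers.

#' Export a field snapshot to a legacy VTK file
#'
#' Writes the mesh as an unstructured grid of tetrahedra with per-cell
#' scalars `sigma` (S/m), `p` (level of poration), `Emag` (V/m) and
#' `jmag` (A/m^2), plus the nodal potential `u` (V) when available.
#'
#' @param mesh an `ep_mesh`.
#' @param state a `tissue_state` (e.g. from a [solve_potential()] result).
#' @param path output `.vtk` path.
#' @param u optional nodal potential vector.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, state, path, u = NULL) {
  stopifnot(inherits(mesh, "ep_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  nN <- mesh$nNodes
  M <- nrow(mesh$tets)
  w("# vtk DataFile Version 3.0",
    sprintf("tissue state at t = %g s", state$t %||% 0),
    "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", nN),
    apply(mesh$nodes, 1, function(r) paste(format(r, digits = 12),
                                           collapse = " ")))
  w(sprintf("CELLS %d %d", M, 5 * M),
    paste(4, mesh$tets[, 1] - 1, mesh$tets[, 2] - 1, mesh$tets[, 3] - 1,
          mesh$tets[, 4] - 1))
  w(sprintf("CELL_TYPES %d", M), rep("10", M))
  jmag <- row_norms(state$jCond + state$jCap)
  w(sprintf("CELL_DATA %d", M))
  for (nm in c("sigma", "p", "Emag")) {
    w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
      format(state[[nm]], digits = 9))
  }
  w("SCALARS jmag double 1", "LOOKUP_TABLE default",
    format(jmag, digits = 9))
  if (!is.null(u)) {
    w(sprintf("POINT_DATA %d", nN), "SCALARS u double 1",
      "LOOKUP_TABLE default", format(u, digits = 9))
  }
  invisible(path)
}
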