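#' Write a legacy VTK snapshot of the substrate and cell
#'
#' ASCII legacy unstructured-grid file with the hexahedral mesh, the
#' substrate modulus and the 0/1 cell mask as cell data, and optionally
#' the sensing displacement field as point data. Loadable by any standard
#' VTK reader (ParaView, meshio, VisIt).
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param file output path
#' @param displacement optional n_nodes x 3 matrix (um)
#' @param cell_mask optional per-element 0/1 vector
#' @return invisibly, \code{file}
#' @export
write_vtk_snapshot <- function(mesh, file, displacement = NULL,
                               cell_mask = NULL) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "taxisim substrate/cell snapshot",
     "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", mesh$nnod))
  writeLines(apply(format(mesh$node_xyz, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  wl(sprintf("CELLS %d %d", mesh$ne, mesh$ne * 9L))
  writeLines(paste(8L, apply(mesh$conn - 1L, 1, paste, collapse = " ")), con)
  wl(sprintf("CELL_TYPES %d", mesh$ne))
  writeLines(rep("12", mesh$ne), con)  # VTK_HEXAHEDRON
  wl(sprintf("CELL_DATA %d", mesh$ne),
     "SCALARS modulus_kPa double 1", "LOOKUP_TABLE default")
  writeLines(format(mesh$E_sub, trim = TRUE), con)
  if (!is.null(cell_mask)) {
    stopifnot(length(cell_mask) == mesh$ne)
    wl("SCALARS cell_mask int 1", "LOOKUP_TABLE default")
    writeLines(format(as.integer(cell_mask), trim = TRUE), con)
  }
  if (!is.null(displacement)) {
    stopifnot(nrow(displacement) == mesh$nnod, ncol(displacement) == 3)
    wl(sprintf("POINT_DATA %d", mesh$nnod),
       "VECTORS displacement_um double")
    writeLines(apply(format(displacement, trim = TRUE, scientific = FALSE),
                     1, paste, collapse = " "), con)
  }
  invisible(file)
}

#' Read back the cell mask of a legacy VTK snapshot
#'
#' Minimal reader for the files produced by
#' \code{\link{write_vtk_snapshot}} (used for round-trip validation).
#'
#' @param file path to a snapshot
#' @return list with \code{n_points}, \code{n_cells} and the
#'   \code{cell_mask} vector (NULL if absent)
#' @export
read_vtk_snapshot_info <- function(file) {
  lines <- readLines(file)
  np <- as.integer(sub("POINTS (\\d+).*", "\\1",
                       grep("^POINTS", lines, value = TRUE)[1]))
  nc <- as.integer(sub("CELLS (\\d+).*", "\\1",
                       grep("^CELLS", lines, value = TRUE)[1]))
  mask <- NULL
  i <- grep("^SCALARS cell_mask", lines)
  if (length(i) == 1L) {
    mask <- as.integer(lines[(i + 2L):(i + 1L + nc)])
  }
  list(n_points = np, n_cells = nc, cell_mask = mask)
}
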