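#' Regular hexahedral substrate mesh
#'
#' Axis-aligned grid of 8-node trilinear hexahedra filling the box
#' \code{[0,Lx] x [0,Ly] x [0,Lz]}, with a per-element Young's modulus
#' evaluated from the stimulus field (or a constant / function) at the
#' element centroid and a single Poisson ratio. All elements share the same
#' geometry, so one reference element stiffness (for E = 1) and one
#' centroid strain-displacement matrix serve the whole mesh.
#'
#' @param L box dimensions \code{c(Lx, Ly, Lz)} in um
#' @param n element counts \code{c(nx, ny, nz)}
#' @param stiffness a \code{\link{stimulus_field}}, a single positive
#'   number (homogeneous), a length-2 vector of end values (linear in x),
#'   or a vectorized function of x returning kPa
#' @param nu Poisson ratio of the substrate (also used for cell elements)
#' @return object of class \code{hex_mesh} with node coordinates, the
#'   element-node incidence table, element DOF table, per-element modulus,
#'   element centroids and cached element matrices
#' @export
#' @examples
#' m <- hex_mesh(L = c(40, 20, 20), n = c(4, 2, 2), stiffness = 10)
#' m$ne  # 16 elements
hex_mesh <- function(L = c(400, 200, 200), n = c(40, 20, 20),
                     stiffness = c(1, 100), nu = 0.3) {
  stopifnot(length(L) == 3, length(n) == 3, all(L > 0), all(n >= 1))
  n <- as.integer(n)
  h <- L / n
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  nnod <- nnx * nny * nnz
  ne <- nx * ny * nz

  # node coordinates, index = 1 + i + nnx*(j + nny*k), 0-based ijk
  gi <- rep.int(0:(nnx - 1L), nny * nnz)
  gj <- rep.int(rep(0:(nny - 1L), each = nnx), nnz)
  gk <- rep(0:(nnz - 1L), each = nnx * nny)
  node_xyz <- cbind(x = gi * h[1], y = gj * h[2], z = gk * h[3])

  nid <- function(i, j, k) 1L + i + nnx * (j + nny * k)
  ei <- rep.int(0:(nx - 1L), ny * nz)
  ej <- rep.int(rep(0:(ny - 1L), each = nx), nz)
  ek <- rep(0:(nz - 1L), each = nx * ny)
  conn <- cbind(nid(ei, ej, ek),         nid(ei + 1L, ej, ek),
                nid(ei + 1L, ej + 1L, ek), nid(ei, ej + 1L, ek),
                nid(ei, ej, ek + 1L),      nid(ei + 1L, ej, ek + 1L),
                nid(ei + 1L, ej + 1L, ek + 1L), nid(ei, ej + 1L, ek + 1L))
  storage.mode(conn) <- "integer"
  dofs <- matrix(0L, ne, 24L)
  for (a in 1:8) dofs[, (3 * a - 2):(3 * a)] <-
    cbind(3L * conn[, a] - 2L, 3L * conn[, a] - 1L, 3L * conn[, a])

  ecent <- cbind(x = (ei + 0.5) * h[1], y = (ej + 0.5) * h[2],
                 z = (ek + 0.5) * h[3])

  E_sub <-
    if (inherits(stiffness, "stimulus_field")) stiffness_at(stiffness, ecent[, 1])
    else if (is.function(stiffness)) stiffness(ecent[, 1])
    else if (length(stiffness) == 1) rep(stiffness, ne)
    else stiffness[1] + (stiffness[2] - stiffness[1]) * ecent[, 1] / L[1]
  if (any(!is.finite(E_sub)) || any(E_sub <= 0))
    stop("all element moduli must be positive and finite")

  # per-element face-neighbor table (-x,+x,-y,+y,-z,+z; NA at the boundary)
  eid <- function(i, j, k) {
    out <- 1L + i + nx * (j + ny * k)
    out[i < 0L | i >= nx | j < 0L | j >= ny | k < 0L | k >= nz] <- NA_integer_
    out
  }
  nbmat <- cbind(eid(ei - 1L, ej, ek), eid(ei + 1L, ej, ek),
                 eid(ei, ej - 1L, ek), eid(ei, ej + 1L, ek),
                 eid(ei, ej, ek - 1L), eid(ei, ej, ek + 1L))

  mesh <- structure(list(
    L = L, n = n, h = h, nu = nu,
    nnod = nnod, ne = ne, ndof = 3L * nnod,
    node_xyz = node_xyz, conn = conn, dofs = dofs,
    ecent = ecent, E_sub = as.numeric(E_sub),
    eijk = cbind(ei, ej, ek), nbmat = nbmat,
    ke_unit = ke_hex(nu, h[1], h[2], h[3]),
    B0 = b0_hex(h[1], h[2], h[3])
  ), class = "hex_mesh")
  mesh
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %g x %g x %g um, %d x %d x %d elements (%d), %d nodes\n",
              x$L[1], x$L[2], x$L[3], x$n[1], x$n[2], x$n[3], x$ne, x$nnod))
  cat(sprintf("  element size %g x %g x %g um, E in [%.3g, %.3g] kPa, nu = %g\n",
              x$h[1], x$h[2], x$h[3], min(x$E_sub), max(x$E_sub), x$nu))
  invisible(x)
}

# element index from 0-based (i,j,k); NA outside the mesh
elem_id <- function(mesh, i, j, k) {
  out <- 1L + i + mesh$n[1] * (j + mesh$n[2] * k)
  bad <- i < 0L | i >= mesh$n[1] | j < 0L | j >= mesh$n[2] | k < 0L | k >= mesh$n[3]
  out[bad] <- NA_integer_
  out
}

# the up-to-6 face neighbors of element e (NA-dropped)
elem_face_neighbors <- function(mesh, e) {
  nb <- mesh$nbmat[e, ]
  nb[!is.na(nb)]
}

# 0-based (i,j,k) of a node index
node_ijk <- function(mesh, nodes) {
  nnx <- mesh$n[1] + 1L; nny <- mesh$n[2] + 1L
  z <- (nodes - 1L)
  i <- z %% nnx
  j <- (z %/% nnx) %% nny
  k <- z %/% (nnx * nny)
  cbind(i, j, k)
}

# elements incident to each node: n x 8 integer matrix, NA where the
# incident cell would fall outside the mesh
elems_at_nodes_mat <- function(mesh, nodes) {
  ijk <- node_ijk(mesh, nodes)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  di <- c(-1L, 0L); out <- matrix(NA_integer_, length(nodes), 8L)
  col <- 1L
  for (a in di) for (b in di) for (cc in di) {
    out[, col] <- elem_id(mesh, i + a, j + b, k + cc)
    col <- col + 1L
  }
  out
}

# elements incident to each node of `nodes`: list of integer vectors
elems_at_nodes <- function(mesh, nodes) {
  m <- elems_at_nodes_mat(mesh, nodes)
  lapply(seq_along(nodes), function(a) {
    v <- m[a, ]
    v[!is.na(v)]
  })
}

# TRUE for nodes lying on the exterior surface of the box
node_on_boundary <- function(mesh, nodes) {
  ijk <- node_ijk(mesh, nodes)
  ijk[, 1] == 0L | ijk[, 1] == mesh$n[1] |
    ijk[, 2] == 0L | ijk[, 2] == mesh$n[2] |
    ijk[, 3] == 0L | ijk[, 3] == mesh$n[3]
}
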