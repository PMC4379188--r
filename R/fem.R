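# Small-strain isotropic linear elasticity on the regular hexahedral grid.
# Trilinear (8-node) elements, 2x2x2 Gauss integration for the stiffness,
# single-point (centroid) evaluation for strain recovery. The substrate is
# loaded only by the cell's mechano-sensing contraction; all six exterior
# surfaces stay traction-free and rigid-body modes are removed by a minimal
# 3-2-1 point constraint scheme.

# local node coordinates of the reference hexahedron
.hex_xi <- c(-1, 1, 1, -1, -1, 1, 1, -1)
.hex_et <- c(-1, -1, 1, 1, -1, -1, 1, 1)
.hex_ze <- c(-1, -1, -1, -1, 1, 1, 1, 1)

# isotropic constitutive matrix (Voigt: xx,yy,zz,xy,yz,zx; engineering shear)
.elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) at local point (a,b,c)
.hex_B <- function(a, b, c, hx, hy, hz) {
  dN <- cbind(0.125 * .hex_xi * (1 + .hex_et * b) * (1 + .hex_ze * c) * 2 / hx,
              0.125 * (1 + .hex_xi * a) * .hex_et * (1 + .hex_ze * c) * 2 / hy,
              0.125 * (1 + .hex_xi * a) * (1 + .hex_et * b) * .hex_ze * 2 / hz)
  B <- matrix(0, 6, 24)
  for (n in 1:8) {
    c0 <- 3 * (n - 1)
    B[1, c0 + 1] <- dN[n, 1]; B[2, c0 + 2] <- dN[n, 2]; B[3, c0 + 3] <- dN[n, 3]
    B[4, c0 + 1] <- dN[n, 2]; B[4, c0 + 2] <- dN[n, 1]
    B[5, c0 + 2] <- dN[n, 3]; B[5, c0 + 3] <- dN[n, 2]
    B[6, c0 + 1] <- dN[n, 3]; B[6, c0 + 3] <- dN[n, 1]
  }
  B
}

# reference element stiffness (24 x 24) for unit Young's modulus
ke_hex <- function(nu, hx, hy, hz) {
  gp <- c(-1, 1) / sqrt(3)
  D <- .elastic_D(1, nu)
  detJ <- hx * hy * hz / 8
  K <- matrix(0, 24, 24)
  for (a in gp) for (b in gp) for (c in gp) {
    B <- .hex_B(a, b, c, hx, hy, hz)
    K <- K + crossprod(B, D %*% B) * detJ
  }
  K
}

# centroid strain-displacement matrix (6 x 24)
b0_hex <- function(hx, hy, hz) .hex_B(0, 0, 0, hx, hy, hz)

#' Assemble the global stiffness matrix
#'
#' Symmetric sparse stiffness operator of the whole mesh, honoring a
#' per-element Young's modulus (substrate elements carry the stiffness
#' field evaluated at their centroid; elements currently occupied by the
#' cell may be given the cell modulus).
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param E_elem per-element modulus in kPa (default: the mesh's substrate
#'   moduli)
#' @return a symmetric sparse matrix (\code{Matrix::dsCMatrix}),
#'   positive-semidefinite before constraints
#' @export
assemble_system <- function(mesh, E_elem = mesh$E_sub) {
  stopifnot(length(E_elem) == mesh$ne)
  if (any(E_elem <= 0)) stop("all element moduli must be > 0")
  Im <- mesh$dofs[, rep(1:24, times = 24), drop = FALSE]
  Jm <- mesh$dofs[, rep(1:24, each = 24), drop = FALSE]
  Xm <- outer(as.numeric(E_elem), as.vector(mesh$ke_unit))
  K <- Matrix::sparseMatrix(i = as.vector(Im), j = as.vector(Jm),
                            x = as.vector(Xm),
                            dims = c(mesh$ndof, mesh$ndof))
  Matrix::forceSymmetric(K)
}

# DOFs fixed by the 3-2-1 scheme: corner (0,0,0) fully fixed, corner
# (nx,0,0) fixed in y,z, corner (0,ny,0) fixed in z. Removes the six
# rigid-body modes while leaving every surface traction-free.
constrained_dofs <- function(mesh) {
  nnx <- mesh$n[1] + 1L; nny <- mesh$n[2] + 1L
  nA <- 1L
  nB <- 1L + mesh$n[1]
  nC <- 1L + nnx * mesh$n[2]
  sort(c(3L * nA - 2L, 3L * nA - 1L, 3L * nA,
         3L * nB - 1L, 3L * nB,
         3L * nC))
}

#' Solve the elastic problem under given nodal loads
#'
#' Direct sparse Cholesky solve of the constrained system. Intended for
#' one-off solves (tests, patch problems); the simulator uses a cached
#' factorization path (\code{\link{sensing_solver}}) with identical
#' results.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param loads full-length load vector (3 * number of nodes), nN
#' @param E_elem optional per-element modulus override
#' @return object of class \code{elastic_solution}: full displacement
#'   vector \code{u} (um; constrained DOFs zero) plus the mesh reference
#' @export
solve_elastic <- function(mesh, loads, E_elem = mesh$E_sub) {
  stopifnot(length(loads) == mesh$ndof)
  K <- assemble_system(mesh, E_elem)
  fixed <- constrained_dofs(mesh)
  free <- setdiff(seq_len(mesh$ndof), fixed)
  Kf <- K[free, free]
  u <- numeric(mesh$ndof)
  ch <- tryCatch(Matrix::Cholesky(Kf, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("stiffness matrix is singular after constraints: ",
                        conditionMessage(e)))
  u[free] <- as.numeric(Matrix::solve(ch, loads[free]))
  structure(list(u = u, mesh = mesh), class = "elastic_solution")
}

#' Centroid strain tensors of selected elements
#'
#' Small-strain tensors \code{eps = (grad u + grad u^T) / 2} evaluated at
#' the element centroid from the trilinear displacement field.
#'
#' @param solution an \code{elastic_solution} (or any list with \code{u}
#'   and \code{mesh})
#' @param elems element indices
#' @return matrix with one row per element, Voigt components
#'   \code{exx, eyy, ezz, gxy, gyz, gzx} (engineering shear)
#' @export
element_strains <- function(solution, elems) {
  mesh <- solution$mesh
  U <- matrix(solution$u[t(mesh$dofs[elems, , drop = FALSE])], nrow = 24L)
  E6 <- t(mesh$B0 %*% U)
  colnames(E6) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")
  E6
}

# Voigt row -> symmetric 3x3 tensor
voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[4] / 2, v[6] / 2,
           v[4] / 2, v[2], v[5] / 2,
           v[6] / 2, v[5] / 2, v[3]), 3, 3)
}

#' Strain tensor at a membrane node
#'
#' Volume-weighted average of the centroid strain tensors of all elements
#' incident to the node; on this regular mesh all element volumes are
#' equal, so the average is plain.
#'
#' @param solution an \code{elastic_solution}
#' @param node node index
#' @return symmetric 3x3 strain tensor
#' @export
membrane_strain_tensor <- function(solution, node) {
  inc <- elems_at_nodes(solution$mesh, node)[[1]]
  if (length(inc) == 0L) stop("node has no incident elements")
  voigt_to_tensor(colMeans(element_strains(solution, inc)))
}

#' Directional strain along a unit vector
#'
#' The normal strain sensed along \code{e_i}:
#' \code{eps_cell = t(e) \%*\% eps \%*\% e}.
#'
#' @param eps_tensor symmetric 3x3 strain tensor
#' @param e_i unit vector
#' @return dimensionless scalar strain
#' @export
directional_strain <- function(eps_tensor, e_i) {
  if (abs(vnorm(e_i) - 1) > 1e-6) stop("e_i must have unit norm")
  as.numeric(t(e_i) %*% eps_tensor %*% e_i)
}

# Batch version used by the simulator: mean Voigt strain over incident
# elements for each of `nodes`, then the quadratic form with rows of `ev`
# (unit vectors). Returns the directional strains.
directional_strains_at_nodes <- function(solution, nodes, ev) {
  mesh <- solution$mesh
  inc <- elems_at_nodes(mesh, nodes)
  ue <- unique(unlist(inc, use.names = FALSE))
  E6 <- element_strains(solution, ue)
  row_of <- match(unlist(inc, use.names = FALSE), ue)
  grp <- rep(seq_along(nodes), lengths(inc))
  sums <- rowsum(E6[row_of, , drop = FALSE], grp)
  avg <- sums / lengths(inc)
  ex <- ev[, 1]; ey <- ev[, 2]; ez <- ev[, 3]
  avg[, "exx"] * ex^2 + avg[, "eyy"] * ey^2 + avg[, "ezz"] * ez^2 +
    avg[, "gxy"] * ex * ey + avg[, "gyz"] * ey * ez + avg[, "gzx"] * ez * ex
}

#' Sensing loads for a cell domain
#'
#' Builds the mechano-sensing load vector: every membrane node receives a
#' force of magnitude \code{F_sens} directed towards the cell centroid.
#' For a (near-)symmetric cell the loads cancel and the total applied
#' force is close to zero.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{\link{cell_domain}}
#' @param F_sens per-node sensing force magnitude (nN)
#' @return list with the full \code{loads} vector, the membrane
#'   \code{nodes} and their node-to-centroid unit vectors \code{e_i}
#'   (one row per node)
#' @export
apply_sensing_loads <- function(mesh, cell, F_sens) {
  mem <- membrane_nodes(mesh, cell)
  if (length(mem$nodes) == 0L) stop("cell has no membrane nodes")
  ctr <- cell_centroid(mesh, cell)
  d <- sweep(-mesh$node_xyz[mem$nodes, , drop = FALSE], 2, -ctr)
  nn <- sqrt(rowSums(d^2))
  nn[nn < 1e-12] <- 1
  ev <- d / nn
  loads <- numeric(mesh$ndof)
  idx <- rbind(3 * mem$nodes - 2, 3 * mem$nodes - 1, 3 * mem$nodes)
  loads[idx[1, ]] <- F_sens * ev[, 1]
  loads[idx[2, ]] <- F_sens * ev[, 2]
  loads[idx[3, ]] <- F_sens * ev[, 3]
  list(loads = loads, nodes = mem$nodes, e_i = ev)
}

#' Cached elastic solver for the per-step sensing solves
#'
#' Pre-assembles the substrate-only stiffness matrix once; each step only
#' the few elements currently occupied by the cell differ (they carry the
#' cell modulus \code{E_cell} instead of the local substrate modulus), so
#' the per-step matrix is the cached base plus a small sparse correction.
#' The solve is a warm-started preconditioned conjugate gradient with a
#' sparse Cholesky preconditioner that is refreshed every
#' \code{refresh_every} calls (or whenever convergence degrades), which
#' exploits the small step-to-step change of the matrix. Iterations stop
#' at a relative residual of \code{rtol}, far below the discretization
#' error of the mesh.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param E_cell modulus assigned to cell-occupied elements during the
#'   sensing solve (kPa)
#' @param rtol relative residual tolerance of the iterative solve
#' @param refresh_every refresh period (in calls) of the preconditioner
#' @return a function \code{f(cell_elems, loads)} returning an
#'   \code{elastic_solution}
#' @export
sensing_solver <- function(mesh, E_cell, rtol = 1e-7, refresh_every = 15L) {
  fixed <- constrained_dofs(mesh)
  free <- setdiff(seq_len(mesh$ndof), fixed)
  fmap <- integer(mesh$ndof)
  fmap[free] <- seq_along(free)
  Kbase <- assemble_system(mesh)[free, free]
  Kbase_g <- as(Kbase, "generalMatrix")  # dgC: fast matvec
  nfree <- length(free)
  ke_vec <- as.vector(mesh$ke_unit)
  prec <- NULL
  calls_since <- Inf
  max_it_seen <- 0L
  u_prev <- numeric(nfree)
  build_K <- function(cell_elems, dE) {
    dmat <- mesh$dofs[cell_elems, , drop = FALSE]
    Im <- fmap[dmat[, rep(1:24, times = 24), drop = FALSE]]
    Jm <- fmap[dmat[, rep(1:24, each = 24), drop = FALSE]]
    Xm <- as.vector(outer(dE, ke_vec))
    keep <- Im > 0L & Jm > 0L
    Kc <- Matrix::sparseMatrix(i = as.vector(Im)[keep],
                               j = as.vector(Jm)[keep],
                               x = Xm[keep], dims = c(nfree, nfree))
    Matrix::forceSymmetric(Kbase + Matrix::forceSymmetric(Kc))
  }
  function(cell_elems, loads) {
    dE <- E_cell - mesh$E_sub[cell_elems]
    active <- length(cell_elems) > 0 && any(dE != 0)
    # implicit matvec: base matrix plus the element-local cell correction
    cdofs <- if (active) mesh$dofs[cell_elems, , drop = FALSE] else NULL
    cfree <- if (active) fmap[cdofs] else NULL  # 0 marks constrained dofs
    dim(cfree) <- dim(cdofs)
    matvec <- function(x) {
      y <- as.numeric(Kbase_g %*% x)
      if (active) {
        X <- matrix(0, nrow(cdofs), 24L)
        X[cfree > 0L] <- x[cfree[cfree > 0L]]
        Y <- (X %*% mesh$ke_unit) * dE
        ok <- cfree > 0L
        add <- rowsum(Y[ok], cfree[ok])
        idx <- as.integer(rownames(add))
        y[idx] <- y[idx] + add[, 1]
      }
      y
    }
    if (is.null(prec) || calls_since >= refresh_every || max_it_seen > 20L) {
      prec <<- Matrix::Cholesky(build_K(cell_elems, dE), LDL = FALSE,
                                super = TRUE)
      calls_since <<- 0L
      max_it_seen <<- 0L
    }
    b <- loads[free]
    bnorm <- sqrt(sum(b * b))
    x <- u_prev
    if (bnorm > 0) {
      converged <- FALSE
      for (attempt in 1:2) {
        r <- b - matvec(x)
        z <- as.numeric(Matrix::solve(prec, r))
        p <- z
        rz <- sum(r * z)
        for (it in seq_len(200L)) {
          Kp <- matvec(p)
          alpha <- rz / sum(p * Kp)
          x <- x + alpha * p
          r <- r - alpha * Kp
          if (sqrt(sum(r * r)) <= rtol * bnorm) {
            converged <- TRUE
            max_it_seen <<- max(max_it_seen, it)
            break
          }
          z <- as.numeric(Matrix::solve(prec, r))
          rz_new <- sum(r * z)
          p <- z + (rz_new / rz) * p
          rz <- rz_new
        }
        if (converged) break
        # stale preconditioner: refresh with the current matrix and retry
        prec <<- Matrix::Cholesky(build_K(cell_elems, dE), LDL = FALSE,
                                  super = TRUE)
        calls_since <<- 0L
        max_it_seen <<- 0L
      }
      if (!converged) stop("sensing solve did not converge")
    } else {
      x <- numeric(nfree)
    }
    calls_since <<- calls_since + 1L
    u_prev <<- x
    u <- numeric(mesh$ndof)
    u[free] <- x
    structure(list(u = u, mesh = mesh), class = "elastic_solution")
  }
}

#' Sensed directional strains at membrane nodes
#'
#' The mechano-sensing readout used by the simulator: for each membrane
#' node the directional strain along the node-to-centroid unit vector is
#' evaluated from the average strain tensor of the adjacent
#' \emph{substrate-side} elements (the matrix the node anchors to), with
#' reversed sign so that a contraction registers as negative strain. The
#' local matrix stretch mirrors, by action-reaction at the membrane, the
#' contraction of the cell at that node; because it is a spatial
#' derivative it is blind to the rigid drift of the whole cell towards
#' the compliant side of a graded substrate, which makes the readout
#' monotone in local substrate compliance: softer surroundings (or a
#' nearby free surface) yield a more negative sensed strain.
#'
#' Membrane nodes with no adjacent substrate element (cell pressed flat
#' against the mesh boundary) have no anchorage and return \code{NA}; the
#' caller assigns them zero traction.
#'
#' @param solution an \code{elastic_solution} from the sensing solve
#' @param cell the \code{cell_domain}
#' @param nodes membrane node indices
#' @param ev matrix of node-to-centroid unit vectors (one row per node)
#' @param n_out optional matrix of outward membrane directions (one row
#'   per node); when given, only substrate elements on the outward side of
#'   the node anchor it
#' @return directional strains (dimensionless), NA for unanchored nodes
#' @export
sensing_strains <- function(solution, cell, nodes, ev, n_out = NULL) {
  mesh <- solution$mesh
  inset <- logical(mesh$ne)
  inset[cell$elems] <- TRUE
  inc <- elems_at_nodes(mesh, nodes)
  inc <- lapply(inc, function(v) v[!inset[v]])
  if (!is.null(n_out)) {
    # anchorage lies beyond the membrane: keep only substrate elements on
    # the outward side of the node, so a node facing a free box surface
    # (no matrix beyond it) correctly registers as unanchored
    xyz <- mesh$node_xyz[nodes, , drop = FALSE]
    inc <- lapply(seq_along(inc), function(a) {
      v <- inc[[a]]
      if (length(v) == 0L) return(v)
      rel <- sweep(mesh$ecent[v, , drop = FALSE], 2, xyz[a, ])
      v[as.numeric(rel %*% n_out[a, ]) > 0]
    })
  }
  n_inc <- lengths(inc)
  keep <- n_inc > 0L
  out <- rep(NA_real_, length(nodes))
  if (!any(keep)) return(out)
  ue <- unique(unlist(inc, use.names = FALSE))
  E6 <- element_strains(solution, ue)
  row_of <- match(unlist(inc, use.names = FALSE), ue)
  grp <- rep(seq_along(nodes), n_inc)
  avg <- rowsum(E6[row_of, , drop = FALSE], grp) / n_inc[keep]
  ex <- ev[keep, 1]; ey <- ev[keep, 2]; ez <- ev[keep, 3]
  out[keep] <- -(avg[, "exx"] * ex^2 + avg[, "eyy"] * ey^2 +
                   avg[, "ezz"] * ez^2 + avg[, "gxy"] * ex * ey +
                   avg[, "gyz"] * ey * ez + avg[, "gzx"] * ez * ex)
  out
}
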