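# The discrete cell domain: a face-connected set of mesh elements that
# migrates by swapping one rear element for one front element at a time.
# The element count (a proxy for cell volume) is conserved; protrusions
# beyond the nominal radius are capped at 10% of the cell volume.

#' Initialize a spherical cell domain
#'
#' Selects every element whose centroid lies within \code{r} of
#' \code{center}, i.e. a voxelized ball on the substrate mesh.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param center cell center (um)
#' @param r nominal cell radius (um)
#' @return object of class \code{cell_domain}: element index set,
#'   conserved element count \code{N}, and the nominal radius
#' @export
init_spherical_cell <- function(mesh, center, r) {
  stopifnot(length(center) == 3, r > 0)
  if (any(center - r < 0) || any(center + r > mesh$L))
    stop("sphere of radius ", r, " at (", paste(center, collapse = ", "),
         ") does not fit inside the mesh")
  d2 <- (mesh$ecent[, 1] - center[1])^2 + (mesh$ecent[, 2] - center[2])^2 +
    (mesh$ecent[, 3] - center[3])^2
  elems <- which(d2 <= r^2)
  if (length(elems) == 0L) {
    # radius below half an element edge: fall back to the single element
    # containing the center (documented degenerate case)
    elems <- which.min(d2)
  }
  if (!elements_connected(mesh, elems))
    stop("voxelized sphere is not face-connected on this mesh")
  structure(list(elems = as.integer(elems), N = length(elems), r = r),
            class = "cell_domain")
}

#' @export
print.cell_domain <- function(x, ...) {
  cat(sprintf("cell_domain: %d elements, nominal radius %g um\n", x$N, x$r))
  invisible(x)
}

#' Centroid of the cell domain
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @return length-3 position (um)
#' @export
cell_centroid <- function(mesh, cell) {
  colMeans(mesh$ecent[cell$elems, , drop = FALSE])
}

# face-connectivity of an element set (BFS over face neighbors)
elements_connected <- function(mesh, elems) {
  m <- length(elems)
  if (m <= 1L) return(m == 1L)
  inset <- logical(mesh$ne)
  inset[elems] <- TRUE
  seen <- logical(mesh$ne)
  stack <- integer(m)
  stack[1L] <- elems[1L]
  top <- 1L
  seen[elems[1L]] <- TRUE
  count <- 1L
  while (top > 0L) {
    e <- stack[top]
    top <- top - 1L
    for (nb in mesh$nbmat[e, ]) {
      if (!is.na(nb) && inset[nb] && !seen[nb]) {
        seen[nb] <- TRUE
        count <- count + 1L
        top <- top + 1L
        stack[top] <- nb
      }
    }
  }
  count == m
}

#' Membrane nodes and membrane area of the cell
#'
#' Membrane nodes are nodes shared by a cell element and a non-cell
#' element, or lying on the exterior surface of the mesh. The membrane
#' area \code{S} is the total area of exposed element faces (faces whose
#' neighbor is missing or not part of the cell).
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @return list with \code{nodes} (integer vector), \code{S} (um^2), the
#'   per-node tributary membrane \code{area} (quarter of each incident
#'   exposed face; sums to S), and \code{avec}, the inward tributary area
#'   vector of each node (quarter-face normals; rows sum to zero over a
#'   closed membrane, so a uniform stress transmits no net traction)
#' @export
membrane_nodes <- function(mesh, cell) {
  inset <- logical(mesh$ne)
  inset[cell$elems] <- TRUE
  face_area <- c(mesh$h[2] * mesh$h[3], mesh$h[2] * mesh$h[3],
                 mesh$h[1] * mesh$h[3], mesh$h[1] * mesh$h[3],
                 mesh$h[1] * mesh$h[2], mesh$h[1] * mesh$h[2])
  nb <- mesh$nbmat[cell$elems, , drop = FALSE]
  exposed <- is.na(nb) | !inset[nb]  # NA-safe: inset[NA] is NA, caught first
  exposed[is.na(nb)] <- TRUE
  S <- sum(colSums(exposed) * face_area)
  # tributary area: every exposed face hands a quarter of its area to each
  # of its four nodes, so the per-node areas sum exactly to S
  fnodes <- list(c(1L, 4L, 8L, 5L), c(2L, 3L, 7L, 6L),
                 c(1L, 2L, 6L, 5L), c(4L, 3L, 7L, 8L),
                 c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L))
  fnorm <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  acc_nodes <- integer(0)
  acc_area <- numeric(0)
  acc_avec <- matrix(0, 0, 3)
  for (f in 1:6) {
    ex_e <- cell$elems[exposed[, f]]
    if (length(ex_e) == 0L) next
    nds <- mesh$conn[ex_e, fnodes[[f]], drop = FALSE]
    m <- length(nds)
    acc_nodes <- c(acc_nodes, as.vector(nds))
    acc_area <- c(acc_area, rep(face_area[f] / 4, m))
    # inward quarter-face area vector handed to each face node
    acc_avec <- rbind(acc_avec,
                      matrix(rep(-fnorm[f, ] * face_area[f] / 4, each = m),
                             m, 3))
  }
  tri <- rowsum(acc_area, acc_nodes)
  tri_avec <- rowsum(acc_avec, acc_nodes)
  tri_nodes <- as.integer(rownames(tri))
  cnodes <- unique(as.vector(mesh$conn[cell$elems, , drop = FALSE]))
  incm <- elems_at_nodes_mat(mesh, cnodes)
  outcnt <- matrix(FALSE, nrow(incm), 8L)
  ok <- !is.na(incm)
  outcnt[ok] <- !inset[incm[ok]]
  has_out <- rowSums(outcnt) > 0
  on_bnd <- node_on_boundary(mesh, cnodes)
  nodes <- cnodes[has_out | on_bnd]
  area <- numeric(length(nodes))
  avec <- matrix(0, length(nodes), 3)
  mi <- match(nodes, tri_nodes)
  area[!is.na(mi)] <- tri[mi[!is.na(mi)], 1]
  avec[!is.na(mi), ] <- tri_avec[mi[!is.na(mi)], ]
  list(nodes = nodes, S = S, area = area, avec = avec)
}

#' Front/rear partition of the membrane
#'
#' Signed distance of every membrane node from the plane through the cell
#' centroid with normal along the polarization direction:
#' \code{delta = e_pol . (node - centroid)}. Nodes with \code{delta >= 0}
#' form the front (ties assigned to the front), the rest the rear.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @param e_pol unit polarization vector
#' @param mem optional precomputed \code{\link{membrane_nodes}} result
#' @return list with \code{nodes}, \code{delta}, and logical \code{front}
#' @export
front_rear_partition <- function(mesh, cell, e_pol, mem = NULL) {
  e_pol <- unit_vector(e_pol)
  if (is.null(e_pol)) stop("degenerate polarization direction")
  mem <- mem %||% membrane_nodes(mesh, cell)
  ctr <- cell_centroid(mesh, cell)
  s <- sweep(mesh$node_xyz[mem$nodes, , drop = FALSE], 2, ctr)
  delta <- as.numeric(s %*% e_pol)
  list(nodes = mem$nodes, delta = delta, front = delta >= 0, S = mem$S)
}

# number (and fraction) of cell elements whose centroid lies beyond the
# nominal radius of the set's own centroid; half an element edge of slack
# absorbs the voxel quantization of the radius (centroids of a voxelized
# ball sit up to h/2 outside r)
pseudopod_count <- function(mesh, cell, elems = cell$elems) {
  px <- mesh$ecent[elems, 1]; py <- mesh$ecent[elems, 2]
  pz <- mesh$ecent[elems, 3]
  d2 <- (px - mean(px))^2 + (py - mean(py))^2 + (pz - mean(pz))^2
  sum(d2 > (cell$r + mean(mesh$h) / 2)^2)
}

pseudopod_fraction <- function(mesh, cell, elems = cell$elems) {
  pseudopod_count(mesh, cell, elems) / length(elems)
}

#' Choose the extension / retraction element pair
#'
#' The membrane node with the largest \code{delta} (most advanced along
#' the polarization) nominates a free substrate element to occupy; the
#' node with the smallest \code{delta} nominates a cell element to
#' release. Among the elements incident to the nominating node the
#' extension candidate maximizes, and the retraction candidate minimizes,
#' the centroid projection on \code{e_pol}. Candidates violating the
#' constraints (mesh bounds, face-connectivity of the cell after the swap,
#' the 10\% pseudopod volume cap) are skipped in rank order; if no
#' feasible pair exists the step records a no-remodel event.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @param part a \code{\link{front_rear_partition}} result
#' @param e_pol unit polarization vector
#' @param max_candidates how many top-ranked membrane nodes to try
#'   (default: all of them)
#' @return list \code{(e_ex, e_re)} of element indices, or NULL if jammed
#' @export
select_extension_retraction <- function(mesh, cell, part, e_pol,
                                        max_candidates = Inf) {
  inset <- logical(mesh$ne)
  inset[cell$elems] <- TRUE
  ctr <- cell_centroid(mesh, cell)
  proj <- as.numeric(sweep(mesh$ecent, 2, ctr) %*% e_pol)
  cap <- ceiling(0.10 * cell$N)
  thr2 <- (cell$r + mean(mesh$h) / 2)^2
  d2 <- rowSums(sweep(mesh$ecent[cell$elems, , drop = FALSE], 2, ctr)^2)
  beyond <- cell$elems[d2 > thr2]

  # retraction candidate: lowest-delta nodes first; optionally restricted
  # to a subset of releasable elements
  pick_retraction <- function(allowed) {
    re_order <- order(part$delta)
    for (a in re_order[seq_len(min(max_candidates, length(re_order)))]) {
      cand <- elems_at_nodes(mesh, part$nodes[a])[[1]]
      cand <- cand[inset[cand]]
      if (!is.null(allowed)) cand <- intersect(cand, allowed)
      cand <- cand[order(proj[cand])]
      for (e in cand) {
        rest <- setdiff(cell$elems, e)
        if (length(rest) > 0L && elements_connected(mesh, rest)) return(e)
      }
    }
    NA_integer_
  }
  # extension candidate for a given remaining set: highest-delta nodes
  # first, face-attached, and within the ~10% pseudopod volume cap (a
  # swap that does not add beyond-radius volume is always admissible)
  pick_extension <- function(rest) {
    # never-worsen rule plus a hard transient allowance of two elements
    # over the budget (centroid shifts can push elements across the
    # radius without any new protrusion being formed)
    cap_now <- min(max(cap, pseudopod_count(mesh, cell, rest)), cap + 2L)
    ex_order <- order(part$delta, decreasing = TRUE)
    inrest <- logical(mesh$ne)
    inrest[rest] <- TRUE
    for (a in ex_order[seq_len(min(max_candidates, length(ex_order)))]) {
      cand <- elems_at_nodes(mesh, part$nodes[a])[[1]]
      cand <- cand[!inset[cand]]
      cand <- cand[order(proj[cand], decreasing = TRUE)]
      for (e in cand) {
        if (!any(inrest[elem_face_neighbors(mesh, e)])) next
        if (pseudopod_count(mesh, cell, c(rest, e)) > cap_now) next
        return(e)
      }
    }
    NA_integer_
  }

  e_re <- pick_retraction(NULL)
  if (!is.na(e_re)) {
    e_ex <- pick_extension(setdiff(cell$elems, e_re))
    if (!is.na(e_ex)) return(list(e_ex = e_ex, e_re = e_re))
  }
  # recovery: release a standing protrusion (beyond-radius element) so the
  # pseudopod budget frees up, then extend
  if (length(beyond) > 0L) {
    e_re2 <- pick_retraction(beyond)
    if (!is.na(e_re2) && !identical(e_re2, e_re)) {
      e_ex <- pick_extension(setdiff(cell$elems, e_re2))
      if (!is.na(e_ex)) return(list(e_ex = e_ex, e_re = e_re2))
    }
  }
  NULL
}

#' Apply one extension/retraction swap
#'
#' Moves \code{e_re} from the cell to the substrate and \code{e_ex} from
#' the substrate into the cell. The element count is conserved and the
#' centroid moves by \code{(x_ex - x_re) / N}.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @param e_ex,e_re element indices from
#'   \code{\link{select_extension_retraction}}
#' @return the updated \code{cell_domain}
#' @export
remodel <- function(mesh, cell, e_ex, e_re) {
  if (!(e_re %in% cell$elems) || (e_ex %in% cell$elems))
    stop("infeasible swap: e_re must be a cell element and e_ex must not")
  cell$elems <- c(setdiff(cell$elems, e_re), as.integer(e_ex))
  stopifnot(length(cell$elems) == cell$N)
  cell
}

#' Principal dimensions of the cell
#'
#' Lengths of the cell along the eigen-axes of the second-moment tensor of
#' its element centroids (rotation-invariant): along each axis the extent
#' of the centroid projections plus one element edge.
#'
#' @param mesh a \code{\link{hex_mesh}}
#' @param cell a \code{cell_domain}
#' @return sorted vector \code{c(l_max, l_med, l_min)} in um
#' @export
principal_dimensions <- function(mesh, cell) {
  P <- mesh$ecent[cell$elems, , drop = FALSE]
  hbar <- mean(mesh$h)
  if (nrow(P) == 1L) return(sort(mesh$h, decreasing = TRUE))
  Pc <- sweep(P, 2, colMeans(P))
  M <- crossprod(Pc) / nrow(Pc)
  ax <- eigen(M, symmetric = TRUE)$vectors
  pr <- Pc %*% ax
  len <- apply(pr, 2, function(v) diff(range(v))) + hbar
  sort(len, decreasing = TRUE)
}

#' Corey shape factor
#'
#' Drag-correction factor for non-spherical bodies,
#' \code{(l_max * l_med / l_min^2)^0.09}; equals 1 for a sphere and grows
#' slowly with elongation. Scale-invariant.
#'
#' @param l_max,l_med,l_min principal dimensions with
#'   \code{l_max >= l_med >= l_min > 0}
#' @return dimensionless shape factor >= 1
#' @export
#' @examples
#' shape_factor(40, 20, 20)  # 2^0.09
shape_factor <- function(l_max, l_med, l_min) {
  if (any(l_min <= 0)) stop("l_min must be > 0")
  if (any(l_max < l_med) || any(l_med < l_min))
    stop("need l_max >= l_med >= l_min")
  (l_max * l_med / l_min^2)^0.09
}
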