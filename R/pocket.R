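#' Define a binding pocket by its lining residues
#'
#' @param resids integer residue indices lining the pocket (>= 3).
#' @param spacing volume-grid spacing in Angstrom (default 0.5).
#' @param probe_radius solvent probe in Angstrom (default 1.4).
#' @param pad outward padding of the lining-atom convex hull in Angstrom
#'   (default 0; the hull of the lining atoms usually already encloses
#'   the cavity).
#' @return object of class \code{pocket_definition}.
#' @export
pocket_definition <- function(resids, spacing = 0.5, probe_radius = 1.4,
                              pad = 0) {
  resids <- sort(unique(as.integer(resids)))
  if (length(resids) < 3) stop("pocket_definition: need >= 3 lining residues")
  stopifnot(spacing > 0, probe_radius >= 0, pad >= 0)
  structure(list(resids = resids, spacing = spacing,
                 probe_radius = probe_radius, pad = pad),
            class = "pocket_definition")
}

#' Pocket backbone RMSD series
#'
#' Superposes each frame on the reference over the whole receptor
#' backbone, then measures the RMSD over the pocket residues' backbone
#' atoms -- the conformational drift of the binding site within the
#' globally fitted receptor.
#'
#' @param traj a \code{mol_trajectory}.
#' @param pocket a \code{pocket_definition}.
#' @param reference full-system reference coordinates.
#' @return an \code{rmsd_series} (see \code{\link{rmsd_series}}).
#' @export
pocket_rmsd <- function(traj, pocket, reference) {
  stopifnot(inherits(pocket, "pocket_definition"))
  sys <- traj$system
  fit <- select_atoms(sys, "backbone and group:receptor", label = "receptor backbone")
  resid_expr <- paste0("resid:", paste(pocket$resids, collapse = ","))
  mea <- select_atoms(sys, paste0("backbone and (", resid_expr, ")"),
                      label = "pocket backbone")
  if (length(mea$indices) == 0) stop("pocket_rmsd: empty pocket selection")
  rmsd_series(traj, reference, fit, mea, selection_label = "pocket backbone")
}

# convex hull of a 3-D point set as half-spaces. Extreme-point candidates
# are found as support argmaxes over a golden-spiral direction set; when
# few (polytope-like linings) the exact facets are enumerated from point
# triples, otherwise the directional supporting half-spaces serve as a
# tight outer approximation (smooth, shell-like linings).
convex_hull_halfspaces <- function(pts, n_directions = 1024,
                                   max_exact_vertices = 60) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4) stop("degenerate hull: need >= 4 points")
  centroid <- colMeans(pts)
  spread <- svd(sweep(pts, 2, centroid))$d
  if (spread[3] < 1e-7 * max(spread[1], 1e-12))
    stop("degenerate hull: lining points are (near) coplanar")
  D <- sphere_points(n_directions)               # M x 3 unit directions
  SP <- pts %*% t(D)
  offsets <- apply(SP, 2, max)                   # support function h(d)
  cand <- sort(unique(apply(SP, 2, which.max)))
  if (length(cand) > max_exact_vertices)
    return(list(normals = D, offsets = offsets))

  # exact facet enumeration over the candidate vertices
  C <- pts[cand, , drop = FALSE]
  k <- nrow(C)
  tol <- 1e-7 * max(spread[1], 1)
  tri <- utils::combn(k, 3)
  p1 <- C[tri[1, ], , drop = FALSE]
  e1 <- C[tri[2, ], , drop = FALSE] - p1
  e2 <- C[tri[3, ], , drop = FALSE] - p1
  nv <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nv^2))
  ok <- nn > tol
  nv <- nv[ok, , drop = FALSE] / nn[ok]
  p1 <- p1[ok, , drop = FALSE]
  off <- rowSums(nv * p1)
  S <- C %*% t(nv)                               # k x n_planes
  above <- colSums(S > rep(off, each = k) + tol)
  below <- colSums(S < rep(off, each = k) - tol)
  keep_pos <- above == 0                         # outward normal as-is
  keep_neg <- below == 0                         # flip to outward
  normals <- rbind(nv[keep_pos, , drop = FALSE], -nv[keep_neg, , drop = FALSE])
  offs <- c(off[keep_pos], -off[keep_neg])
  if (nrow(normals) == 0)                        # fall back to directional
    return(list(normals = D, offsets = offsets))
  key <- paste(round(normals[, 1], 6), round(normals[, 2], 6),
               round(normals[, 3], 6), round(offs, 6))
  dedupe <- !duplicated(key)
  list(normals = normals[dedupe, , drop = FALSE], offsets = offs[dedupe])
}

#' Grid-based pocket volume
#'
#' Lays a regular grid over the padded convex hull of the pocket lining
#' atoms and counts grid points that are (a) inside every hull half-space
#' (offset outward by \code{pad}) and (b) at least \code{atom radius +
#' probe} away from every receptor atom -- i.e. solvent-probe-reachable
#' cavity space. Volume = count x spacing^3. Deterministic for a fixed
#' spacing; the result is method-dependent, as all grid cavity volumes
#' are.
#'
#' @param coords full-system coordinates (Angstrom).
#' @param system the \code{mol_system} (radii must be set on receptor
#'   atoms).
#' @param pocket a \code{pocket_definition}.
#' @param exclude_sel optional selection of atoms acting as steric
#'   blockers (default: all receptor heavy atoms).
#' @return volume in Angstrom^3, with attribute \code{n_points} (grid
#'   points counted).
#' @export
pocket_volume <- function(coords, system, pocket, exclude_sel = NULL) {
  stopifnot(inherits(pocket, "pocket_definition"))
  coords <- as.matrix(coords)
  a <- system$atoms
  lin_idx <- which(a$resid %in% pocket$resids & toupper(a$element) != "H")
  if (length(lin_idx) < 4) stop("pocket_volume: too few lining atoms")
  if (is.null(exclude_sel))
    exclude_sel <- select_atoms(system, "group:receptor and heavy")
  ei <- if (inherits(exclude_sel, "atom_selection")) exclude_sel$indices else exclude_sel
  hull <- convex_hull_halfspaces(coords[lin_idx, , drop = FALSE])
  pad <- pocket$pad
  sp <- pocket$spacing
  # sample voxel centres so the counted volume tiles space exactly
  lo <- apply(coords[lin_idx, , drop = FALSE], 2, min) - pad - sp
  hi <- apply(coords[lin_idx, , drop = FALSE], 2, max) + pad + sp
  gx <- seq(lo[1] + sp / 2, hi[1], by = sp)
  gy <- seq(lo[2] + sp / 2, hi[2], by = sp)
  gz <- seq(lo[3] + sp / 2, hi[3], by = sp)
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # keep points inside every (pad-offset) supporting half-space,
  # testing directions in blocks over the surviving points only
  blocks <- split(seq_along(hull$offsets),
                  ceiling(seq_along(hull$offsets) / 64))
  for (b in blocks) {
    if (nrow(G) == 0) break
    S <- G %*% t(hull$normals[b, , drop = FALSE])
    ok <- rowSums(sweep(S, 2, hull$offsets[b] + pad, ">")) == 0
    G <- G[ok, , drop = FALSE]
  }
  if (nrow(G) == 0) return(structure(0, n_points = 0L))
  free <- rep(TRUE, nrow(G))
  rads <- a$radius[ei]
  if (anyNA(rads)) stop("pocket_volume: missing radii on blocking atoms")
  for (j in seq_along(ei)) {
    if (!any(free)) break
    d2 <- rowSums(sweep(G[free, , drop = FALSE], 2, coords[ei[j], ])^2)
    free[free] <- d2 >= (rads[j] + pocket$probe_radius)^2
  }
  structure(sum(free) * sp^3, n_points = sum(free))
}
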