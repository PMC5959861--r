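#' Deterministic golden-section spiral points on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  # z strata midpoints; golden-angle azimuthal increments
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius \code{r_i + probe} is sampled with a
#' deterministic golden-section spiral; a sample point is accessible when
#' it lies outside every other atom's inflated sphere. Per-atom areas are
#' the accessible fraction times the sphere area; they sum to the total.
#'
#' @param coords n x 3 coordinate matrix (Angstrom) for the atoms under
#'   consideration (already subset to a selection).
#' @param radii per-atom radii (Angstrom), all > 0.
#' @param probe_radius probe radius in Angstrom (default 1.4, water).
#' @param n_points spiral points per atom (default 960).
#' @return list with \code{total} (Angstrom^2) and \code{per_atom}.
#' @export
sasa <- function(coords, radii, probe_radius = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(radii) == nrow(coords))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("SASA parameter error: all radii must be positive")
  n <- nrow(coords)
  rr <- radii + probe_radius
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  tie_tol <- 1e-9
  # neighbor prefilter: pairwise distances once (fixture-scale systems)
  for (i in seq_len(n)) {
    ri <- rr[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + rr)^2 & seq_len(n) != i)
    area_i <- 4 * pi * ri^2
    if (length(nb) == 0) { per_atom[i] <- area_i; next }
    sp <- sweep(pts * ri, 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(sp[acc, , drop = FALSE], 2, coords[j, ])^2)
      # strictly inside occludes; a point exactly on the neighbour's
      # surface is ceded to the lower-indexed atom (so coincident equal
      # spheres expose exactly one sphere's worth of surface)
      occ <- dj < rr[j]^2 - tie_tol
      if (j < i) occ <- occ | (abs(dj - rr[j]^2) <= tie_tol)
      acc[acc] <- !occ
    }
    per_atom[i] <- area_i * sum(acc) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Receptor-nanotube contact area
#'
#' Buried-interface area between two disjoint atom groups:
#' \deqn{contact = [ (SAS_{rec} + SAS_{cnt}) - SAS_{complex} ] / 2}
#' with the three SASA terms evaluated on the isolated receptor, the
#' isolated tube, and their union.
#'
#' @param coords full-system n x 3 coordinate matrix (Angstrom).
#' @param rec_sel,tube_sel disjoint nonempty \code{atom_selection}s (or
#'   index vectors).
#' @param radii per-atom radii for the full system.
#' @param probe_radius,n_points forwarded to \code{\link{sasa}}.
#' @return list with \code{contact_area}, \code{sas_rec}, \code{sas_tube},
#'   \code{sas_complex} (Angstrom^2).
#' @export
contact_area <- function(coords, rec_sel, tube_sel, radii,
                         probe_radius = 1.4, n_points = 960) {
  ri <- if (inherits(rec_sel, "atom_selection")) rec_sel$indices else rec_sel
  ti <- if (inherits(tube_sel, "atom_selection")) tube_sel$indices else tube_sel
  if (length(ri) == 0 || length(ti) == 0)
    stop("contact_area: empty selection")
  if (length(intersect(ri, ti)) > 0)
    stop("contact_area: receptor and tube selections overlap")
  coords <- as.matrix(coords)
  s_rec <- sasa(coords[ri, , drop = FALSE], radii[ri], probe_radius, n_points)$total
  s_tub <- sasa(coords[ti, , drop = FALSE], radii[ti], probe_radius, n_points)$total
  un <- c(ri, ti)
  s_cpx <- sasa(coords[un, , drop = FALSE], radii[un], probe_radius, n_points)$total
  list(contact_area = 0.5 * ((s_rec + s_tub) - s_cpx),
       sas_rec = s_rec, sas_tube = s_tub, sas_complex = s_cpx)
}
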