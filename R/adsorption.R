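# minimum distance from each query atom to any target atom, via a cell
# list over the targets (cell size = cutoff); returns TRUE where the
# minimum distance is <= cutoff (inclusive criterion)
within_cutoff <- function(query, target, cutoff) {
  query <- as.matrix(query); target <- as.matrix(target)
  stopifnot(cutoff > 0)
  origin <- apply(rbind(query, target), 2, min)
  tcell <- floor(sweep(target, 2, origin) / cutoff)
  tkey <- paste(tcell[, 1], tcell[, 2], tcell[, 3])
  tmap <- split(seq_len(nrow(target)), tkey)
  qcell <- floor(sweep(query, 2, origin) / cutoff)
  out <- logical(nrow(query))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  c2 <- cutoff^2
  for (i in seq_len(nrow(query))) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      key <- paste(qcell[i, 1] + offs[o, 1], qcell[i, 2] + offs[o, 2],
                   qcell[i, 3] + offs[o, 3])
      hit <- tmap[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0) next
    d2 <- rowSums(sweep(target[cand, , drop = FALSE], 2, query[i, ])^2)
    out[i] <- any(d2 <= c2)
  }
  out
}

#' Count receptor heavy atoms adsorbed onto the tube
#'
#' An atom is adsorbed when its minimum distance to any tube atom is
#' within the cutoff (inclusive), the standard 6 Angstrom hydrophobic
#' contact criterion.
#'
#' @param coords full-system n x 3 coordinates (Angstrom).
#' @param rec_heavy \code{atom_selection} (or indices) of receptor heavy
#'   (non-hydrogen) atoms.
#' @param tube \code{atom_selection} (or indices) of tube atoms; must be
#'   nonempty.
#' @param cutoff distance criterion in Angstrom (default 6).
#' @return integer adsorbed-atom count.
#' @export
adsorbed_atom_count <- function(coords, rec_heavy, tube, cutoff = 6.0) {
  ri <- if (inherits(rec_heavy, "atom_selection")) rec_heavy$indices else rec_heavy
  ti <- if (inherits(tube, "atom_selection")) tube$indices else tube
  if (length(ti) == 0) stop("adsorbed_atom_count: empty tube selection")
  if (length(ri) == 0) return(0L)
  stopifnot(cutoff > 0)
  coords <- as.matrix(coords)
  sum(within_cutoff(coords[ri, , drop = FALSE],
                    coords[ti, , drop = FALSE], cutoff))
}

#' Residues adsorbed onto the tube
#'
#' A residue is adsorbed when at least one of its heavy atoms lies within
#' the cutoff of any tube atom.
#'
#' @param coords full-system coordinates.
#' @param system the \code{mol_system}.
#' @param tube tube \code{atom_selection} (or indices), nonempty.
#' @param cutoff Angstrom (default 6).
#' @param candidate_sel optional selection restricting the residues
#'   scanned (default: receptor heavy atoms).
#' @return sorted integer vector of adsorbed residue indices.
#' @export
adsorbed_residues <- function(coords, system, tube, cutoff = 6.0,
                              candidate_sel = NULL) {
  ti <- if (inherits(tube, "atom_selection")) tube$indices else tube
  if (length(ti) == 0) stop("adsorbed_residues: empty tube selection")
  stopifnot(cutoff > 0)
  if (is.null(candidate_sel))
    candidate_sel <- select_atoms(system, "group:receptor and heavy")
  ci <- if (inherits(candidate_sel, "atom_selection")) candidate_sel$indices else candidate_sel
  if (length(ci) == 0) return(integer(0))
  coords <- as.matrix(coords)
  hit <- within_cutoff(coords[ci, , drop = FALSE],
                       coords[ti, , drop = FALSE], cutoff)
  sort(unique(system$atoms$resid[ci[hit]]))
}

#' Adsorption time series: adsorbed atoms and contact area per frame
#'
#' @param traj a \code{mol_trajectory} with radii set on the atoms (only
#'   needed when \code{with_contact_area}).
#' @param rec_heavy,tube selections as in \code{\link{adsorbed_atom_count}}.
#' @param cutoff Angstrom (default 6).
#' @param stride frame stride >= 1 (default 1).
#' @param with_contact_area also compute the buried-interface area per
#'   frame (default TRUE).
#' @param probe_radius,n_points forwarded to \code{\link{sasa}}.
#' @return object of class \code{adsorption_series}: data.frame with
#'   \code{time}, \code{adsorbed_atoms}, and (when requested)
#'   \code{contact_area}, \code{sas_rec}, \code{sas_tube},
#'   \code{sas_complex}.
#' @export
adsorption_series <- function(traj, rec_heavy, tube, cutoff = 6.0, stride = 1L,
                              with_contact_area = TRUE,
                              probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(traj, "mol_trajectory"), stride >= 1)
  idx <- seq(1L, n_frames(traj), by = as.integer(stride))
  counts <- integer(length(idx))
  ca <- sr <- st <- sc <- rep(NA_real_, length(idx))
  radii <- traj$system$atoms$radius
  for (q in seq_along(idx)) {
    x <- frame_coords(traj, idx[q])
    counts[q] <- adsorbed_atom_count(x, rec_heavy, tube, cutoff)
    if (with_contact_area) {
      cc <- contact_area(x, rec_heavy, tube, radii, probe_radius, n_points)
      ca[q] <- cc$contact_area; sr[q] <- cc$sas_rec
      st[q] <- cc$sas_tube; sc[q] <- cc$sas_complex
    }
  }
  out <- data.frame(time = traj$times[idx], adsorbed_atoms = counts)
  if (with_contact_area) {
    out$contact_area <- ca; out$sas_rec <- sr
    out$sas_tube <- st; out$sas_complex <- sc
  }
  class(out) <- c("adsorption_series", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "stride") <- as.integer(stride)
  out
}
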