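#' Molecular system container
#'
#' A \code{mol_system} bundles an ordered atom table with an optional
#' periodic box. Atoms carry the per-atom inputs needed downstream:
#' radii (SASA), partial charges and Lennard-Jones parameters
#' (energetics), and a coarse group label used by selections.
#'
#' @param atoms data.frame with one row per atom. Required columns:
#'   \code{name}, \code{element}, \code{resid} (integer residue index,
#'   1-based), \code{resname}. Optional columns (filled with defaults when
#'   absent): \code{chain} (""), \code{radius} (NA), \code{charge} (NA),
#'   \code{epsilon} (NA), \code{sigma} (NA), \code{group} ("other").
#'   \code{group} must be one of \code{receptor}, \code{tube},
#'   \code{solvent}, \code{ligand}, \code{other}.
#' @param box optional numeric length-3 box vector in Angstrom.
#'
#' @return An object of class \code{mol_system}: a list with elements
#'   \code{atoms} (the completed atom table) and \code{box}.
#'
#' @details Residues are derived from \code{resid}: atoms of one residue
#'   must be contiguous so residue atom ranges partition the atom list.
#'   Units are Angstrom, elementary charges and kcal/mol throughout.
#'
#' @export
mol_system <- function(atoms, box = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "resid", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  defaults <- list(chain = "", radius = NA_real_, charge = NA_real_,
                   epsilon = NA_real_, sigma = NA_real_, group = "other")
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms$resid <- as.integer(atoms$resid)
  bad <- setdiff(unique(atoms$group), c("receptor", "tube", "solvent", "ligand", "other"))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  # contiguity: each resid forms one run
  runs <- rle(atoms$resid)$values
  if (anyDuplicated(runs))
    stop("atoms of one residue must be contiguous (resid ",
         runs[duplicated(runs)][1], " appears in separate runs)")
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = box), class = "mol_system")
}

#' Residue table of a system
#'
#' @param system a \code{mol_system}.
#' @return data.frame with columns \code{resid}, \code{resname},
#'   \code{first}, \code{last} (atom index range, 1-based inclusive).
#' @export
residues <- function(system) {
  stopifnot(inherits(system, "mol_system"))
  a <- system$atoms
  r <- rle(a$resid)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(resid = r$values,
             resname = a$resname[first],
             first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Number of atoms in a system
#' @param system a \code{mol_system}.
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' @export
print.mol_system <- function(x, ...) {
  res <- residues(x)
  cat(sprintf("mol_system: %d atoms, %d residues", nrow(x$atoms), nrow(res)))
  grp <- table(x$atoms$group)
  cat(" (", paste(sprintf("%s: %d", names(grp), grp), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$box))
    cat(sprintf("box: %.1f x %.1f x %.1f A\n", x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Trajectory container
#'
#' Ordered coordinate frames over one \code{mol_system}.
#'
#' @param system a \code{mol_system}.
#' @param coords numeric array of dimension \code{c(n_atoms, 3, n_frames)},
#'   or a list of \code{n_atoms x 3} matrices, in Angstrom.
#' @param times numeric vector of frame times in ps, strictly increasing.
#'   Defaults to \code{(0:(n_frames-1)) * dt}.
#' @param dt frame spacing in ps used when \code{times} is absent (default 1).
#' @return Object of class \code{mol_trajectory}: list with \code{system},
#'   \code{coords} (n_atoms x 3 x n_frames array), \code{times}.
#' @export
trajectory <- function(system, coords, times = NULL, dt = 1) {
  stopifnot(inherits(system, "mol_system"))
  if (is.list(coords) && !is.array(coords)) {
    nf <- length(coords)
    stopifnot(nf >= 1)
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, nf))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != n_atoms(system))
    stop(sprintf("frame atom count (%d) does not match system (%d)",
                 dim(coords)[1], n_atoms(system)))
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  times <- as.numeric(times)
  if (length(times) != nf)
    stop("length(times) must equal the number of frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(system = system, coords = coords, times = times),
            class = "mol_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a \code{mol_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj a \code{mol_trajectory}.
#' @param i frame index (1-based).
#' @return numeric matrix n_atoms x 3 (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  x <- traj$coords[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("mol_trajectory: %d frames x %d atoms, t = %.6g .. %.6g ps\n",
              n_frames(x), dim(x$coords)[1], x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

# element inference used at format boundaries: strip digits, take the
# leading letter; two-letter elements only when the PDB element column says so
infer_element <- function(name) {
  s <- gsub("[0-9'\"]", "", trimws(name))
  toupper(substr(s, 1, 1))
}

# default group assignment from residue name
infer_group <- function(resname) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN")
  wat <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC")
  ifelse(resname %in% aa, "receptor",
    ifelse(resname == "CNT", "tube",
      ifelse(resname %in% wat, "solvent", "other")))
}
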