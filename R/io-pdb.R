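#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses ATOM/HETATM records, one frame per MODEL (a file without MODEL
#' records yields a single frame). Atom identity and ordering are taken
#' from the first model; every subsequent model must match its atom count.
#'
#' @param path PDB file path.
#' @param model_range optional integer vector of model positions (in file
#'   order, 1-based) to keep.
#' @param dt frame spacing in ps used for the time axis (default 1).
#' @param groups optional named character vector mapping residue names to
#'   group labels, overriding the built-in inference (standard amino acids
#'   -> receptor, water -> solvent, \code{CNT} -> tube, else other).
#' @return a \code{mol_trajectory}.
#' @export
read_pdb <- function(path, model_range = NULL, dt = 1, groups = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("PDB format error: empty file: ", path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("PDB format error: no ATOM/HETATM records in ", path)

  # assign a model id to every atom line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines)) else
    model_id[model_id == 0L] <- 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  models <- unique(atom_model)

  counts <- tabulate(match(atom_model, models))
  if (length(unique(counts)) > 1) {
    bad <- models[which(counts != counts[1])[1]]
    stop(sprintf("PDB format error: model %d has %d atoms, expected %d",
                 bad, counts[which(models == bad)], counts[1]))
  }

  first <- atom_lines[atom_model == models[1]]
  name <- trimws(substr(first, 13, 16))
  resname <- trimws(substr(first, 18, 20))
  chain <- trimws(substr(first, 22, 22))
  resseq <- as.integer(substr(first, 23, 26))
  elem_col <- toupper(trimws(substr(first, 77, 78)))
  element <- ifelse(nzchar(elem_col), elem_col, infer_element(name))
  # re-index residues 1..n in order of appearance (resSeq kept via resname key)
  key <- paste(chain, resseq)
  resid <- as.integer(factor(key, levels = unique(key)))
  group <- infer_group(resname)
  if (!is.null(groups)) {
    hit <- resname %in% names(groups)
    group[hit] <- unname(groups[resname[hit]])
  }
  atoms <- data.frame(name = name, element = element, resid = resid,
                      resname = resname, chain = chain, group = group,
                      stringsAsFactors = FALSE)
  sys <- mol_system(atoms)

  xyz <- cbind(as.numeric(substr(atom_lines, 31, 38)),
               as.numeric(substr(atom_lines, 39, 46)),
               as.numeric(substr(atom_lines, 47, 54)))
  if (anyNA(xyz)) stop("PDB format error: unreadable coordinates in ", path)
  nf <- length(models)
  na <- counts[1]
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (k in seq_len(nf))
    coords[, , k] <- xyz[atom_model == models[k], , drop = FALSE]
  if (!is.null(model_range)) {
    coords <- coords[, , model_range, drop = FALSE]
    nf <- dim(coords)[3]
  }
  trajectory(sys, coords, times = (seq_len(nf) - 1) * dt)
}

#' Write a trajectory (or single frame) as a multi-model PDB
#'
#' @param traj a \code{mol_trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "mol_trajectory"))
  a <- traj$system$atoms
  nf <- n_frames(traj)
  res <- residues(traj$system)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nf > 1
  for (k in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    x <- frame_coords(traj, k)
    ln <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  seq_len(nrow(a)) %% 100000,
                  formatC(a$name, width = 4),
                  substr(a$resname, 1, 3),
                  ifelse(nzchar(a$chain), a$chain, "A"),
                  a$resid %% 10000, x[, 1], x[, 2], x[, 3], 1, 0,
                  toupper(a$element))
    writeLines(ln, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
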