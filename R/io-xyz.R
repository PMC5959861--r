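#' Read an XYZ trajectory against a known system
#'
#' Standard XYZ framing: atom count line, comment line, then one
#' \code{label x y z} line per atom. A comment line containing
#' \code{t = <value>} (or \code{time = <value>}) sets the frame time in ps;
#' otherwise times default to frame index x \code{dt}.
#'
#' @param path XYZ file path.
#' @param system the \code{mol_system} the frames belong to; every frame
#'   must have exactly \code{n_atoms(system)} atoms.
#' @param dt default frame spacing in ps (used when no time stamps).
#' @return a \code{mol_trajectory}.
#' @export
read_xyz_trajectory <- function(path, system, dt = 1) {
  stopifnot(inherits(system, "mol_system"))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("XYZ format error: empty file: ", path)
  na_sys <- n_atoms(system)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    k <- k + 1L
    if (is.na(cnt))
      stop(sprintf("XYZ format error: frame %d: bad atom-count line", k))
    if (cnt != na_sys)
      stop(sprintf("XYZ format error: frame %d has %d atoms, system has %d",
                   k, cnt, na_sys))
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    tm <- regmatches(comment,
                     regexpr("t(ime)?\\s*=\\s*-?[0-9.eE+-]+", comment))
    t_k <- if (length(tm) == 1)
      as.numeric(sub(".*=\\s*", "", tm)) else (k - 1) * dt
    body <- lines[(i + 2L):(i + 1L + cnt)]
    if (length(body) < cnt || anyNA(body))
      stop(sprintf("XYZ format error: frame %d truncated", k))
    fields <- strsplit(trimws(body), "\\s+")
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("XYZ format error: frame %d: unreadable coordinates", k))
    frames[[k]] <- xyz
    times[k] <- t_k
    i <- i + 2L + cnt
  }
  trajectory(system, frames, times = times)
}

#' Write a trajectory in XYZ format
#'
#' @param traj a \code{mol_trajectory}.
#' @param path output path.
#' @param digits coordinate decimal places (default 6; round trips are
#'   well inside 1e-4 Angstrom).
#' @return \code{path}, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "mol_trajectory"))
  a <- traj$system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-4s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("t = %.6f ps", traj$times[k]), con)
    x <- frame_coords(traj, k)
    writeLines(sprintf(fmt, a$element, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}
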