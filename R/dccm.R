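#' Aligned per-frame fluctuation vectors
#'
#' Superposes every frame onto the iteratively refined mean structure
#' (fit, recompute mean, refit, until the mean shifts by less than
#' \code{tol} or \code{max_iter} passes) and returns the displacement of
#' each selected atom from its mean position in each frame.
#'
#' @param traj a \code{mol_trajectory} with at least 2 frames.
#' @param ca_sel \code{atom_selection} (or indices) of the atoms whose
#'   fluctuations are wanted (typically C-alpha atoms).
#' @param align_sel selection used for the superposition fit (default:
#'   \code{ca_sel}).
#' @param tol mean-structure convergence threshold in Angstrom (1e-6).
#' @param max_iter fit iterations cap (10).
#' @return list with \code{disp}: array n_sel x 3 x n_frames of
#'   displacements (Angstrom); \code{mean}: n_sel x 3 mean structure;
#'   \code{iterations} used.
#' @export
fluctuation_matrix <- function(traj, ca_sel, align_sel = ca_sel,
                               tol = 1e-6, max_iter = 10L) {
  stopifnot(inherits(traj, "mol_trajectory"))
  if (n_frames(traj) < 2)
    stop("fluctuation_matrix: need at least 2 frames")
  ci <- if (inherits(ca_sel, "atom_selection")) ca_sel$indices else ca_sel
  ai <- if (inherits(align_sel, "atom_selection")) align_sel$indices else align_sel
  stopifnot(length(ci) >= 1, length(ai) >= 3)
  nf <- n_frames(traj)
  # work in the subspace of atoms needed (fit + measured)
  sub <- sort(unique(c(ci, ai)))
  ci_s <- match(ci, sub); ai_s <- match(ai, sub)
  X <- array(NA_real_, dim = c(length(sub), 3, nf))
  for (k in seq_len(nf)) X[, , k] <- frame_coords(traj, k)[sub, , drop = FALSE]

  ref <- X[, , 1]
  iter_used <- 0L
  for (it in seq_len(max_iter)) {
    fitted <- array(NA_real_, dim = dim(X))
    for (k in seq_len(nf)) {
      f <- kabsch_superpose(X[, , k], ref, ai_s)
      fitted[, , k] <- f$transform(X[, , k])
    }
    new_mean <- apply(fitted, c(1, 2), mean)
    shift <- max(abs(new_mean - ref))
    ref <- new_mean
    iter_used <- it
    if (it > 1 && shift < tol) break
  }
  # final pass against the converged mean
  fitted <- array(NA_real_, dim = dim(X))
  for (k in seq_len(nf)) {
    f <- kabsch_superpose(X[, , k], ref, ai_s)
    fitted[, , k] <- f$transform(X[, , k])
  }
  mean_str <- apply(fitted, c(1, 2), mean)
  disp <- sweep(fitted, c(1, 2), mean_str)
  list(disp = disp[ci_s, , , drop = FALSE],
       mean = mean_str[ci_s, , drop = FALSE],
       iterations = iter_used)
}

#' Dynamical cross-correlation matrix
#'
#' Normalized covariance of positional fluctuations:
#' \deqn{C(i,j) = c(i,j) / \sqrt{c(i,i) c(j,j)}, \quad
#'       c(i,j) = \langle \Delta r_i \cdot \Delta r_j \rangle}
#' with displacements from \code{\link{fluctuation_matrix}} (frames
#' superposed on the iterated mean structure).
#'
#' @param traj a \code{mol_trajectory} (>= 2 frames).
#' @param ca_sel selection of the atoms entering the matrix (one per
#'   residue, typically C-alpha).
#' @param align_sel fit selection (default \code{ca_sel}).
#' @param labels optional residue labels for the matrix dimnames.
#' @param zero_variance how to treat atoms with zero positional variance:
#'   \code{"error"} (default) or \code{"drop"}.
#' @return object of class \code{dccm_matrix}: the n x n correlation
#'   matrix with residue labels, symmetric, unit diagonal, entries in
#'   [-1, 1].
#' @export
dccm <- function(traj, ca_sel, align_sel = ca_sel, labels = NULL,
                 zero_variance = c("error", "drop")) {
  zero_variance <- match.arg(zero_variance)
  fl <- fluctuation_matrix(traj, ca_sel, align_sel)
  disp <- fl$disp
  n <- dim(disp)[1]; nf <- dim(disp)[3]
  # c(i,j) = mean over frames of dot(dr_i, dr_j): flatten to (n x 3nf)/sqrt style
  D <- matrix(aperm(disp, c(1, 3, 2)), nrow = n)  # n x (nf*3)
  C_raw <- D %*% t(D) / nf
  v <- diag(C_raw)
  if (is.null(labels)) {
    ci <- if (inherits(ca_sel, "atom_selection")) ca_sel$indices else ca_sel
    labels <- as.character(traj$system$atoms$resid[ci])
  }
  zero <- v <= 0 | !is.finite(v)
  if (any(zero)) {
    if (zero_variance == "error")
      stop("dccm: zero-variance residue(s): ",
           paste(labels[zero], collapse = ", "))
    keep <- !zero
    C_raw <- C_raw[keep, keep, drop = FALSE]
    v <- v[keep]; labels <- labels[keep]
    n <- sum(keep)
  }
  Cm <- C_raw / sqrt(outer(v, v))
  Cm <- (Cm + t(Cm)) / 2
  Cm[Cm > 1] <- 1; Cm[Cm < -1] <- -1
  diag(Cm) <- 1
  dimnames(Cm) <- list(labels, labels)
  class(Cm) <- c("dccm_matrix", "matrix", "array")
  Cm
}

#' Write a correlation matrix as labelled delimited text
#' @param mat a \code{dccm_matrix} (or plain matrix).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dccm <- function(mat, path) {
  m <- as.data.frame(unclass(mat))
  utils::write.table(cbind(residue = rownames(mat), m), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
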