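#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two coordinate sets over a fit selection, via the SVD of the covariance
#' matrix with the usual determinant sign correction.
#'
#' @param mobile n x 3 coordinate matrix to be moved (Angstrom).
#' @param reference n x 3 coordinate matrix held fixed.
#' @param fit_indices indices of the rows used for the fit (default: all).
#'   At least 3 non-collinear fit atoms are required.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom, over the fit atoms), and
#'   \code{transform(x)} applying the fit to any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (inherits(fit_indices, "atom_selection")) fit_indices <- fit_indices$indices
  if (length(fit_indices) < 3)
    stop("degenerate fit: need at least 3 fit atoms")
  A <- mobile[fit_indices, , drop = FALSE]
  B <- reference[fit_indices, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check on the fit set
  s <- svd(A0)$d
  if (s[2] < 1e-8 * max(s[1], 1e-12))
    stop("degenerate fit: fit atoms are collinear")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  transform <- function(x) sweep(as.matrix(x) %*% t(R), 2, t_vec, "+")
  list(rotation = R, translation = t_vec, rmsd = rmsd, transform = transform)
}

#' Root-mean-square deviation between coordinate sets
#'
#' @param a,b n x 3 matrices (same atoms, same order).
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed onto the reference over \code{fit_sel}; the
#' RMSD is then measured over \code{measure_sel} (which may differ, e.g.
#' fit on the whole receptor backbone, measure on pocket residues).
#'
#' @param traj a \code{mol_trajectory}.
#' @param reference n_atoms x 3 reference coordinates (full system).
#' @param fit_sel,measure_sel \code{atom_selection}s (or index vectors).
#'   \code{measure_sel} defaults to \code{fit_sel}.
#' @param reference_label,selection_label labels stored on the result.
#' @return object of class \code{rmsd_series}: data.frame with columns
#'   \code{time} (ps) and \code{rmsd} (Angstrom), plus label attributes.
#' @export
rmsd_series <- function(traj, reference, fit_sel, measure_sel = fit_sel,
                        reference_label = "reference",
                        selection_label = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"))
  fit_idx <- if (inherits(fit_sel, "atom_selection")) fit_sel$indices else fit_sel
  mea_idx <- if (inherits(measure_sel, "atom_selection")) measure_sel$indices else measure_sel
  if (length(fit_idx) == 0 || length(mea_idx) == 0)
    stop("empty selection in rmsd_series")
  reference <- as.matrix(reference)
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    fit <- kabsch_superpose(x, reference, fit_idx)
    xf <- fit$transform(x)
    out[k] <- coord_rmsd(xf[mea_idx, , drop = FALSE],
                         reference[mea_idx, , drop = FALSE])
  }
  res <- data.frame(time = traj$times, rmsd = out)
  attr(res, "reference_label") <- reference_label
  attr(res, "selection_label") <- selection_label %||%
    (if (inherits(measure_sel, "atom_selection")) measure_sel$label else "indices")
  class(res) <- c("rmsd_series", "data.frame")
  res
}
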