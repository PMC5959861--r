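#' Water occupancy density grid
#'
#' Bins water-oxygen positions into a regular cubic grid after rms-fitting
#' every frame onto a reference over a fit selection (typically all
#' receptor atoms). Waters falling outside the box are tallied separately
#' so counts are conserved exactly:
#' in-box + out-of-box = n_waters x n_frames.
#'
#' @param traj a \code{mol_trajectory}.
#' @param water_sel \code{atom_selection} (or indices) of water oxygen
#'   atoms; must be nonempty.
#' @param fit_sel selection used for the superposition (>= 3 atoms); NULL
#'   skips fitting (frames already aligned).
#' @param reference full-system reference coordinates (required when
#'   \code{fit_sel} is given).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param box cubic box edge in Angstrom (default 150); the grid is
#'   centered on \code{center}.
#' @param center grid center (default: centroid of the reference fit
#'   atoms, else the first frame's water centroid).
#' @param frames integer frame indices to bin (default: all).
#' @return object of class \code{density_grid}: list with \code{origin},
#'   \code{spacing}, \code{shape}, \code{counts} (3-D array),
#'   \code{n_frames}, \code{n_out_of_box}.
#' @export
water_density_grid <- function(traj, water_sel, fit_sel = NULL,
                               reference = NULL, spacing = 0.5, box = 150,
                               center = NULL, frames = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"), spacing > 0, box > 0)
  wi <- sel_idx(water_sel)
  if (length(wi) == 0) stop("water_density_grid: empty water selection")
  fi <- if (is.null(fit_sel)) NULL else sel_idx(fit_sel)
  if (!is.null(fi) && is.null(reference))
    stop("water_density_grid: reference required when fitting")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  nbin <- max(1L, round(box / spacing))
  if (is.null(center)) {
    center <- if (!is.null(fi)) colMeans(as.matrix(reference)[fi, , drop = FALSE])
              else colMeans(frame_coords(traj, frames[1])[wi, , drop = FALSE])
  }
  origin <- center - nbin * spacing / 2
  counts <- array(0L, dim = rep(nbin, 3))
  out_of_box <- 0L
  for (k in frames) {
    x <- frame_coords(traj, k)
    if (!is.null(fi))
      x <- kabsch_superpose(x, reference, fi)$transform(x)
    w <- x[wi, , drop = FALSE]
    ib <- floor(sweep(w, 2, origin) / spacing) + 1
    ok <- rowSums(ib >= 1 & ib <= nbin) == 3
    out_of_box <- out_of_box + sum(!ok)
    ib <- ib[ok, , drop = FALSE]
    if (nrow(ib) > 0) {
      lin <- ib[, 1] + (ib[, 2] - 1) * nbin + (ib[, 3] - 1) * nbin^2
      t_lin <- table(lin)
      counts[as.integer(names(t_lin))] <-
        counts[as.integer(names(t_lin))] + as.integer(t_lin)
    }
  }
  structure(list(origin = origin, spacing = spacing,
                 shape = rep(nbin, 3L), counts = counts,
                 n_frames = length(frames), n_out_of_box = out_of_box),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d^3 voxels at %.2f A, %d frames, %d in-box + %d out-of-box counts\n",
              x$shape[1], x$spacing, x$n_frames, sum(x$counts), x$n_out_of_box))
  invisible(x)
}

#' Axial water-count profile
#'
#' Mean per-frame number of water oxygens per Z bin after the same
#' optional rms fit as \code{\link{water_density_grid}}. The Z axis is
#' the membrane normal of the input frames; no axis auto-detection.
#'
#' @param traj a \code{mol_trajectory}.
#' @param water_sel water-oxygen selection.
#' @param bin_width Z bin width in Angstrom (> 0).
#' @param fit_sel,reference optional superposition, as in
#'   \code{\link{water_density_grid}}.
#' @param z_range length-2 range in Angstrom (default: data range over
#'   the first frame, expanded to whole bins).
#' @param frames frame indices (default all).
#' @return data.frame with \code{z} (bin centers) and \code{count}
#'   (mean per-frame waters in the bin); attribute
#'   \code{mean_in_range} = sum of counts.
#' @export
z_profile <- function(traj, water_sel, bin_width, fit_sel = NULL,
                      reference = NULL, z_range = NULL, frames = NULL) {
  stopifnot(inherits(traj, "mol_trajectory"), bin_width > 0)
  wi <- sel_idx(water_sel)
  if (length(wi) == 0) stop("z_profile: empty water selection")
  fi <- if (is.null(fit_sel)) NULL else sel_idx(fit_sel)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  get_z <- function(k) {
    x <- frame_coords(traj, k)
    if (!is.null(fi))
      x <- kabsch_superpose(x, reference, fi)$transform(x)
    x[wi, 3]
  }
  if (is.null(z_range)) {
    z0 <- get_z(frames[1])
    z_range <- c(floor(min(z0) / bin_width) * bin_width,
                 ceiling(max(z0) / bin_width) * bin_width)
    if (diff(z_range) < bin_width) z_range[2] <- z_range[1] + bin_width
  }
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (edges[length(edges)] < z_range[2])
    edges <- c(edges, edges[length(edges)] + bin_width)
  acc <- numeric(length(edges) - 1)
  for (k in frames) {
    z <- get_z(k)
    h <- graphics::hist(z[z >= edges[1] & z <= edges[length(edges)]],
                        breaks = edges, plot = FALSE)
    acc <- acc + h$counts
  }
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                    count = acc / length(frames))
  attr(out, "mean_in_range") <- sum(out$count)
  out
}

#' Write a density grid in OpenDX scalar-field format
#'
#' @param grid a \code{density_grid}.
#' @param path output path.
#' @param normalize write mean per-frame occupancy instead of raw counts
#'   (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_dx <- function(grid, path, normalize = TRUE) {
  stopifnot(inherits(grid, "density_grid"))
  n <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  v <- as.numeric(grid$counts)
  if (normalize) v <- v / grid$n_frames
  # OpenDX expects x fastest-varying last: emit in x-major order
  vv <- aperm(array(v, dim = n), c(3, 2, 1))
  v <- as.numeric(vv)
  idx <- seq(1, length(v), by = 3)
  lines <- vapply(idx, function(i)
    paste(sprintf("%.6g", v[i:min(i + 2, length(v))]), collapse = " "), "")
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}
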