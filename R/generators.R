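# run expr under a private RNG stream: the global .Random.seed is saved
# and restored, so generators are bit-reproducible and side-effect free
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a C-alpha chain trajectory with a specified correlation
#'
#' Draws Gaussian positional fluctuations around an extended C-alpha
#' chain from a specified residue-residue correlation model, identically
#' and independently in x, y, z, then removes the rigid-body component
#' of every frame (net translation and linearized rotation about the
#' reference). The emitted ground truth is the correlation matrix of the
#' projected fluctuations, computed analytically from the model -- the
#' quantity a correlation analysis of the frames estimates.
#'
#' @param n_residues chain length.
#' @param correlation either an n x n positive-semidefinite correlation
#'   matrix, or a list \code{list(kind = "blocks", blocks = list(c(i1, i2),
#'   ...), rho = within-block correlation)} or
#'   \code{list(kind = "decay", length_scale = L)} for
#'   \eqn{\rho_{ij} = exp(-|i-j|/L)}.
#' @param amplitude fluctuation scale in Angstrom (default 0.3).
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param spacing C-alpha spacing along the chain axis (3.8 A).
#' @return list with \code{trajectory} (a \code{mol_trajectory} of CA
#'   atoms, group receptor) and \code{truth} (list: \code{dccm_true},
#'   \code{correlation_input}, \code{amplitude}, \code{seed}).
#' @export
gen_correlated_trajectory <- function(n_residues, correlation, amplitude = 0.3,
                                      n_frames = 1000, seed = 1,
                                      spacing = 3.8) {
  n <- as.integer(n_residues)
  stopifnot(n >= 2, n_frames >= 2, amplitude > 0)
  R <- build_correlation(n, correlation)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation specification is not positive semidefinite")
  # reference: gentle helix so the chain is non-collinear (fit needs 3-D)
  t_ax <- seq_len(n)
  r0 <- cbind(2 * cos(t_ax * 0.6), 2 * sin(t_ax * 0.6), spacing * t_ax)
  # rigid modes at the reference (Eckart frame): 3 translations + 3
  # linearized rotations, orthonormalized
  cen <- colMeans(r0)
  rc <- sweep(r0, 2, cen)
  modes <- matrix(0, 3 * n, 6)
  for (d in 1:3) modes[seq(d, 3 * n, by = 3), d] <- 1
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  for (k in 1:3) {
    e <- list(ex, ey, ez)[[k]]
    v <- t(apply(rc, 1, function(p) c(e[2] * p[3] - e[3] * p[2],
                                      e[3] * p[1] - e[1] * p[3],
                                      e[1] * p[2] - e[2] * p[1])))
    modes[, 3 + k] <- as.numeric(t(v))
  }
  Q <- qr.Q(qr(modes))
  # covariance of stacked (atom-major, dim-fast) fluctuations: R x I3
  S <- matrix(0, 3 * n, 3 * n)
  for (d in 1:3) {
    idx <- seq(d, 3 * n, by = 3)
    S[idx, idx] <- amplitude^2 * R
  }
  P <- diag(3 * n) - Q %*% t(Q)
  Sp <- P %*% S %*% t(P)
  # contract over dimensions: c(i,j) = sum_d Sp[(i,d),(j,d)]
  cmat <- matrix(0, n, n)
  for (d in 1:3) {
    idx <- seq(d, 3 * n, by = 3)
    cmat <- cmat + Sp[idx, idx]
  }
  dvar <- diag(cmat)
  dccm_true <- cmat / sqrt(outer(dvar, dvar))

  L <- chol_psd(R)
  coords <- with_seed(seed, {
    out <- array(NA_real_, dim = c(n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      Z <- matrix(stats::rnorm(n * 3), n, 3)
      disp <- amplitude * (L %*% Z)            # n x 3, per-dim cov R
      y <- as.numeric(t(disp))                 # stacked, dim-fast
      yp <- y - Q %*% (t(Q) %*% y)             # remove rigid component
      out[, , f] <- r0 + matrix(yp, n, 3, byrow = TRUE)
    }
    out
  })
  atoms <- data.frame(name = "CA", element = "C", resid = seq_len(n),
                      resname = "ALA", group = "receptor",
                      stringsAsFactors = FALSE)
  sys <- mol_system(atoms)
  list(trajectory = trajectory(sys, coords),
       truth = list(dccm_true = dccm_true, correlation_input = R,
                    amplitude = amplitude, seed = seed))
}

build_correlation <- function(n, correlation) {
  if (is.matrix(correlation)) {
    stopifnot(nrow(correlation) == n, ncol(correlation) == n)
    return(correlation)
  }
  stopifnot(is.list(correlation), !is.null(correlation$kind))
  if (correlation$kind == "blocks") {
    R <- diag(n)
    for (b in correlation$blocks) {
      idx <- b[1]:b[2]
      R[idx, idx] <- correlation$rho
    }
    diag(R) <- 1
    return(R)
  }
  if (correlation$kind == "decay") {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    return(exp(-d / correlation$length_scale))
  }
  stop("unknown correlation kind: ", correlation$kind)
}

chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v))
}

#' Generate a staged helix-bundle-on-nanotube adsorption trajectory
#'
#' A rigid coarse four-helix bundle (CA plus a CB pseudo-side-chain
#' carbon per residue) approaches a cylindrical carbon lattice in
#' programmed stages: each schedule entry holds the bundle at a given
#' surface separation for a frame range, with optional per-frame seeded
#' jitter. Ground-truth adsorbed-atom counts are computed by all-pairs
#' brute force at generation time.
#'
#' @param schedule data.frame with columns \code{from}, \code{to}
#'   (frame ranges, 1-based inclusive, non-overlapping and covering
#'   1..n_frames) and \code{separation} (bundle-to-surface gap in
#'   Angstrom, >= 0).
#' @param n_res_per_helix residues per helix (default 8).
#' @param tube_length tube length in Angstrom (default 40).
#' @param tube_radius tube radius in Angstrom (default 6.8).
#' @param jitter per-frame Gaussian positional noise sd in Angstrom
#'   (default 0; the schedule separations are exact).
#' @param cutoff adsorption criterion used for the emitted ground truth
#'   (default 6).
#' @param seed RNG seed.
#' @return list with \code{trajectory} (system groups: receptor +
#'   tube; all atoms carbon, radius 1.7) and \code{truth} (list:
#'   \code{counts} per frame, \code{plateau_counts} per schedule row,
#'   \code{schedule}, \code{cutoff}, \code{seed}).
#' @export
gen_adsorption_trajectory <- function(schedule, n_res_per_helix = 8L,
                                      tube_length = 40, tube_radius = 6.8,
                                      jitter = 0, cutoff = 6.0, seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("from", "to", "separation") %in% names(schedule)))
  if (any(schedule$separation < 0)) stop("schedule separations must be >= 0")
  sched <- schedule[order(schedule$from), , drop = FALSE]
  covered <- unlist(Map(seq, sched$from, sched$to))
  if (anyDuplicated(covered)) stop("overlapping schedule frame ranges")
  n_frames <- max(sched$to)
  if (!identical(sort(covered), seq_len(n_frames)))
    stop("schedule frame ranges must cover 1..n_frames without gaps")

  # coarse four-helix bundle: helices along z, CA on a 2.3 A-radius
  # spiral, CB pushed 1.5 A outward
  nr <- as.integer(n_res_per_helix)
  helix_xy <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  ca <- cb <- NULL
  resid <- integer(0)
  rid <- 0L
  for (h in 1:4) {
    for (i in seq_len(nr)) {
      rid <- rid + 1L
      ang <- i * 100 * pi / 180
      base <- c(helix_xy[h, 1] + 2.3 * cos(ang),
                helix_xy[h, 2] + 2.3 * sin(ang), 1.5 * i)
      dir <- c(cos(ang), sin(ang), 0)
      ca <- rbind(ca, base)
      cb <- rbind(cb, base + 1.5 * dir)
      resid <- c(resid, rid)
    }
  }
  n_res <- rid
  bundle <- matrix(NA_real_, 2 * n_res, 3)
  bundle[seq(1, 2 * n_res, 2), ] <- ca
  bundle[seq(2, 2 * n_res, 2), ] <- cb
  b_res <- rep(resid, each = 2)
  b_name <- rep(c("CA", "CB"), n_res)

  # tube: hexagonal-ish carbon lattice on a cylinder along z
  n_around <- max(8L, round(2 * pi * tube_radius / 2.46))
  n_along <- max(2L, round(tube_length / 2.13))
  th <- (seq_len(n_around) - 1) * 2 * pi / n_around
  tube <- NULL
  for (iz in seq_len(n_along)) {
    off <- if (iz %% 2 == 0) pi / n_around else 0
    tube <- rbind(tube, cbind(tube_radius * cos(th + off),
                              tube_radius * sin(th + off),
                              (iz - 1) * tube_length / (n_along - 1)))
  }
  # place the tube axis parallel to z at x = -(tube_radius + gap) from
  # the bundle's min-x face; approach along x
  bundle_span_z <- range(bundle[, 3])
  tube[, 3] <- tube[, 3] - mean(range(tube[, 3])) + mean(bundle_span_z)
  tube[, 2] <- tube[, 2] + mean(range(bundle[, 2]))

  atoms <- data.frame(
    name = c(b_name, rep("C1", nrow(tube))),
    element = "C",
    resid = c(b_res, rep(n_res + 1L, nrow(tube))),
    resname = c(rep("ALA", 2 * n_res), rep("CNT", nrow(tube))),
    group = c(rep("receptor", 2 * n_res), rep("tube", nrow(tube))),
    radius = 1.7, charge = 0, epsilon = 0.086, sigma = 3.4,
    stringsAsFactors = FALSE)
  sys <- mol_system(atoms)

  min_bx <- min(bundle[, 1])
  coords <- with_seed(seed, {
    out <- array(NA_real_, dim = c(nrow(atoms), 3, n_frames))
    for (r in seq_len(nrow(sched))) {
      gap <- sched$separation[r]
      # tube surface at x = tube_center_x + tube_radius; bundle min-x
      # face sits `gap` beyond it
      tube_cx <- min_bx - gap - tube_radius
      tshift <- tube
      tshift[, 1] <- tshift[, 1] + tube_cx
      for (f in sched$from[r]:sched$to[r]) {
        jit_b <- if (jitter > 0)
          matrix(stats::rnorm(length(bundle), 0, jitter), ncol = 3) else 0
        out[, , f] <- rbind(bundle + jit_b, tshift)
      }
    }
    out
  })

  # ground truth by brute force (all receptor atoms are heavy carbons)
  n_b <- 2 * n_res
  counts <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    bx <- coords[seq_len(n_b), , f]
    tx <- coords[(n_b + 1):nrow(atoms), , f]
    d2 <- outer(rowSums(bx^2), rowSums(tx^2), "+") - 2 * bx %*% t(tx)
    counts[f] <- sum(apply(d2, 1, min) <= cutoff^2 + 1e-12)
  }
  plateau <- vapply(seq_len(nrow(sched)),
                    function(r) counts[sched$from[r]], integer(1))
  list(trajectory = trajectory(sys, coords),
       truth = list(counts = counts, plateau_counts = plateau,
                    schedule = sched, cutoff = cutoff, seed = seed))
}

#' Generate a water box with a programmed axial density profile
#'
#' Water oxygens are placed uniformly in x, y and drawn along z from a
#' piecewise-constant density, independently each frame.
#'
#' @param n_waters waters per frame.
#' @param axial_profile data.frame with columns \code{z_min}, \code{z_max},
#'   \code{weight} (relative densities, >= 0, at least one > 0); weights
#'   are normalized to integrate to 1 over the listed slabs.
#' @param box length-3 box vector in Angstrom (x, y span the box; z
#'   samples use the profile slabs).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with \code{trajectory} (O atoms, group solvent) and
#'   \code{truth} (list: \code{profile} with normalized densities,
#'   \code{expected_per_slab} = n_waters x slab probability,
#'   \code{seed}).
#' @export
gen_water_box <- function(n_waters, axial_profile, box = c(30, 30, 30),
                          n_frames = 10, seed = 1) {
  stopifnot(is.data.frame(axial_profile),
            all(c("z_min", "z_max", "weight") %in% names(axial_profile)))
  if (any(axial_profile$weight < 0)) stop("negative density in axial profile")
  if (all(axial_profile$weight == 0)) stop("axial profile has zero mass")
  widths <- axial_profile$z_max - axial_profile$z_min
  stopifnot(all(widths > 0))
  mass <- axial_profile$weight * widths
  p_slab <- mass / sum(mass)
  coords <- with_seed(seed, {
    out <- array(NA_real_, dim = c(n_waters, 3, n_frames))
    for (f in seq_len(n_frames)) {
      slab <- sample.int(nrow(axial_profile), n_waters, replace = TRUE,
                         prob = p_slab)
      z <- stats::runif(n_waters, axial_profile$z_min[slab],
                        axial_profile$z_max[slab])
      out[, , f] <- cbind(stats::runif(n_waters, 0, box[1]),
                          stats::runif(n_waters, 0, box[2]), z)
    }
    out
  })
  atoms <- data.frame(name = "O", element = "O",
                      resid = seq_len(n_waters), resname = "WAT",
                      group = "solvent", radius = 1.52,
                      stringsAsFactors = FALSE)
  sys <- mol_system(atoms, box = box)
  prof <- axial_profile
  prof$density <- p_slab / widths
  list(trajectory = trajectory(sys, coords),
       truth = list(profile = prof,
                    expected_per_slab = n_waters * p_slab,
                    seed = seed))
}

#' Generate a fully parameterized toy receptor-ligand complex
#'
#' Random coordinates, charges and Lennard-Jones parameters for a small
#' two-group system, with reference interaction energies computed by
#' brute-force double loops at generation time.
#'
#' @param n_receptor_atoms,n_ligand_atoms group sizes.
#' @param charge_range length-2 charge range in e (default c(-0.5, 0.5));
#'   use c(0, 0) for an uncharged system.
#' @param epsilon_range,sigma_range LJ parameter ranges (kcal/mol, A).
#' @param separation center-to-center distance between the two groups in
#'   Angstrom (default 8).
#' @param spread coordinate spread within each group (default 2.5).
#' @param seed RNG seed.
#' @return list with \code{system} (a \code{mol_system}), \code{coords}
#'   (n x 3), \code{receptor_sel}, \code{ligand_sel}
#'   (\code{atom_selection}s), and \code{truth} (list: \code{ele},
#'   \code{vdw} reference energies by brute force, \code{seed}).
#' @export
gen_toy_complex <- function(n_receptor_atoms = 8L, n_ligand_atoms = 3L,
                            charge_range = c(-0.5, 0.5),
                            epsilon_range = c(0.05, 0.2),
                            sigma_range = c(2.8, 3.8),
                            separation = 8, spread = 2.5, seed = 1) {
  nr <- as.integer(n_receptor_atoms); nl <- as.integer(n_ligand_atoms)
  stopifnot(nr >= 1, nl >= 1, all(is.finite(c(charge_range, epsilon_range,
                                              sigma_range))))
  dat <- with_seed(seed, {
    xr <- matrix(stats::runif(nr * 3, -spread, spread), nr, 3)
    xl <- sweep(matrix(stats::runif(nl * 3, -spread, spread), nl, 3),
                2, c(separation, 0, 0), "+")
    q <- stats::runif(nr + nl, charge_range[1], charge_range[2])
    ep <- stats::runif(nr + nl, epsilon_range[1], epsilon_range[2])
    sg <- stats::runif(nr + nl, sigma_range[1], sigma_range[2])
    list(x = rbind(xr, xl), q = q, ep = ep, sg = sg)
  })
  atoms <- data.frame(
    name = paste0("X", seq_len(nr + nl)), element = "C",
    resid = c(rep(1L, nr), rep(2L, nl)),
    resname = c(rep("REC", nr), rep("LIG", nl)),
    group = c(rep("receptor", nr), rep("ligand", nl)),
    radius = 1.7, charge = dat$q, epsilon = dat$ep, sigma = dat$sg,
    stringsAsFactors = FALSE)
  sys <- mol_system(atoms)
  # brute-force references (plain double loops, no vectorization)
  ele <- 0; vdw <- 0
  for (i in seq_len(nr)) for (j in (nr + 1):(nr + nl)) {
    r <- sqrt(sum((dat$x[i, ] - dat$x[j, ])^2))
    ele <- ele + K_COULOMB * dat$q[i] * dat$q[j] / r
    eab <- sqrt(dat$ep[i] * dat$ep[j])
    sab <- (dat$sg[i] + dat$sg[j]) / 2
    vdw <- vdw + 4 * eab * ((sab / r)^12 - (sab / r)^6)
  }
  list(system = sys, coords = dat$x,
       receptor_sel = select_atoms(sys, "group:receptor", label = "receptor"),
       ligand_sel = select_atoms(sys, "group:ligand", label = "ligand"),
       truth = list(ele = ele, vdw = vdw, seed = seed))
}

#' Generate an odorant score table with known score model
#'
#' Descriptors are drawn uniformly within the stated ranges; scores
#' follow either a monotone response in a chosen descriptor or a
#' turnover model (affinity strengthens up to a stated volume, then
#' weakens), plus Gaussian noise. More negative scores mean stronger
#' binding throughout.
#'
#' @param n number of odorants (default 132).
#' @param mw_range,volume_range,logP_range descriptor ranges (defaults
#'   42-236 g/mol, 45-267 A^3, 0.7-9.6).
#' @param score_model \code{"monotone"} (score decreases linearly with
#'   the descriptor) or \code{"turnover"} (decreases until
#'   \code{turnover_volume}, then increases).
#' @param descriptor descriptor driving the score (default
#'   \code{"volume"}).
#' @param turnover_volume turnover point in A^3 (default 170).
#' @param slope score change per descriptor unit (default 0.03
#'   kcal/mol per unit; sign handled by the model).
#' @param base_score intercept (default -4 kcal/mol).
#' @param noise_sd Gaussian score noise (default 0.5).
#' @param seed RNG seed.
#' @return list with \code{records} (an \code{odor_table}; classes drawn
#'   from the common odorant chemical classes) and \code{truth}
#'   (model parameters).
#' @export
gen_odor_table <- function(n = 132L, mw_range = c(42, 236),
                           volume_range = c(45, 267),
                           logP_range = c(0.7, 9.6),
                           score_model = c("monotone", "turnover"),
                           descriptor = "volume", turnover_volume = 170,
                           slope = 0.03, base_score = -4, noise_sd = 0.5,
                           seed = 1) {
  score_model <- match.arg(score_model)
  stopifnot(mw_range[1] < mw_range[2], volume_range[1] < volume_range[2],
            logP_range[1] < logP_range[2])
  classes <- c("alcohol", "ketone", "acid", "ester", "aldehyde",
               "ether", "aromatic", "other")
  dat <- with_seed(seed, {
    mw <- stats::runif(n, mw_range[1], mw_range[2])
    vol <- stats::runif(n, volume_range[1], volume_range[2])
    lp <- stats::runif(n, logP_range[1], logP_range[2])
    cl <- sample(classes, n, replace = TRUE)
    noise <- stats::rnorm(n, 0, noise_sd)
    list(mw = mw, vol = vol, lp = lp, cl = cl, noise = noise)
  })
  x <- switch(descriptor, mol_weight = dat$mw, volume = dat$vol,
              logP = dat$lp, stop("unknown descriptor: ", descriptor))
  det <- if (score_model == "monotone") {
    base_score - slope * x
  } else {
    base_score - slope * (turnover_volume - abs(x - turnover_volume))
  }
  records <- data.frame(
    id = sprintf("odor%03d", seq_len(n)),
    score = det + dat$noise,
    mol_weight = dat$mw, volume = dat$vol, logP = dat$lp,
    chem_class = dat$cl, stringsAsFactors = FALSE)
  class(records) <- c("odor_table", "data.frame")
  list(records = records,
       truth = list(model = score_model, descriptor = descriptor,
                    turnover_volume = if (score_model == "turnover")
                      turnover_volume else NA_real_,
                    slope = slope, base_score = base_score,
                    noise_sd = noise_sd, deterministic_score = det,
                    seed = seed))
}

#' Write a generator's ground truth as YAML
#'
#' @param truth a generator \code{truth} list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  clean <- rapply(truth, function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x
  }, how = "replace")
  yaml::write_yaml(clean, path)
  invisible(path)
}
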