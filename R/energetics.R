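# electrostatic conversion constant, kcal A mol^-1 e^-2
K_COULOMB <- 332.0637

sel_idx <- function(sel) if (inherits(sel, "atom_selection")) sel$indices else sel

pair_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Inter-group Coulomb energy
#'
#' All-pairs electrostatic interaction between two disjoint selections:
#' \deqn{E = \sum_{a \in A, b \in B} k q_a q_b / (\epsilon r_{ab})}
#' with k = 332.0637 kcal A mol^-1 e^-2 and no distance cutoff.
#'
#' @param coords full-system coordinates (Angstrom).
#' @param selA,selB disjoint \code{atom_selection}s (or index vectors).
#' @param charges per-atom partial charges (e) for the full system.
#' @param dielectric relative dielectric (default 1).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, selA, selB, charges, dielectric = 1) {
  ia <- sel_idx(selA); ib <- sel_idx(selB)
  if (length(intersect(ia, ib)) > 0) stop("coulomb_energy: selections overlap")
  qa <- charges[ia]; qb <- charges[ib]
  if (anyNA(qa) || anyNA(qb)) stop("unparameterized atom: missing charge")
  coords <- as.matrix(coords)
  r <- pair_distances(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  if (any(r < 1e-6)) stop("coulomb_energy: coincident atom pair (r < 1e-6 A)")
  sum(K_COULOMB * outer(qa, qb) / (dielectric * r))
}

#' Inter-group Lennard-Jones energy
#'
#' All-pairs 12-6 interaction with Lorentz-Berthelot combining:
#' \deqn{E = \sum 4\epsilon_{ab}[(\sigma_{ab}/r)^{12} - (\sigma_{ab}/r)^6]},
#' \eqn{\epsilon_{ab} = \sqrt{\epsilon_a \epsilon_b}},
#' \eqn{\sigma_{ab} = (\sigma_a + \sigma_b)/2}; no cutoff.
#'
#' @param coords full-system coordinates (Angstrom).
#' @param selA,selB disjoint selections.
#' @param epsilon,sigma per-atom LJ parameters (kcal/mol, Angstrom).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(coords, selA, selB, epsilon, sigma) {
  ia <- sel_idx(selA); ib <- sel_idx(selB)
  if (length(intersect(ia, ib)) > 0) stop("lj_energy: selections overlap")
  ea <- epsilon[ia]; eb <- epsilon[ib]
  sa <- sigma[ia]; sb <- sigma[ib]
  if (anyNA(ea) || anyNA(eb) || anyNA(sa) || anyNA(sb))
    stop("unparameterized atom: missing LJ parameters")
  coords <- as.matrix(coords)
  r <- pair_distances(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  if (any(r < 1e-6)) stop("lj_energy: coincident atom pair (r < 1e-6 A)")
  eab <- sqrt(outer(ea, eb))
  sab <- outer(sa, sb, "+") / 2
  sr6 <- (sab / r)^6
  sum(4 * eab * (sr6^2 - sr6))
}

#' Nonpolar solvation energy from SASA
#'
#' Surface-tension model \eqn{G_{npsolv} = \gamma \times SASA}.
#'
#' @param sasa_value solvent-accessible surface area, Angstrom^2 (>= 0).
#' @param gamma surface tension, kcal mol^-1 A^-2 (default 0.0072).
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_value, gamma = 0.0072) {
  if (any(sasa_value < 0)) stop("nonpolar_solvation: negative SASA")
  gamma * sasa_value
}

#' Polar solvation energy (pluggable model)
#'
#' The polar solvation term is a pluggable contract: deterministic per
#' frame and additive over atoms. Built-in models:
#' \itemize{
#'   \item \code{"zero"}: 0 regardless of charges (useful when polar
#'     solvation is supplied externally or deliberately omitted).
#'   \item \code{"born"}: Born-style screening. Self terms
#'     \eqn{-\tfrac12 (1/\epsilon_{in} - 1/\epsilon_{out}) k q_i^2 / (R_i + probe)}
#'     plus pairwise screened cross terms with the effective radius
#'     \eqn{f_{ij} = \sqrt{r_{ij}^2 + B_i B_j}} (with
#'     \eqn{B_i = R_i + probe}), a smooth generalized-Born-like
#'     interpolation recorded in run manifests.
#' }
#' A finite-difference Poisson-Boltzmann solver is deliberately out of
#' scope; quantitative agreement with grid PB values is not claimed.
#'
#' @param coords coordinates of the selected atoms only, or full-system
#'   coordinates with \code{sel} given.
#' @param charges,radii per-atom charges (e) and radii (Angstrom),
#'   full-system when \code{sel} is given.
#' @param sel optional \code{atom_selection} restricting the computation.
#' @param model \code{"born"} (default) or \code{"zero"}, or a function
#'   \code{f(coords, charges, radii)} returning kcal/mol.
#' @param eps_in,eps_out interior/exterior dielectrics (defaults 1, 80).
#' @param probe_radius added to atomic radii for the Born radii
#'   (default 1.4).
#' @return energy in kcal/mol.
#' @export
polar_solvation <- function(coords, charges, radii, sel = NULL,
                            model = "born", eps_in = 1, eps_out = 80,
                            probe_radius = 1.4) {
  if (!is.null(sel)) {
    ii <- sel_idx(sel)
    coords <- as.matrix(coords)[ii, , drop = FALSE]
    charges <- charges[ii]; radii <- radii[ii]
  } else coords <- as.matrix(coords)
  if (is.function(model)) return(model(coords, charges, radii))
  model <- match.arg(model, c("born", "zero"))
  if (model == "zero") return(0)
  if (anyNA(charges) || anyNA(radii))
    stop("unparameterized atom: missing charge or radius")
  if (all(charges == 0)) return(0)
  B <- radii + probe_radius
  if (any(B <= 0)) stop("polar_solvation: non-positive Born radius")
  pref <- -0.5 * (1 / eps_in - 1 / eps_out) * K_COULOMB
  n <- nrow(coords)
  e_self <- sum(pref * charges^2 / B)
  if (n < 2) return(e_self)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * coords %*% t(coords)
  f <- sqrt(pmax(d2, 0) + outer(B, B))
  qq <- outer(charges, charges)
  cross <- sum((pref * qq / f)[upper.tri(f)]) * 2
  e_self + cross
}

#' Assemble an energy-components ledger
#'
#' @param ele,vdw,npsolv,psolv component values in kcal/mol (scalars).
#' @param se optional named numeric vector of standard errors (names among
#'   ele, vdw, gas, npsolv, psolv, solv, binding).
#' @param n_frames number of frames averaged.
#' @param int internal energy (0 in single-trajectory mode).
#' @return object of class \code{energy_components}: list with ele, vdw,
#'   int, gas, npsolv, psolv, solv, binding, se, n_frames; the identities
#'   gas = ele + vdw + int, solv = npsolv + psolv,
#'   binding = gas + solv hold by construction.
#' @export
energy_components <- function(ele, vdw, npsolv, psolv, se = NULL,
                              n_frames = NA_integer_, int = 0) {
  gas <- ele + vdw + int
  solv <- npsolv + psolv
  structure(list(ele = ele, vdw = vdw, int = int, gas = gas,
                 npsolv = npsolv, psolv = psolv, solv = solv,
                 binding = gas + solv, se = se,
                 n_frames = as.integer(n_frames)),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  lab <- c("ele", "vdw", "gas", "npsolv", "psolv", "solv", "binding")
  for (l in lab) {
    s <- if (!is.null(x$se) && l %in% names(x$se))
      sprintf(" +/- %.1f", x$se[[l]]) else ""
    cat(sprintf("%-8s %8.1f%s kcal/mol\n", l, x[[l]], s))
  }
  if (!is.na(x$n_frames)) cat(sprintf("n_frames %d\n", x$n_frames))
  invisible(x)
}

block_se <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) return(stats::sd(x) / sqrt(max(n, 1)))
  grp <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, grp, mean)
  stats::sd(bm) / sqrt(n_blocks)
}

#' Single-trajectory MM-PBSA-style binding energy
#'
#' Per-frame interaction components between receptor and ligand, taken
#' from complex frames only (so the internal term cancels exactly):
#' gas = ele + vdw (all-pairs, no cutoff); nonpolar solvation from the
#' SASA change gamma * (SASA_complex - SASA_receptor - SASA_ligand);
#' polar solvation from the pluggable model as the same complex-minus-
#' parts difference. Components are averaged over the frame window with
#' standard errors from 5-block averaging; the conformational-entropy
#' term is omitted throughout.
#'
#' @param traj a \code{mol_trajectory} whose atoms carry charges, LJ
#'   parameters and radii.
#' @param receptor_sel,ligand_sel disjoint selections partitioning the
#'   complex.
#' @param window integer frame indices to average over (default: all).
#' @param stride frame stride within the window (default 1).
#' @param gamma surface tension for nonpolar solvation (0.0072).
#' @param polar_model forwarded to \code{\link{polar_solvation}}
#'   (default \code{"born"}).
#' @param eps_in,eps_out dielectrics for the polar model (1, 80).
#' @param probe_radius,n_points SASA parameters (1.4, 960).
#' @param n_blocks blocks for the standard error (5).
#' @return an \code{energy_components} object; per-frame component series
#'   attached as attribute \code{"frames"}.
#' @export
binding_energy <- function(traj, receptor_sel, ligand_sel, window = NULL,
                           stride = 1L, gamma = 0.0072, polar_model = "born",
                           eps_in = 1, eps_out = 80, probe_radius = 1.4,
                           n_points = 960, n_blocks = 5) {
  stopifnot(inherits(traj, "mol_trajectory"))
  ri <- sel_idx(receptor_sel); li <- sel_idx(ligand_sel)
  if (length(intersect(ri, li)) > 0)
    stop("binding_energy: receptor and ligand selections overlap")
  if (is.null(window)) window <- seq_len(n_frames(traj))
  if (any(window < 1) || any(window > n_frames(traj)))
    stop("binding_energy: window outside trajectory")
  window <- window[seq(1, length(window), by = as.integer(stride))]
  a <- traj$system$atoms
  q <- a$charge; epsv <- a$epsilon; sig <- a$sigma; rad <- a$radius
  un <- c(ri, li)
  nf <- length(window)
  ele <- vdw <- npv <- psv <- numeric(nf)
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, window[k])
    ele[k] <- coulomb_energy(x, ri, li, q)
    vdw[k] <- lj_energy(x, ri, li, epsv, sig)
    s_cpx <- sasa(x[un, , drop = FALSE], rad[un], probe_radius, n_points)$total
    s_rec <- sasa(x[ri, , drop = FALSE], rad[ri], probe_radius, n_points)$total
    s_lig <- sasa(x[li, , drop = FALSE], rad[li], probe_radius, n_points)$total
    npv[k] <- nonpolar_solvation(s_cpx, gamma) -
      nonpolar_solvation(s_rec, gamma) - nonpolar_solvation(s_lig, gamma)
    p_cpx <- polar_solvation(x, q, rad, sel = un, model = polar_model,
                             eps_in = eps_in, eps_out = eps_out,
                             probe_radius = probe_radius)
    p_rec <- polar_solvation(x, q, rad, sel = ri, model = polar_model,
                             eps_in = eps_in, eps_out = eps_out,
                             probe_radius = probe_radius)
    p_lig <- polar_solvation(x, q, rad, sel = li, model = polar_model,
                             eps_in = eps_in, eps_out = eps_out,
                             probe_radius = probe_radius)
    psv[k] <- p_cpx - p_rec - p_lig
  }
  se <- c(ele = block_se(ele, n_blocks), vdw = block_se(vdw, n_blocks),
          gas = block_se(ele + vdw, n_blocks),
          npsolv = block_se(npv, n_blocks), psolv = block_se(psv, n_blocks),
          solv = block_se(npv + psv, n_blocks),
          binding = block_se(ele + vdw + npv + psv, n_blocks))
  out <- energy_components(mean(ele), mean(vdw), mean(npv), mean(psv),
                           se = se, n_frames = nf)
  attr(out, "frames") <- data.frame(frame = window, ele = ele, vdw = vdw,
                                    npsolv = npv, psolv = psv)
  out
}

#' Per-residue decomposition of the binding energy
#'
#' Residue r receives its full pairwise gas-phase terms with the ligand,
#' the nonpolar solvation delta of its own atoms plus the ligand's
#' burial apportioned by the residue's share of the receptor-side SASA
#' change, and (under the Born model) the full screened cross terms
#' between its atoms and the ligand -- so the profile sums exactly to
#' the corresponding \code{\link{binding_energy}} totals.
#'
#' @param traj,receptor_sel,ligand_sel,window,stride as
#'   \code{\link{binding_energy}}.
#' @param gamma,polar_model,eps_in,eps_out,probe_radius,n_points as
#'   \code{\link{binding_energy}}.
#' @return object of class \code{residue_energy_profile}: data.frame with
#'   \code{resid}, \code{resname}, \code{energy} (kcal/mol, averaged over
#'   the window).
#' @export
per_residue_decomposition <- function(traj, receptor_sel, ligand_sel,
                                      window = NULL, stride = 1L,
                                      gamma = 0.0072, polar_model = "born",
                                      eps_in = 1, eps_out = 80,
                                      probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(traj, "mol_trajectory"))
  ri <- sel_idx(receptor_sel); li <- sel_idx(ligand_sel)
  if (is.null(window)) window <- seq_len(n_frames(traj))
  if (any(window < 1) || any(window > n_frames(traj)))
    stop("per_residue_decomposition: window outside trajectory")
  window <- window[seq(1, length(window), by = as.integer(stride))]
  a <- traj$system$atoms
  q <- a$charge; epsv <- a$epsilon; sig <- a$sigma; rad <- a$radius
  rres <- sort(unique(a$resid[ri]))
  acc <- stats::setNames(numeric(length(rres)), rres)
  un <- c(ri, li)
  pref <- -0.5 * (1 / eps_in - 1 / eps_out) * K_COULOMB
  for (fk in window) {
    x <- frame_coords(traj, fk)
    # per-atom SASA deltas (complex vs isolated parts)
    s_cpx <- sasa(x[un, , drop = FALSE], rad[un], probe_radius, n_points)$per_atom
    s_rec <- sasa(x[ri, , drop = FALSE], rad[ri], probe_radius, n_points)$per_atom
    s_lig <- sasa(x[li, , drop = FALSE], rad[li], probe_radius, n_points)$per_atom
    dsasa_rec <- s_cpx[seq_along(ri)] - s_rec
    dsasa_lig_total <- sum(s_cpx[length(ri) + seq_along(li)] - s_lig)
    # apportion the ligand's burial by each residue's share of the
    # receptor-side SASA change (equal split when that change is zero)
    dres <- vapply(rres, function(rv)
      sum(dsasa_rec[match(ri[a$resid[ri] == rv], ri)]), numeric(1))
    wts <- if (sum(abs(dres)) > 1e-12) abs(dres) / sum(abs(dres))
           else rep(1 / length(rres), length(rres))
    for (rr in seq_along(rres)) {
      rsel <- ri[a$resid[ri] == rres[rr]]
      e_ele <- coulomb_energy(x, rsel, li, q)
      e_vdw <- lj_energy(x, rsel, li, epsv, sig)
      e_np <- gamma * (dres[rr] + wts[rr] * dsasa_lig_total)
      e_p <- 0
      if (!identical(polar_model, "zero") && !is.function(polar_model)) {
        # the complex-minus-parts polar delta is exactly the screened
        # receptor-ligand cross terms; self and within-group terms cancel
        B <- rad + probe_radius
        rmat <- pair_distances(x[rsel, , drop = FALSE], x[li, , drop = FALSE])
        f <- sqrt(rmat^2 + outer(B[rsel], B[li]))
        # the Born double sum counts each unordered pair twice
        e_p <- 2 * sum(pref * outer(q[rsel], q[li]) / f)
      }
      acc[rr] <- acc[rr] + e_ele + e_vdw + e_np + e_p
    }
  }
  res <- residues(traj$system)
  out <- data.frame(resid = rres,
                    resname = res$resname[match(rres, res$resid)],
                    energy = as.numeric(acc) / length(window))
  class(out) <- c("residue_energy_profile", "data.frame")
  out
}

#' Check the printed-ledger identities of an energy table
#'
#' Verifies, for each system column of a printed MM-PBSA component table,
#' the footnote identities gas = ele + vdw (+ int), solv = npsolv +
#' psolv, binding = gas + solv, to a stated rounding tolerance. Rows that
#' fail are flagged, not corrected.
#'
#' @param tab data.frame with columns \code{component} (ele, vdw, gas,
#'   npsolv, psolv, solv, binding) and one numeric column per system.
#' @param tol rounding tolerance (default 0.05 kcal/mol, half a printed
#'   decimal).
#' @return data.frame with one row per (system, identity): columns
#'   \code{system}, \code{identity}, \code{lhs}, \code{rhs},
#'   \code{consistent}.
#' @export
check_energy_ledger <- function(tab, tol = 0.05) {
  stopifnot("component" %in% names(tab))
  comp <- tab$component
  systems <- setdiff(names(tab), "component")
  get <- function(sys, what) {
    v <- tab[[sys]][match(what, comp)]
    if (anyNA(v)) stop("ledger table missing component: ", what)
    v
  }
  out <- list()
  for (sys in systems) {
    rows <- data.frame(
      system = sys,
      identity = c("gas = ele + vdw", "solv = npsolv + psolv",
                   "binding = gas + solv"),
      lhs = c(get(sys, "gas"), get(sys, "solv"), get(sys, "binding")),
      rhs = c(get(sys, "ele") + get(sys, "vdw"),
              get(sys, "npsolv") + get(sys, "psolv"),
              get(sys, "gas") + get(sys, "solv")))
    rows$consistent <- abs(rows$lhs - rows$rhs) <= tol + 1e-12
    out[[sys]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Printed MM-PBSA component tables shipped with the package
#'
#' Loads the packaged plain-text copy of the published receptor-nanotube
#' and odor-receptor binding-energy component tables (kcal/mol), used for
#' ledger-identity checks.
#'
#' @return data.frame with a \code{component} column and one column per
#'   system.
#' @export
printed_energy_tables <- function() {
  path <- system.file("extdata", "mmpbsa_printed_tables.tsv", package = "cntmd")
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
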