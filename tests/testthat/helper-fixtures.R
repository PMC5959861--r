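# shared fixture builders (all programmatic; no stored data)

# one-residue peptide with a side chain
peptide_system <- function() {
  mol_system(data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    resid = 1L, resname = "ALA", group = "receptor",
    stringsAsFactors = FALSE))
}

# water molecule (O, H, H)
water_system <- function() {
  mol_system(data.frame(
    name = c("O", "H1", "H2"), element = c("O", "H", "H"),
    resid = 1L, resname = "HOH", group = "solvent",
    stringsAsFactors = FALSE))
}

# mixed receptor + tube system of carbons with radii
mixed_system <- function(n_rec = 4, n_tube = 3) {
  mol_system(data.frame(
    name = "C", element = "C",
    resid = c(rep(1L, n_rec), rep(2L, n_tube)),
    resname = c(rep("ALA", n_rec), rep("CNT", n_tube)),
    group = c(rep("receptor", n_rec), rep("tube", n_tube)),
    radius = 1.7, stringsAsFactors = FALSE))
}

# a structure_network built directly from an edge data.frame
make_network <- function(nodes, edges) {
  structure(list(nodes = as.integer(nodes), edges = edges,
                 parameters = list(Imin = 3, occupancy_min = 0.5,
                                   n_frames = 1L)),
            class = "structure_network")
}

# rotation matrix about z by angle (radians)
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# arbitrary proper rotation from three angles
rot_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- rot_z(az)
  rz %*% ry %*% rx
}

# brute-force all-pairs adsorbed count (independent of the cell list)
brute_adsorbed <- function(coords, rec_idx, tube_idx, cutoff) {
  cnt <- 0L
  for (i in rec_idx) {
    dmin <- Inf
    for (j in tube_idx)
      dmin <- min(dmin, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    if (dmin <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# brute-force Mann-Whitney AUC by pair counting (ties = 1/2)
brute_auc <- function(score, positive, more_negative_first = TRUE) {
  s <- if (more_negative_first) -score else score
  pos <- s[positive]; neg <- s[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
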