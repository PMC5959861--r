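test_that("fluctuation_matrix removes rigid motion and centres displacements", {
  sys <- mol_system(data.frame(
    name = "CA", element = "C", resid = 1:5, resname = "ALA",
    group = "receptor", stringsAsFactors = FALSE))
  set.seed(20)
  base <- matrix(rnorm(15, sd = 4), 5, 3)

  # static trajectory (duplicated frames) -> all displacements zero
  co <- array(rep(base, 3), dim = c(5, 3, 3))
  fl <- fluctuation_matrix(trajectory(sys, co), 1:5)
  expect_lt(max(abs(fl$disp)), 1e-10)

  # rigid-rotation-only trajectory -> displacements vanish after alignment
  co2 <- array(NA_real_, dim = c(5, 3, 4))
  for (k in 1:4) co2[, , k] <- sweep(base %*% t(rot_xyz(0.1 * k, -0.05 * k, 0.2 * k)),
                                     2, c(k, 0, -k), "+")
  fl2 <- fluctuation_matrix(trajectory(sys, co2), 1:5)
  expect_lt(max(abs(fl2$disp)), 1e-6)

  # mirrored pair about the mean: opposite displacements
  d <- matrix(rnorm(15, sd = 0.1), 5, 3)
  co3 <- array(c(base + d, base - d), dim = c(5, 3, 2))
  fl3 <- fluctuation_matrix(trajectory(sys, co3), 1:5)
  expect_equal(fl3$disp[, , 1], -fl3$disp[, , 2], tolerance = 1e-8)

  expect_error(fluctuation_matrix(trajectory(sys, co[, , 1, drop = FALSE]), 1:5),
               "at least 2 frames")
})

test_that("dccm honours exact correlation limits and matrix invariants", {
  # residues 5-7 are static anchors used for the fit, so the engineered
  # displacement pattern of residues 1-4 reaches the correlation step
  # unchanged (the anchor fit is the identity)
  sys <- mol_system(data.frame(
    name = "CA", element = "C", resid = 1:7, resname = "ALA",
    group = "receptor", stringsAsFactors = FALSE))
  base <- cbind(c(0, 10, 10, 0, 30, 30, 25),
                c(0, 0, 10, 10, 0, 30, 15),
                c(0, 5, 10, 15, 20, 0, 30))
  nf <- 40
  set.seed(21)
  amp <- rnorm(nf, sd = 0.2)
  ind <- rnorm(nf, sd = 0.2)
  co <- array(NA_real_, dim = c(7, 3, nf))
  for (k in seq_len(nf)) {
    fr <- base
    fr[1, 1] <- fr[1, 1] + amp[k]      # residues 1,2: identical x series
    fr[2, 1] <- fr[2, 1] + amp[k]
    fr[3, 1] <- fr[3, 1] - amp[k]      # residue 3: exactly opposite, same axis
    fr[4, 2] <- fr[4, 2] + ind[k]      # residue 4: orthogonal axis, independent
    co[, , k] <- fr
  }
  tr <- trajectory(sys, co)
  M <- dccm(tr, select_atoms(sys, "resid:1-4"), align_sel = 5:7)
  expect_true(isSymmetric(unclass(M)))
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_true(all(M >= -1 & M <= 1))
  expect_equal(unname(M[1, 2]), 1, tolerance = 1e-10)   # identical series
  expect_equal(unname(M[1, 3]), -1, tolerance = 1e-10)  # opposite series
  expect_equal(unname(M[1, 4]), 0, tolerance = 1e-10)   # orthogonal axes

  # zero-variance residues flagged, or dropped on request: everything
  # static (the fit is then the identity) except residue 4
  co_static <- array(rep(base, nf), dim = c(7, 3, nf))
  set.seed(26)
  co_static[4, 3, ] <- base[4, 3] + rnorm(nf, sd = 0.2)
  trs <- trajectory(sys, co_static)
  expect_error(dccm(trs, select_atoms(sys, "name:CA"), align_sel = 1:3,
                    zero_variance = "error"), "zero-variance")
  Md <- dccm(trs, select_atoms(sys, "name:CA"), align_sel = 1:3,
             zero_variance = "drop")
  expect_equal(nrow(Md), 1)
})

test_that("dccm recovers a generator's correlation matrix (reduced-size draw)", {
  g <- gen_correlated_trajectory(
    8, list(kind = "blocks", blocks = list(c(1, 4), c(5, 8)), rho = 0.7),
    amplitude = 0.25, n_frames = 1500, seed = 5)
  M <- dccm(g$trajectory, select_atoms(g$trajectory$system, "name:CA"))
  expect_lt(max(abs(unclass(M) - g$truth$dccm_true)), 0.08)
  expect_true(isSymmetric(unclass(M)))
})

test_that("interaction strengths follow the normalized pair-count formula and match brute force", {
  # two residues with side chains engineered to give n_ij = 4 pairs
  sys <- mol_system(data.frame(
    name = c("CA", "CB", "CG", "CA", "CB", "CG"),
    element = "C", resid = c(1L, 1L, 1L, 3L, 3L, 3L),
    resname = c(rep("LYS", 3), rep("TRP", 3)),
    group = "receptor", stringsAsFactors = FALSE))
  co <- rbind(c(-9, 0, 0), c(0, 0, 0), c(0, 2, 0),
              c(9, 0, 0), c(3, 0, 0), c(3, 2, 0))
  # side-chain pairs across: (CB,CB)=3, (CB,CG)=3.6, (CG,CB)=3.6, (CG,CG)=3
  # all <= 4.5; CA excluded as backbone -> n_ij = 4
  nt <- psn_normalization()
  nt["LYS"] <- 64; nt["TRP"] <- 100
  I <- interaction_strength_frame(co, sys, distance_cutoff = 4.5,
                                  norm_table = nt)
  expect_equal(I["1", "3"], 4 / sqrt(64 * 100) * 100)  # = 5.0
  expect_equal(I["1", "3"], 5.0)
  expect_true(isSymmetric(I))

  # scale check: n_ij = sqrt(N_i N_j) gives exactly 100
  sys2 <- mol_system(data.frame(
    name = c(paste0("C", 1:8), paste0("D", 1:10)),
    element = "C", resid = c(rep(1L, 8), rep(3L, 10)),
    resname = c(rep("AAA", 8), rep("BBB", 10)),
    group = "receptor", stringsAsFactors = FALSE))
  co2 <- rbind(matrix(rnorm(24, sd = 0.5), 8, 3),
               sweep(matrix(rnorm(30, sd = 0.5), 10, 3), 2, c(1.5, 0, 0), "+"))
  nt2 <- psn_normalization()   # AAA/BBB unknown -> default 100
  I2 <- interaction_strength_frame(co2, sys2, distance_cutoff = 50,
                                   norm_table = nt2)
  # all 80 cross pairs within cutoff; sqrt(100*100) = 100
  expect_equal(I2["1", "3"], 80 / sqrt(100 * 100) * 100)

  # random 3-residue toy vs all-pairs brute force on n_ij
  set.seed(22)
  nm <- c("CB", "CG", "CD")
  sys3 <- mol_system(data.frame(
    name = rep(nm, 3), element = "C",
    resid = rep(c(1L, 3L, 5L), each = 3),
    resname = rep(c("ALA", "SER", "VAL"), each = 3),
    group = "receptor", stringsAsFactors = FALSE))
  for (rep_i in 1:5) {
    co3 <- matrix(runif(27, 0, 8), 9, 3)
    I3 <- interaction_strength_frame(co3, sys3, distance_cutoff = 4.5,
                                     norm_table = psn_normalization())
    for (pair in list(c(1, 3), c(1, 5), c(3, 5))) {
      ii <- which(sys3$atoms$resid == pair[1])
      jj <- which(sys3$atoms$resid == pair[2])
      nij <- 0
      for (p in ii) for (q in jj)
        if (sqrt(sum((co3[p, ] - co3[q, ])^2)) <= 4.5) nij <- nij + 1
      Np <- norm_for(unique(sys3$atoms$resname[ii]), psn_normalization())
      Nq <- norm_for(unique(sys3$atoms$resname[jj]), psn_normalization())
      expect_equal(I3[as.character(pair[1]), as.character(pair[2])],
                   nij / sqrt(Np * Nq) * 100)
    }
  }

  # glycine participates through its CA pseudo-side-chain
  sysg <- mol_system(data.frame(
    name = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O"),
    element = c("N", "C", "C", "O", "C", "N", "C", "C", "O"),
    resid = c(rep(1L, 5), rep(3L, 4)),
    resname = c(rep("ALA", 5), rep("GLY", 4)),
    group = "receptor", stringsAsFactors = FALSE))
  cog <- rbind(c(0, 3, 0), c(0, 1, 0), c(0, -1, 0), c(0, -3, 0), c(0, 0, 0),
               c(3, 3, 0), c(3, 0, 0), c(3, -1, 0), c(3, -3, 0))
  Ig <- interaction_strength_frame(cog, sysg, norm_table = psn_normalization())
  expect_gt(Ig["1", "3"], 0)   # ALA CB to GLY CA at 3 A
})

test_that("network construction applies Imin and occupancy thresholds monotonically", {
  rid <- c(1L, 3L, 5L)
  mk <- function(v13, v15, v35) {
    M <- matrix(0, 3, 3, dimnames = list(rid, rid))
    M[1, 2] <- M[2, 1] <- v13
    M[1, 3] <- M[3, 1] <- v15
    M[2, 3] <- M[3, 2] <- v35
    M
  }
  # edge (1,3) present in 6 of 10 frames; (1,5) in all; (3,5) never
  mats <- c(replicate(6, mk(4, 5, 0), simplify = FALSE),
            replicate(4, mk(1, 5, 0), simplify = FALSE))
  net5 <- build_network(mats, Imin = 3, occupancy_min = 0.5)
  expect_equal(nrow(net5$edges), 2)
  expect_true(any(net5$edges$i == 1 & net5$edges$j == 3))
  e13 <- net5$edges[net5$edges$i == 1 & net5$edges$j == 3, ]
  expect_equal(e13$occupancy, 0.6)
  expect_equal(e13$mean_strength, 4)  # averaged over frames where present

  net7 <- build_network(mats, Imin = 3, occupancy_min = 0.7)
  expect_false(any(net7$edges$i == 1 & net7$edges$j == 3))

  # raising Imin never adds edges
  for (im in c(1, 3, 4.5, 6)) {
    lo <- build_network(mats, Imin = im, occupancy_min = 0.5)
    hi <- build_network(mats, Imin = im + 1, occupancy_min = 0.5)
    expect_lte(nrow(hi$edges), nrow(lo$edges))
  }
  expect_error(build_network(list()), "empty")
})

test_that("shortest paths equal a BFS oracle on correlation-filtered random graphs", {
  skip_if_not_installed("igraph")
  set.seed(23)
  n_graphs <- 40
  for (gi in seq_len(n_graphs)) {
    n <- sample(4:20, 1)
    nodes <- seq_len(n)
    # random edges
    all_pairs <- t(combn(n, 2))
    m <- sample.int(nrow(all_pairs), size = min(nrow(all_pairs),
                                                rbinom(1, nrow(all_pairs), 0.3)))
    if (length(m) == 0) m <- 1L
    ed <- data.frame(i = all_pairs[m, 1], j = all_pairs[m, 2],
                     mean_strength = runif(length(m), 1, 10),
                     occupancy = 1)
    net <- make_network(nodes, ed)
    # random correlation matrix (symmetric, unit diagonal)
    C <- matrix(runif(n * n, -1, 1), n, n)
    C <- (C + t(C)) / 2; diag(C) <- 1
    dimnames(C) <- list(nodes, nodes)
    corr_min <- 0.3
    src <- sample(nodes, 2); snk <- sample(nodes, 2)
    got <- shortest_paths(net, C, src, snk, corr_min = corr_min)

    # oracle: BFS on the |C| >= corr_min subgraph via igraph
    keep <- abs(C[cbind(ed$i, ed$j)]) >= corr_min
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$i[keep], to = ed$j[keep]),
      directed = FALSE, vertices = data.frame(name = nodes))
    D <- igraph::distances(g)
    for (p in got) {
      oracle_d <- D[as.character(p$source), as.character(p$sink)]
      if (is.null(p$nodes)) {
        expect_true(is.infinite(oracle_d))
      } else {
        expect_equal(p$length, unname(oracle_d))
        # the returned node sequence is a real path in the subgraph
        if (p$length > 0) {
          for (e in seq_len(length(p$nodes) - 1)) {
            a <- p$nodes[e]; b <- p$nodes[e + 1]
            hit <- (ed$i == min(a, b) & ed$j == max(a, b))
            expect_true(any(hit & keep))
          }
        }
      }
    }
  }
})

test_that("shortest paths handle trivial, tied and self cases deterministically", {
  ed <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                   mean_strength = c(5, 5, 2, 9), occupancy = 1)
  net <- make_network(1:4, ed)
  C <- matrix(1, 4, 4, dimnames = list(1:4, 1:4))

  # single qualifying edge
  p <- shortest_paths(net, C, 1, 2)[[1]]
  expect_equal(p$nodes, c(1, 2)); expect_equal(p$length, 1L)

  # two 2-hop routes 1-2-4 (5+2) and 1-3-4 (5+9): larger total strength wins
  p2 <- shortest_paths(net, C, 1, 4)[[1]]
  expect_equal(p2$nodes, c(1, 3, 4))

  # equal strengths: lexicographic node order breaks the tie
  ed_tie <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                       mean_strength = c(5, 5, 5, 5), occupancy = 1)
  p3 <- shortest_paths(make_network(1:4, ed_tie), C, 1, 4)[[1]]
  expect_equal(p3$nodes, c(1, 2, 4))

  # source equals sink: zero-length path, not an error
  p4 <- shortest_paths(net, C, 2, 2)[[1]]
  expect_equal(p4$length, 0L)

  # disconnected
  net_d <- make_network(1:5, ed)
  p5 <- shortest_paths(net_d, C_ext <- {
    Ce <- matrix(1, 5, 5, dimnames = list(1:5, 1:5)); Ce
  }, 1, 5)[[1]]
  expect_null(p5$nodes)
  expect_true(is.na(p5$length))

  # source not in network errors
  expect_error(shortest_paths(net, C, 9, 1), "not a network node")
})

test_that("path frequency counts per-frame edge conjunctions and is subpath-monotone", {
  rid <- c(1L, 3L, 5L, 7L)
  mk <- function(e13, e35, e57) {
    M <- matrix(0, 4, 4, dimnames = list(rid, rid))
    M[1, 2] <- M[2, 1] <- e13
    M[2, 3] <- M[3, 2] <- e35
    M[3, 4] <- M[4, 3] <- e57
    M
  }
  # edge (1,3) in 81/100 frames, others always present
  mats <- c(replicate(81, mk(5, 5, 5), simplify = FALSE),
            replicate(19, mk(0, 5, 5), simplify = FALSE))
  expect_equal(path_frequency(mats, c(1, 3, 5, 7), Imin = 3), 81)
  expect_equal(path_frequency(mats, c(3, 5, 7), Imin = 3), 100)

  # random fixture: full path vs brute-force conjunction; subpath monotone
  set.seed(24)
  rand_mats <- replicate(50, mk(runif(1, 0, 6), runif(1, 0, 6), runif(1, 0, 6)),
                         simplify = FALSE)
  brute <- mean(vapply(rand_mats, function(M)
    M["1", "3"] >= 3 && M["3", "5"] >= 3 && M["5", "7"] >= 3, logical(1))) * 100
  expect_equal(path_frequency(rand_mats, c(1, 3, 5, 7), Imin = 3), brute)
  expect_gte(path_frequency(rand_mats, c(1, 3, 5), Imin = 3),
             path_frequency(rand_mats, c(1, 3, 5, 7), Imin = 3))

  expect_error(path_frequency(mats, c(1)), "at least one edge")
})

test_that("node frequency summaries rank by weighted counts with index ties", {
  mkp <- function(s, t, freq) list(source = s, sink = t, nodes = c(s, t),
                                   length = 1L, frequency = freq)
  pws <- structure(list(mkp(10, 50, 100), mkp(10, 60, 100), mkp(10, 50, 100),
                        mkp(20, 60, 100)), class = "pathway_list")
  s <- node_frequency_summary(pws, k = 2)
  expect_equal(s$top_sources$resid[1], 10)
  expect_equal(s$top_sources$count[1], 3)
  # sink tie between 50 and 60 at count 2: lower residue index first
  expect_equal(s$top_sinks$resid, c(50, 60))

  # weighting by frequency
  pww <- structure(list(mkp(1, 2, 10), mkp(3, 2, 100)), class = "pathway_list")
  sw <- node_frequency_summary(pww, k = 2)
  expect_equal(sw$top_sources$resid[1], 3)

  # planted-skew fixture vs direct counting oracle
  set.seed(25)
  srcs <- sample(c(rep(7L, 20), sample(1:5, 22, replace = TRUE)))
  pl <- structure(lapply(seq_along(srcs), function(k)
    mkp(srcs[k], 99L, 100)), class = "pathway_list")
  so <- node_frequency_summary(pl, k = 3)
  expect_equal(so$top_sources$resid[1], 7L)
  expect_equal(so$top_sources$count[1], 20)
})
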