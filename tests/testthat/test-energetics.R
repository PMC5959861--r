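test_that("coulomb energy follows k*q1*q2/(eps*r) and matches brute force", {
  sys <- mixed_system(1, 1)
  co <- rbind(c(0, 0, 0), c(3.320637, 0, 0))
  a <- select_atoms(sys, 1L); b <- select_atoms(sys, 2L)

  # opposite unit charges at r = k/100 -> -100 kcal/mol
  expect_equal(coulomb_energy(co, a, b, charges = c(1, -1)), -100,
               tolerance = 1e-10)
  # zero charges -> 0
  expect_equal(coulomb_energy(co, a, b, charges = c(0, 0)), 0)
  # dielectric scales inversely
  expect_equal(coulomb_energy(co, a, b, charges = c(1, -1), dielectric = 80),
               -100 / 80, tolerance = 1e-10)
  # coincident pair -> singularity error
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), a, b,
                              charges = c(1, 1)), "coincident")

  # random 5x5 sets vs brute-force double loop
  set.seed(30)
  for (rep_i in 1:10) {
    n1 <- 5; n2 <- 5
    x <- rbind(matrix(runif(n1 * 3, 0, 6), n1, 3),
               sweep(matrix(runif(n2 * 3, 0, 6), n2, 3), 2, c(10, 0, 0), "+"))
    q <- runif(n1 + n2, -1, 1)
    brute <- 0
    for (i in 1:n1) for (j in (n1 + 1):(n1 + n2))
      brute <- brute + 332.0637 * q[i] * q[j] / sqrt(sum((x[i, ] - x[j, ])^2))
    got <- coulomb_energy(x, 1:n1, (n1 + 1):(n1 + n2), q)
    expect_equal(got, brute, tolerance = 1e-10)
  }
})

test_that("LJ energy has the right zero and minimum and matches brute force", {
  sys <- mixed_system(1, 1)
  a <- select_atoms(sys, 1L); b <- select_atoms(sys, 2L)
  eps <- c(0.12, 0.30); sig <- c(3.2, 3.6)
  eab <- sqrt(prod(eps)); sab <- mean(sig)

  # r = sigma_ab -> 0
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(sab, 0, 0)), a, b, eps, sig), 0,
               tolerance = 1e-12)
  # r = 2^(1/6) sigma_ab -> -eps_ab exactly
  expect_equal(lj_energy(rbind(c(0, 0, 0), c(2^(1/6) * sab, 0, 0)), a, b,
                         eps, sig), -eab, tolerance = 1e-12)

  # random 10-atom pair sets vs brute force
  set.seed(31)
  for (rep_i in 1:10) {
    x <- rbind(matrix(runif(30, 0, 5), 10, 3),
               sweep(matrix(runif(30, 0, 5), 10, 3), 2, c(8, 0, 0), "+"))
    ep <- runif(20, 0.05, 0.3); sg <- runif(20, 2.5, 4)
    brute <- 0
    for (i in 1:10) for (j in 11:20) {
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      e <- sqrt(ep[i] * ep[j]); s <- (sg[i] + sg[j]) / 2
      brute <- brute + 4 * e * ((s / r)^12 - (s / r)^6)
    }
    expect_equal(lj_energy(x, 1:10, 11:20, ep, sg), brute, tolerance = 1e-8)
  }
})

test_that("generated toy complexes reproduce their emitted brute-force references", {
  for (seed in c(2, 7, 19)) {
    g <- gen_toy_complex(8, 3, seed = seed)
    q <- g$system$atoms$charge
    expect_equal(coulomb_energy(g$coords, g$receptor_sel, g$ligand_sel, q),
                 g$truth$ele, tolerance = 1e-8)
    expect_equal(lj_energy(g$coords, g$receptor_sel, g$ligand_sel,
                           g$system$atoms$epsilon, g$system$atoms$sigma),
                 g$truth$vdw, tolerance = 1e-8)
  }
  # zero charges, far separation: interaction energies negligible
  g0 <- gen_toy_complex(5, 2, charge_range = c(0, 0), separation = 60, seed = 1)
  expect_equal(coulomb_energy(g0$coords, g0$receptor_sel, g0$ligand_sel,
                              g0$system$atoms$charge), 0)
  expect_lt(abs(lj_energy(g0$coords, g0$receptor_sel, g0$ligand_sel,
                          g0$system$atoms$epsilon, g0$system$atoms$sigma)),
            1e-6)
})

test_that("nonpolar solvation is gamma * SASA with validation", {
  expect_equal(nonpolar_solvation(0), 0)
  expect_equal(nonpolar_solvation(1000), 7.2)
  expect_equal(nonpolar_solvation(500, gamma = 0.005), 2.5)
  expect_error(nonpolar_solvation(-1), "negative")
})

test_that("polar solvation models honour their contracts", {
  co <- matrix(0, 1, 3)
  # all charges zero -> 0 for every model
  expect_equal(polar_solvation(co, charges = 0, radii = 1.5), 0)
  expect_equal(polar_solvation(co, charges = 0, radii = 1.5, model = "zero"), 0)
  # zero model ignores charges
  expect_equal(polar_solvation(co, charges = 3, radii = 1.5, model = "zero"), 0)
  # Born ion: -1/2 (1 - 1/80) k q^2 / (R + probe)
  got <- polar_solvation(co, charges = 1, radii = 0.26032)
  expect_equal(got, -0.5 * (1 - 1/80) * 332.0637 / 1.66032, tolerance = 1e-9)
  # user-supplied model function is used as-is
  expect_equal(polar_solvation(co, charges = 1, radii = 1,
                               model = function(x, q, r) 42), 42)
  # determinism
  set.seed(32)
  xs <- matrix(rnorm(9), 3, 3)
  q <- c(0.3, -0.2, 0.5)
  expect_identical(polar_solvation(xs, q, rep(1.5, 3)),
                   polar_solvation(xs, q, rep(1.5, 3)))
})

test_that("binding energy obeys the ledger identities and vanishes for inert dimers", {
  # noninteracting far-separated toy with zero charges
  g0 <- gen_toy_complex(4, 2, charge_range = c(0, 0), separation = 80, seed = 3)
  tr <- trajectory(g0$system, array(g0$coords, dim = c(6, 3, 2)),
                   times = c(0, 1))
  be0 <- binding_energy(tr, g0$receptor_sel, g0$ligand_sel, n_points = 240)
  expect_equal(be0$ele, 0)
  expect_lt(abs(be0$vdw), 1e-6)
  expect_lt(abs(be0$npsolv), 1e-6)  # no mutual burial at 80 A
  expect_equal(be0$psolv, 0)
  expect_lt(abs(be0$binding), 1e-5)

  # charged interacting toy: identities hold to rounding tolerance
  g <- gen_toy_complex(6, 3, separation = 7, seed = 8)
  nfr <- 4
  set.seed(33)
  co <- array(NA_real_, dim = c(9, 3, nfr))
  for (k in 1:nfr) co[, , k] <- g$coords + matrix(rnorm(27, sd = 0.05), 9, 3)
  trj <- trajectory(g$system, co)
  be <- binding_energy(trj, g$receptor_sel, g$ligand_sel, n_points = 240)
  expect_equal(be$gas, be$ele + be$vdw + be$int, tolerance = 1e-10)
  expect_equal(be$solv, be$npsolv + be$psolv, tolerance = 1e-10)
  expect_equal(be$binding, be$gas + be$solv, tolerance = 1e-10)
  expect_equal(be$int, 0)  # single-trajectory mode
  expect_equal(be$n_frames, nfr)
  expect_true(all(c("ele", "vdw", "gas", "npsolv", "psolv", "solv", "binding")
                  %in% names(be$se)))

  # energies invariant under a rigid transform of the complex
  R <- rot_xyz(0.5, -0.8, 0.3)
  co2 <- co
  for (k in 1:nfr) co2[, , k] <- sweep(co[, , k] %*% t(R), 2, c(10, 5, -3), "+")
  be2 <- binding_energy(trajectory(g$system, co2), g$receptor_sel,
                        g$ligand_sel, n_points = 240)
  expect_equal(be2$ele, be$ele, tolerance = 1e-8)
  expect_equal(be2$vdw, be$vdw, tolerance = 1e-8)
  expect_equal(be2$psolv, be$psolv, tolerance = 1e-8)

  # window validation
  expect_error(binding_energy(trj, g$receptor_sel, g$ligand_sel, window = 1:99),
               "window")
})

test_that("per-residue decomposition sums exactly to the binding totals", {
  atoms <- data.frame(
    name = paste0("X", 1:12), element = "C",
    resid = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6),
    resname = c(rep("REC", 10), rep("LIG", 2)),
    group = c(rep("receptor", 10), rep("ligand", 2)),
    radius = 1.7,
    charge = c(0.2, -0.1, 0.3, -0.2, 0.1, 0.15, -0.25, 0.2, 0.05, -0.3, 0.4, -0.1),
    epsilon = 0.12, sigma = 3.3, stringsAsFactors = FALSE)
  sys <- mol_system(atoms)
  set.seed(34)
  nfr <- 3
  co <- array(NA_real_, dim = c(12, 3, nfr))
  base <- rbind(matrix(runif(30, 0, 5), 10, 3),
                sweep(matrix(runif(6, 0, 2), 2, 3), 2, c(8, 2, 2), "+"))
  for (k in 1:nfr) co[, , k] <- base + matrix(rnorm(36, sd = 0.05), 12, 3)
  tr <- trajectory(sys, co)
  rs <- select_atoms(sys, "group:receptor"); ls <- select_atoms(sys, "group:ligand")

  be <- binding_energy(tr, rs, ls, n_points = 240)
  pr <- per_residue_decomposition(tr, rs, ls, n_points = 240)
  expect_equal(nrow(pr), 5)
  expect_equal(sum(pr$energy), be$binding, tolerance = 1e-6)

  # two identical residues symmetric about the ligand get equal shares:
  # exactly so without mutual burial, and to the spherical-point-set
  # resolution when the surfaces overlap
  atoms2 <- data.frame(
    name = c("A1", "A2", "L1"), element = "C",
    resid = c(1L, 2L, 3L), resname = c("REC", "REC", "LIG"),
    group = c("receptor", "receptor", "ligand"),
    radius = 1.7, charge = c(0.2, 0.2, -0.3), epsilon = 0.1, sigma = 3.2,
    stringsAsFactors = FALSE)
  sys2 <- mol_system(atoms2)
  co_far <- array(rbind(c(-8, 0, 0), c(8, 0, 0), c(0, 0, 0)), dim = c(3, 3, 1))
  pr_far <- per_residue_decomposition(trajectory(sys2, co_far),
                                      select_atoms(sys2, "group:receptor"),
                                      select_atoms(sys2, "group:ligand"),
                                      n_points = 240)
  expect_equal(pr_far$energy[1], pr_far$energy[2], tolerance = 1e-12)

  co2 <- array(rbind(c(-4, 0, 0), c(4, 0, 0), c(0, 0, 0)), dim = c(3, 3, 1))
  pr2 <- per_residue_decomposition(trajectory(sys2, co2),
                                   select_atoms(sys2, "group:receptor"),
                                   select_atoms(sys2, "group:ligand"),
                                   n_points = 960)
  expect_equal(pr2$energy[1], pr2$energy[2], tolerance = 0.02)

  # single-residue receptor: profile equals the total
  atoms3 <- atoms2; atoms3$resid <- c(1L, 1L, 3L)
  sys3 <- mol_system(atoms3)
  tr3 <- trajectory(sys3, co2)
  be3 <- binding_energy(tr3, select_atoms(sys3, "group:receptor"),
                        select_atoms(sys3, "group:ligand"), n_points = 240)
  pr3 <- per_residue_decomposition(tr3, select_atoms(sys3, "group:receptor"),
                                   select_atoms(sys3, "group:ligand"),
                                   n_points = 240)
  expect_equal(pr3$energy, be3$binding, tolerance = 1e-9)
})

test_that("printed component tables satisfy (or are flagged by) the ledger identities", {
  tab <- printed_energy_tables()
  # the receptor-nanotube table sums reproduce the printed values exactly
  chk <- check_energy_ledger(tab[, c("component", "CNT-opsin", "CNT-hOR2AG1")],
                             tol = 1e-9)
  expect_true(all(chk$consistent))
  expect_equal(chk$lhs[chk$system == "CNT-opsin" &
                         chk$identity == "gas = ele + vdw"], -176.8)
  expect_equal(chk$lhs[chk$system == "CNT-opsin" &
                         chk$identity == "solv = npsolv + psolv"], 55.1)
  expect_equal(chk$lhs[chk$system == "CNT-opsin" &
                         chk$identity == "binding = gas + solv"], -121.7)

  # odor tables: with printed-rounding tolerance (three addends at half a
  # decimal each) every row is consistent except one internally
  # inconsistent binding row, which is flagged, not fixed
  odor_cols <- c("component", "CNT-icaridin", "Free-icaridin",
                 "CNT-3-nonanone", "Free-3-nonanone",
                 "CNT-2-pentanol", "Free-2-pentanol")
  chk2 <- check_energy_ledger(tab[, odor_cols], tol = 0.15)
  bad <- chk2[!chk2$consistent, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$system, "CNT-icaridin")
  expect_equal(bad$identity, "binding = gas + solv")
  # the free-icaridin row reproduces its own sum: -29.0 + 8.9 = -20.1
  fi <- chk2[chk2$system == "Free-icaridin" &
               chk2$identity == "binding = gas + solv", ]
  expect_equal(fi$rhs, -20.1, tolerance = 1e-9)
  expect_true(fi$consistent)
})

test_that("energy_components enforces its bookkeeping identities by construction", {
  ec <- energy_components(ele = -0.0, vdw = -176.8, npsolv = -6.5, psolv = 61.6)
  expect_equal(ec$gas, -176.8)
  expect_equal(ec$solv, 55.1)
  expect_equal(ec$binding, -121.7)
})
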