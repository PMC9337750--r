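# exp-6 and Ewald lattice sums and the total-energy breakdown.

test_that("exp-6 energy reduces to the scalar pair form for isolated dimers", {
  fx <- make_diatomic_fixture(with_reference = FALSE)
  p <- fx$params
  p$tail_correction <- FALSE
  # two aligned diatomics 3 A apart along x in a huge cell
  s <- crystal_structure(unit_cell(100, 100, 100), "P1",
                         list(list(molecule = fx$molecule, frac = c(0, 0, 0)),
                              list(molecule = fx$molecule, frac = c(0.03, 0, 0))))
  phi <- function(r) 306000 * exp(-3.6 * r) - 8200 / r^6
  # atom separations: 1.8 (Y..X), 3.0 (X..X), 3.0 (Y..Y), 4.2 (X..Y)
  expect_equal(exp6_energy(s, p), phi(1.8) + 2 * phi(3) + phi(4.2),
               tolerance = 1e-9)
})

test_that("pairs beyond the cutoff contribute nothing", {
  a1 <- molecule("a1", "X", matrix(0, 1, 3))
  s <- crystal_structure(unit_cell(300, 300, 300), "P1",
                         list(list(molecule = a1, frac = c(0, 0, 0)),
                              list(molecule = a1, frac = c(1 / 3, 0, 0))))
  p <- fixture_params(cutoff = 20)
  p$tail_correction <- FALSE
  expect_equal(exp6_energy(s, p), 0)
})

test_that("close contacts trigger the overlap error", {
  a1 <- molecule("a1", "X", matrix(0, 1, 3))
  s <- crystal_structure(unit_cell(50, 50, 50), "P1",
                         list(list(molecule = a1, frac = c(0, 0, 0)),
                              list(molecule = a1, frac = c(0.004, 0, 0))))
  expect_error(exp6_energy(s, fixture_params()), "overlap")
})

test_that("Ewald reproduces the rock-salt and CsCl Madelung constants", {
  k_e <- 1389.35457644382
  d <- 2.5
  rs <- make_reference_lattice("rocksalt", d)
  M_rs <- -ewald_energy(rs) * d / k_e / 4   # 4 ion pairs per cell
  expect_equal(M_rs, 1.7476, tolerance = 5e-5)

  cs <- make_reference_lattice("cscl", d)
  M_cs <- -ewald_energy(cs) * d / k_e / 1
  expect_equal(M_cs, 1.7627, tolerance = 5e-5)

  # independent neutral-cube direct-summation oracle
  expect_equal(M_rs, oracle_madelung(rs, d), tolerance = 1e-4)
  expect_equal(M_cs, oracle_madelung(cs, d), tolerance = 1e-4)
})

test_that("Ewald is independent of the splitting parameter and needs neutrality", {
  rs <- make_reference_lattice("rocksalt", 2.8)
  vals <- vapply(c(4.4, 4.8, 5.2), function(acc) {
    p <- potential_params(elements = list(Na = list(A = 0, B = 1, C = 0),
                                          Cl = list(A = 0, B = 1, C = 0)),
                          cutoff = 14, ewald_accuracy = acc)
    ewald_energy(rs, p)
  }, 0)
  expect_lt(max(vals) - min(vals), 1e-4)

  bad <- crystal_structure(unit_cell(10, 10, 10), "P1",
                           list(list(molecule = molecule("q", "Na",
                                                         matrix(0, 1, 3),
                                                         charges = 1),
                                     frac = c(0, 0, 0))))
  expect_error(ewald_energy(bad), "charge-neutral")
})

test_that("an isolated neutral molecule's Coulomb energy vanishes in the infinite-box limit", {
  # under tinfoil boundary conditions a periodic box of one dipole carries a
  # finite-size energy -(2 pi / 3V) k_e p^2, so the isolated limit is
  # approached as 1/V rather than hit exactly at any finite box
  m <- molecule("dip", c("H", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                bonds = rbind(c(1, 2)), charges = c(0.4, -0.4))
  e_at <- function(L) {
    s <- crystal_structure(unit_cell(L, L, L), "P1",
                           list(list(molecule = m, frac = c(0.5, 0.5, 0.5))))
    ewald_energy(s)
  }
  e200 <- e_at(200)
  expect_lt(abs(e200), 1e-4)
  # matches the closed-form finite-size term
  p2 <- (0.4 * 1.2)^2
  expect_equal(e200, -2 * pi / 3 / 200^3 * 1389.35457644382 * p2,
               tolerance = 1e-3)
  # and decays as 1/V
  expect_equal(e_at(320) / e200, (200 / 320)^3, tolerance = 1e-3)
})

test_that("energies are invariant under lattice translation and supercell doubling", {
  d <- 2.3
  rs <- make_reference_lattice("rocksalt", d)
  p <- potential_params(elements = list(Na = list(A = 5e4, B = 3.2, C = 900),
                                        Cl = list(A = 9e4, B = 3.1, C = 1800)),
                        cutoff = 10)
  e6 <- exp6_energy(rs, p); ee <- ewald_energy(rs, p)

  shifted <- rs
  shifted$asym <- lapply(rs$asym, function(pl) { pl$frac <- pl$frac + c(1, 0, 0); pl })
  shifted <- crystal_structure(rs$cell, rs$sg, shifted$asym)
  expect_equal(exp6_energy(shifted, p), e6, tolerance = 1e-10)
  expect_equal(ewald_energy(shifted, p), ee, tolerance = 1e-8)

  # 2x1x1 supercell: per-cell energy doubles, so per-formula bookkeeping
  # (here per P1 cell) scales exactly with the duplication
  big_cell <- unit_cell(2 * rs$cell$a, rs$cell$b, rs$cell$c)
  dup <- c(lapply(rs$asym, function(pl) { pl$frac <- pl$frac * c(.5, 1, 1); pl }),
           lapply(rs$asym, function(pl) { pl$frac <- pl$frac * c(.5, 1, 1) + c(.5, 0, 0); pl }))
  super <- crystal_structure(big_cell, "P1", dup)
  expect_equal(exp6_energy(super, p) / 2, e6, tolerance = 1e-6)
  expect_equal(ewald_energy(super, p) / 2, ee, tolerance = 1e-6)
})

test_that("periodic cutoff sum agrees with a brute-force direct sum", {
  # oracle: expanding direct sum without switching or tail, large radius
  fx <- make_diatomic_fixture()
  s <- fx$reference
  cont <- cocryscreen:::.cell_contents(s)
  M <- cell_matrix(s$cell)
  phi <- function(r) 306000 * exp(-3.6 * r) - 8200 / r^6
  direct <- 0
  reach <- 14L
  for (na in -reach:reach) for (nb in -reach:reach) for (nc in -reach:reach) {
    shift <- na * M[1, ] + nb * M[2, ] + nc * M[3, ]
    home <- na == 0 && nb == 0 && nc == 0
    for (i in 1:2) for (j in 1:2) {
      if (home && cont$mol_id[i] == cont$mol_id[j]) next
      r <- sqrt(sum((cont$xyz[j, ] + shift - cont$xyz[i, ])^2))
      direct <- direct + 0.5 * phi(r)
    }
  }
  got <- exp6_energy(s, fx$params)
  # agreement within the truncation + tail-correction approximation
  expect_lt(abs(got - direct), 0.02 * abs(direct))
})

test_that("compressing the diatomic crystal below its minimum raises the exp-6 energy", {
  fx <- make_diatomic_fixture()
  scales <- c(0.97, 0.93, 0.89, 0.85)
  vals <- vapply(scales, function(s) {
    cell <- fx$reference$cell
    sc <- unit_cell(cell$a * s, cell$b * s, cell$c * s,
                    cell$alpha, cell$beta, cell$gamma)
    exp6_energy(crystal_structure(sc, "P1", fx$reference$asym), fx$params)
  }, 0)
  expect_true(all(diff(vals) > 0))  # monotone increase under compression
  expect_gt(vals[1], exp6_energy(fx$reference, fx$params))
})

test_that("total energy decomposes additively with a zero intramolecular term for rigid molecules", {
  fx <- make_diatomic_fixture()
  en <- total_lattice_energy(fx$reference, NULL, fx$params)
  expect_equal(en$dU_intra, 0)
  expect_equal(en$U_total, en$U_exp6 + en$U_electrostatic + en$dU_intra,
               tolerance = 1e-9)

  # flexible molecule pinned at its LAM grid minimum contributes nothing
  m <- make_chain_molecule()
  o <- make_torsion_oracle("cosine", amp = 10)
  db <- build_lam_grid(m, 1L, o, spacing = 60)
  p <- potential_params(elements = list(C = list(A = 3e5, B = 3.6, C = 2400)),
                        cutoff = 10)
  s <- crystal_structure(unit_cell(9, 9, 9), "P1",
                         list(list(molecule = m, frac = c(0, 0, 0),
                                   torsions = 0)))
  en2 <- total_lattice_energy(s, setNames(list(db), m$id), p)
  expect_equal(en2$dU_intra, 0)
  # and an off-minimum torsion adds exactly the interpolated LAM energy
  s3 <- crystal_structure(unit_cell(9, 9, 9), "P1",
                          list(list(molecule = m, frac = c(0, 0, 0),
                                    torsions = 90)))
  en3 <- total_lattice_energy(s3, setNames(list(db), m$id), p)
  expect_equal(en3$dU_intra, evaluate_lam(db, 90)$energy)

  # missing database reports the stage
  expect_error(total_lattice_energy(s3, NULL, p), "intramolecular stage")
})

test_that("P21/c asymmetric-unit evaluation equals the expanded P1 evaluation", {
  fx <- make_diatomic_fixture(with_reference = FALSE)
  s <- crystal_structure(unit_cell(6.4, 5.8, 7.9, beta = 99), "P21/c",
                         list(list(molecule = fx$molecule,
                                   frac = c(0.21, 0.33, 0.12),
                                   quat = c(0.8, 0.36, 0.3, sqrt(1 - 0.8^2 - 0.36^2 - 0.3^2)))))
  p1 <- as_p1_structure(s)
  e_sym <- total_lattice_energy(s, NULL, fx$params)
  e_p1 <- total_lattice_energy(p1, NULL, fx$params)
  expect_equal(e_sym$U_total, e_p1$U_total / 4, tolerance = 1e-6)
  expect_equal(e_sym$U_exp6, e_p1$U_exp6 / 4, tolerance = 1e-6)
})
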