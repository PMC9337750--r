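# Packing similarity, duplicate clustering and global-minimum extraction.

fx <- make_diatomic_fixture()
cfg5 <- cluster_config(n = 5, rmsd_threshold = 0.5)

test_that("a structure matches itself and its lattice-translated copy at RMSD ~0", {
  # exact zero is not guaranteed: degenerate coordination shells admit
  # several equivalent pairings; any of them superposes to well under 1e-3 A
  s <- fx$reference
  expect_lt(as.numeric(packing_rmsd(s, s, cfg5)), 1e-3)

  shifted <- crystal_structure(s$cell, "P1",
    lapply(s$asym, function(p) { p$frac <- (p$frac + c(1, 1, 0)) %% 1; p }))
  expect_lt(as.numeric(packing_rmsd(s, shifted, cfg5)), 1e-3)
})

test_that("packing RMSD of a strained copy matches a direct Kabsch oracle", {
  s <- fx$reference
  strained <- crystal_structure(
    unit_cell(s$cell$a * 1.04, s$cell$b * 0.96, s$cell$c,
              s$cell$alpha, s$cell$beta, s$cell$gamma), "P1", s$asym)
  r <- packing_rmsd(s, strained, cfg5)
  got <- as.numeric(r)
  expect_gt(got, 0.01)
  # oracle: brute-force Kabsch superposition of the matched clusters,
  # implemented independently of the package's fitting code
  m <- attr(r, "matched")
  expect_equal(got, oracle_kabsch_rmsd(m$A, m$B), tolerance = 1e-9)
  # and it never beats the natural image-to-image correspondence by failing
  # to cover the cluster: the value stays below the match threshold scale
  expect_lt(got, cfg5$rmsd_threshold)
})

test_that("packing RMSD is symmetric and rejects mixed compositions", {
  s <- fx$reference
  strained <- crystal_structure(
    unit_cell(s$cell$a * 1.02, s$cell$b * 0.99, s$cell$c,
              s$cell$alpha, s$cell$beta, s$cell$gamma), "P1", s$asym)
  r12 <- as.numeric(packing_rmsd(s, strained, cfg5))
  r21 <- as.numeric(packing_rmsd(strained, s, cfg5))
  expect_equal(r12, r21, tolerance = 1e-9)

  other <- molecule("other", c("X", "X"), rbind(c(-0.5, 0, 0), c(0.5, 0, 0)),
                    bonds = rbind(c(1, 2)))
  s2 <- crystal_structure(s$cell, "P1",
                          list(list(molecule = other, frac = c(0, 0, 0))))
  expect_error(packing_rmsd(s, s2, cfg5), "same composition")
})

test_that("clustering keeps one copy of duplicates and is idempotent", {
  mk <- function(st, val) structure(list(structure = st, value = val,
                                         energy = list(U_exp6 = val,
                                                       U_electrostatic = 0,
                                                       dU_intra = 0,
                                                       U_total = val),
                                         density = crystal_density(st)),
                                    class = "ccs_minimum")
  s <- fx$reference
  pert <- crystal_structure(
    unit_cell(s$cell$a * 1.001, s$cell$b, s$cell$c,
              s$cell$alpha, s$cell$beta, s$cell$gamma), "P1", s$asym)
  distinct <- crystal_structure(unit_cell(4.4, 4.6, 5.2, 90, 104, 90), "P1",
                                lapply(s$asym, function(p) {
                                  p$quat <- c(sqrt(0.5), sqrt(0.5), 0, 0); p
                                }))
  trio <- list(mk(s, -124.0), mk(pert, -123.9), mk(distinct, -100))
  land <- cluster_landscape(trio, cfg5)
  expect_length(land$entries, 2)
  # oracle: the pairwise RMSD table says exactly one pair is a duplicate
  rmsds <- c(packing_rmsd(s, pert, cfg5), packing_rmsd(s, distinct, cfg5),
             packing_rmsd(pert, distinct, cfg5))
  expect_identical(sum(!is.na(rmsds) & rmsds <= cfg5$rmsd_threshold &
                       c(0.1, 24, 23.9) <= cfg5$energy_tol), 1L)

  # identical structures collapse to one keeper
  land2 <- cluster_landscape(list(mk(s, -124), mk(s, -124)), cfg5)
  expect_length(land2$entries, 1)

  # idempotence and non-increasing cluster count
  reclustered <- cluster_landscape(land$entries, cfg5)
  expect_length(reclustered$entries, length(land$entries))
  expect_equal(vapply(reclustered$entries, `[[`, 0, "value"),
               vapply(land$entries, `[[`, 0, "value"))

  # energies are sorted ascending
  E <- vapply(land$entries, `[[`, 0, "value")
  expect_true(all(diff(E) >= 0))

  # empty input gives an empty landscape
  expect_length(cluster_landscape(list(), cfg5)$entries, 0)
})

test_that("global minimum extraction honours the energy-source policy", {
  mk <- function(val) structure(list(structure = fx$reference, value = val,
                                     energy = list(U_total = val)),
                                class = "ccs_minimum")
  land <- structure(list(composition = "x",
                         entries = list(mk(-100), mk(-95))),
                    class = "ccs_landscape")
  expect_equal(global_minimum(land)$U_total, -100)

  exp_ref <- list(structure = fx$reference, U_total = -102)
  got <- global_minimum(land, experimental = exp_ref, policy = "experimental")
  expect_equal(got$U_total, -102)
  expect_identical(got$source, "experimental")
  # CSP best wins when it is lower
  exp_hi <- list(structure = fx$reference, U_total = -99)
  expect_equal(global_minimum(land, exp_hi, policy = "experimental")$U_total, -100)

  single <- structure(list(composition = "x", entries = list(mk(-7))),
                      class = "ccs_landscape")
  expect_equal(global_minimum(single)$U_total, -7)
  empty <- structure(list(composition = "x", entries = list()),
                     class = "ccs_landscape")
  expect_error(global_minimum(empty), "widen the search")
})

test_that("landscapes export a tidy table and a JSON + CIF bundle", {
  cfg <- search_config(list(list(molecule = fx$molecule, count = 1)),
                       spacegroups = "P1", n_candidates = 15, seed = 3)
  land <- cluster_landscape(global_search(cfg, list(), fx$params), cfg5)
  df <- as.data.frame(land)
  expect_true(all(c("rank", "U_total", "density", "spacegroup") %in% names(df)))
  expect_true(all(diff(df$U_total) >= 0))

  dir <- file.path(withr::local_tempdir(), "land")
  save_landscape(land, dir)
  expect_true(file.exists(file.path(dir, "landscape.json")))
  expect_true(file.exists(file.path(dir, "structure_001.cif")))
  idx <- jsonlite::read_json(file.path(dir, "landscape.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(idx$entries), nrow(df))
  # CIFs are readable back
  s <- read_cif(file.path(dir, "structure_001.cif"))
  expect_s3_class(s, "ccs_structure")
})
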