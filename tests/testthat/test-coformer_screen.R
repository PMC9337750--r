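# The screening metric: fusion correction, ddU, ranking, classification,
# statistics and the end-to-end screen.

test_that("the pyridine fusion correction reproduces the printed shift", {
  f <- fusion_data(T_fus = 231.5, dH_fus = 8.3, T = 300)
  res <- fusion_correction(f, m = 1)
  expect_equal(round(res$shift, 1), 2.5)
  expect_equal(res$dG_fus, 8.3 * (1 - 300 / 231.5), tolerance = 1e-12)
  expect_gt(res$shift, 0)

  # melting-point identity
  at_melt <- fusion_correction(fusion_data(231.5, 8.3, T = 231.5))
  expect_equal(at_melt$shift, 0)
  expect_equal(at_melt$dG_fus, 0)

  # linear in stoichiometry
  m2 <- fusion_correction(f, m = 2)
  expect_equal(m2$shift, 2 * res$shift, tolerance = 1e-12)

  # solid coformer: no correction, with a note
  expect_message(res_solid <- fusion_correction(fusion_data(350, 20, T = 300)),
                 "solid")
  expect_equal(res_solid$shift, 0)

  # alternative 3/2 RT policy
  rt <- fusion_correction(f, m = 1, policy = "rt")
  expect_equal(rt$shift, 1.5 * 8.31446261815324e-3 * 300, tolerance = 1e-12)
})

test_that("ddU arithmetic, fusion augmentation and hash guard", {
  expect_equal(as.numeric(delta_delta_U(-205, -100, -105)), 0)
  expect_equal(as.numeric(delta_delta_U(-210, -100, -105)), -5)

  pyr <- fusion_data(231.5, 8.3, T = 300)
  dd <- delta_delta_U(-210, -100, -105, fusion = pyr)
  expect_equal(round(as.numeric(dd), 3), -2.544)
  expect_equal(attr(dd, "correction"), -8.3 * (1 - 300 / 231.5),
               tolerance = 1e-12)

  # stoichiometry weighting
  expect_equal(as.numeric(delta_delta_U(-420, -100, -105, n = 2, m = 2)), -10)

  expect_error(delta_delta_U(-210, -100, -105, hash_cc = "a", hash_api = "b"),
               "hash mismatch")

  # invariance under a uniform additive shift of all single-molecule references
  s <- 17.3
  base <- as.numeric(delta_delta_U(-210, -100, -105, n = 1, m = 2))
  shifted <- as.numeric(delta_delta_U(-210 + 3 * s, -100 + s, -105 + s,
                                      n = 1, m = 2))
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("ranking is a stable ascending permutation with lexicographic ties", {
  e <- data.frame(coformer = c("c3", "c1", "c2"), ddU = c(3, -1, 0))
  r <- rank_coformers(e)
  expect_identical(r$coformer, c("c1", "c2", "c3"))
  expect_identical(r$rank, 1:3)

  tie <- data.frame(coformer = c("B", "A"), ddU = c(2.0, 2.0))
  expect_identical(rank_coformers(tie)$coformer, c("A", "B"))

  single <- rank_coformers(data.frame(coformer = "only", ddU = 1.2))
  expect_identical(single$rank, 1L)

  # permutation property
  set.seed(3)
  big <- data.frame(coformer = paste0("c", 1:25), ddU = rnorm(25))
  rb <- rank_coformers(big)
  expect_setequal(rb$coformer, big$coformer)
  expect_identical(sort(rb$rank), 1:25)
})

test_that("classification uses a strict exceeds rule with named presets", {
  e <- data.frame(coformer = c("a", "b", "c", "d"),
                  ddU = c(5.0, -3, 0.1, 5.0001))
  scr <- classify(e, "screening")
  expect_identical(scr$classification, c("retain", "retain", "retain", "exclude"))
  strict <- classify(e, "strict")
  expect_identical(strict$classification,
                   c("exclude", "retain", "exclude", "exclude"))
  num <- classify(e, 1)
  expect_identical(num$classification, c("exclude", "retain", "retain", "exclude"))
})

test_that("screening statistics match hand counts", {
  e <- data.frame(ddU = c(6, 7, 8, 9, rep(1, 6)),
                  observed = c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 4)))
  st <- screening_stats(e, threshold = 5)
  expect_identical(st$exclusion_pct, 40)
  expect_identical(st$hit_pct, 33)
  expect_identical(st$n_retained, 6L)

  all_obs <- data.frame(ddU = rep(-1, 5), observed = TRUE)
  st2 <- screening_stats(all_obs, 5)
  expect_identical(st2$exclusion_pct, 0)
  expect_identical(st2$hit_pct, 100)

  none_obs <- data.frame(ddU = c(-1, 6), observed = FALSE)
  st3 <- screening_stats(none_obs, 5)
  expect_identical(st3$hit_pct, 0)

  all_excluded <- data.frame(ddU = c(9, 12), observed = FALSE)
  expect_true(is.na(screening_stats(all_excluded, 5)$hit_pct))
})

test_that("table-mode screening produces a self-consistent serialised report", {
  tab <- data.frame(
    coformer = c("nice", "meh", "bad", "wet"),
    U_cc = c(-212, -206, -195, -207),
    U_api = rep(-100, 4), U_c = rep(-105, 4),
    T_fus = c(NA, NA, NA, 231.5), dH_fus = c(NA, NA, NA, 8.3),
    observed = c(TRUE, FALSE, FALSE, TRUE))
  rep <- screen_from_table(tab, threshold = "screening", T = 300)
  expect_identical(rep$entries$coformer[1], "nice")
  expect_equal(rep$entries$ddU[rep$entries$coformer == "bad"], 10)
  expect_equal(round(rep$entries$ddU[rep$entries$coformer == "wet"], 3), 0.456)
  expect_identical(rep$entries$classification[rep$entries$coformer == "bad"],
                   "exclude")

  dir <- file.path(withr::local_tempdir(), "rep")
  save_screen_report(rep, dir)
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  # statistics recompute exactly from the serialised entry list
  st <- screening_stats(back$entries, back$threshold)
  expect_identical(st$exclusion_pct, rep$stats$exclusion_pct)
  expect_identical(st$hit_pct, rep$stats$hit_pct)
  expect_true(file.exists(file.path(dir, "ranked_ddU.csv")))
})

test_that("an end-to-end screen is deterministic and reports the engineered sign", {
  pair <- make_toy_cocrystal_pair(seed = 1)
  cfg <- search_config(list(), spacegroups = "P1", n_candidates = 60, seed = 8)
  api <- list(molecule = pair$api)
  cofs <- list(partner = list(molecule = pair$coformer, observed = TRUE))
  r1 <- run_screen(api, cofs, cfg, pair$params)
  r2 <- run_screen(api, cofs, cfg, pair$params)
  expect_equal(r1$entries, r2$entries)
  expect_identical(nrow(r1$entries), 1L)
  # the engineered pair packs better mixed than neat
  expect_lt(r1$entries$ddU, 0)
  expect_identical(r1$entries$classification, "retain")
  # the searches should have found (at least) the engineered references
  expect_lte(r1$entries$U_cc, pair$U_AC + 0.5)
  expect_lte(r1$entries$U_api, pair$U_A + 0.5)
})

test_that("LAM databases persist across screen runs with zero oracle calls", {
  mol <- make_chain_molecule("flexi")
  oracle1 <- make_torsion_oracle("cosine", amp = 6)
  p <- potential_params(elements = list(C = list(A = 306000, B = 3.6, C = 8200)),
                        cutoff = 6)
  cfg <- search_config(list(), spacegroups = "P1", n_candidates = 6, seed = 4,
                       density_bounds = c(0.2, 4), gtol = 0.5, maxit = 400)
  lam_dir <- file.path(withr::local_tempdir(), "lamdb")
  api <- list(molecule = mol, torsions = 1L, oracle = oracle1)
  cof <- list(partner = list(molecule = make_chain_molecule("rigidc")))
  r1 <- run_screen(api, cof, cfg, p, lam_dir = lam_dir, lam_spacing = 90)
  expect_gt(oracle1$count(), 0)

  oracle2 <- make_torsion_oracle("cosine", amp = 6)
  api2 <- list(molecule = mol, torsions = 1L, oracle = oracle2)
  r2 <- run_screen(api2, cof, cfg, p, lam_dir = lam_dir, lam_spacing = 90)
  expect_identical(oracle2$count(), 0L)   # reuse contract
  # both runs produced a ranked entry from the same persisted database
  expect_identical(nrow(r2$entries), nrow(r1$entries))
})
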