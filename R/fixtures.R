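# Deterministic generators for test inputs: reference ionic lattices with
# known electrostatic (Madelung) constants, synthetic torsional-energy
# oracles, a rigid diatomic molecular crystal with a constructed global
# minimum, and an engineered API/coformer pair for end-to-end screening.
# All fixture potential parameters are fabricated, documented constants.

#' Reference ionic lattice fixtures
#'
#' Charge-neutral prototype lattices with unit charges, used as closed-form
#' oracles for the electrostatic summation (their Madelung constants are
#' known to many decimals).
#'
#' @param kind `"rocksalt"` (8-ion cubic cell, a = 2d) or `"cscl"` (2-ion
#'   cubic cell, a = 2d/sqrt(3)).
#' @param d nearest-neighbour cation-anion distance in angstrom.
#' @return A [crystal_structure()] in P1 whose "molecules" are single ions.
#' @export
make_reference_lattice <- function(kind = c("rocksalt", "cscl"), d = 2.5) {
  kind <- match.arg(kind)
  ion <- function(el, q) molecule(paste0(el, ifelse(q > 0, "+", "-")),
                                  el, matrix(0, 1, 3), charges = q)
  if (kind == "rocksalt") {
    a <- 2 * d
    cell <- unit_cell(a, a, a)
    cat_pos <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5))
    an_pos <- rbind(c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
    placements <- c(
      lapply(seq_len(4), function(i) list(molecule = ion("Na", 1),
                                          frac = cat_pos[i, ])),
      lapply(seq_len(4), function(i) list(molecule = ion("Cl", -1),
                                          frac = an_pos[i, ])))
  } else {
    a <- 2 * d / sqrt(3)
    cell <- unit_cell(a, a, a)
    placements <- list(list(molecule = ion("Cs", 1), frac = c(0, 0, 0)),
                       list(molecule = ion("Cl", -1), frac = c(.5, .5, .5)))
  }
  crystal_structure(cell, "P1", placements)
}

#' Synthetic torsional-energy oracles
#'
#' Closed-form conformational profiles standing in for isolated-molecule
#' electronic-structure calculations, with an evaluation counter.
#'
#' * `"quadratic"`: `sum(k_i * wrap(theta_i)^2)` with `wrap` into
#'   `[-180, 180)` degrees.
#' * `"cosine"`: `sum(amp_i * (1 - cos(theta_i)) / 2)`.
#' * `"sum"`: quadratic + cosine with the two coefficient sets.
#'
#' Charges are the molecule's reference charges, optionally modulated
#' zero-sum by `charge_amp * sin(theta_1)` on the first two atoms (so the
#' total molecular charge is conserved at every conformation).
#'
#' @param profile profile name.
#' @param k quadratic coefficients (kJ/mol/deg^2), recycled over torsions.
#' @param amp cosine amplitudes (kJ/mol), recycled.
#' @param charge_amp zero-sum charge modulation amplitude (e).
#' @param id oracle identifier.
#' @return A [conformational_oracle()].
#' @export
make_torsion_oracle <- function(profile = c("quadratic", "cosine", "sum"),
                                k = 0.01, amp = 10, charge_amp = 0,
                                id = NULL) {
  profile <- match.arg(profile)
  if (is.null(id)) id <- paste0("synthetic-", profile)
  wrap <- function(th) ((th + 180) %% 360) - 180
  fn <- function(molecule, torsions) {
    nt <- length(torsions)
    e <- 0
    if (profile %in% c("quadratic", "sum") && nt > 0)
      e <- e + sum(rep_len(k, nt) * wrap(torsions)^2)
    if (profile %in% c("cosine", "sum") && nt > 0)
      e <- e + sum(rep_len(amp, nt) * (1 - cos(torsions * pi / 180)) / 2)
    q <- molecule$charges
    if (charge_amp != 0 && nt > 0 && length(q) >= 2) {
      dq <- charge_amp * sin(torsions[1] * pi / 180)
      q[1] <- q[1] + dq
      q[2] <- q[2] - dq
    }
    list(energy = e, charges = q)
  }
  conformational_oracle(fn, id = id)
}

#' Fabricated exp-6 parameters for the fixture elements X and Y
#'
#' Documented constants chosen so an X...X contact has its pair minimum near
#' 3 angstrom with a well depth of about 5 kJ/mol. Never to be confused with
#' any published potential.
#'
#' @param pair_C_scale multiplier applied to the X-Y cross dispersion term
#'   (1 = plain geometric-mean combining rule). Values above 1 favour mixed
#'   X/Y packing, values below 1 disfavour it.
#' @param cutoff real-space cutoff (angstrom).
#' @return A [potential_params()] object.
#' @export
fixture_params <- function(pair_C_scale = 1, cutoff = 6) {
  el <- list(A = 306000, B = 3.6, C = 8200)
  pairs <- list()
  if (pair_C_scale != 1) {
    pairs[["X-Y"]] <- list(A = el$A, B = el$B, C = el$C * pair_C_scale)
  }
  potential_params(elements = list(X = el, Y = el), pairs = pairs,
                   cutoff = cutoff,
                   provenance = "fabricated fixture constants")
}

#' Rigid diatomic molecular-crystal fixture
#'
#' A rigid X-Y diatomic (bond 1.2 angstrom, zero charges) together with
#' fabricated exp-6 parameters and a reference structure obtained by
#' relaxing a hand-built dense P1 packing; the relaxation is re-verified to
#' be a fixed point at generation time. The reference serves as the
#' constructed global minimum for search-recovery tests.
#'
#' @param with_reference logical; set `FALSE` to skip the (quick) reference
#'   relaxation.
#' @return `list(molecule, params, reference, U_ref)`.
#' @export
make_diatomic_fixture <- function(with_reference = TRUE) {
  mol <- molecule("diatomic", c("X", "Y"),
                  rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                  bonds = rbind(c(1, 2)))
  params <- fixture_params()
  out <- list(molecule = mol, params = params)
  if (with_reference) {
    start <- crystal_structure(
      unit_cell(3.25, 3.25, 4.8, 75, 70, 70), "P1",
      list(list(molecule = mol, frac = c(0, 0, 0), quat = c(1, 0, 0, 0))))
    ref <- minimize_structure(start, list(), params, gtol = 1e-3, maxit = 500)
    for (i in 1:5) {
      ref2 <- minimize_structure(ref$structure, list(), params, gtol = 1e-3,
                                 maxit = 500)
      if (abs(ref2$value - ref$value) <= 1e-6) break
      ref <- ref2
    }
    if (abs(ref2$value - ref$value) > 1e-6)
      stop("fixture generation error: reference relaxation is not a fixed point")
    out$reference <- ref2$structure
    out$U_ref <- ref2$value
  }
  out
}

#' Engineered API/coformer screening fixture
#'
#' Two rigid diatomics, `A` (X-X) and `C` (Y-Y), with an X-Y cross-term
#' override that makes mixed packing either favourable (`"former"`:
#' reference cocrystal strictly below the sum of the neat references, ddU of
#' the references < 0) or unfavourable (`"non_former"`: ddU > +5 kJ/mol).
#' All three reference structures are produced by deterministic local
#' relaxation and the energy ordering is verified at generation time; a
#' violation raises an error rather than silently emitting a bad fixture.
#'
#' @param seed integer; deterministically perturbs the relaxation starting
#'   points (identical seeds give byte-identical structures).
#' @param variant `"former"` or `"non_former"`.
#' @return `list(api, coformer, params, neat_A, neat_C, cocrystal, U_A, U_C,
#'   U_AC, ddU_ref)` where the structure entries are relaxed
#'   [crystal_structure()]s.
#' @export
make_toy_cocrystal_pair <- function(seed = 1, variant = c("former", "non_former")) {
  variant <- match.arg(variant)
  eps <- 1e-3 * (seed %% 97) / 97  # tiny deterministic start perturbation
  molA <- molecule("toyA", c("X", "X"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                   bonds = rbind(c(1, 2)))
  molC <- molecule("toyC", c("Y", "Y"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                   bonds = rbind(c(1, 2)))
  scale <- if (variant == "former") 1.25 else 0.3
  params <- fixture_params(pair_C_scale = scale)

  relax <- function(cellpar, placements) {
    start <- crystal_structure(do.call(unit_cell, as.list(cellpar)), "P1",
                               placements)
    m <- minimize_structure(start, list(), params, gtol = 1e-5, maxit = 500)
    if (is.null(m$energy)) stop("fixture generation error: relaxation failed")
    m
  }
  neatA <- relax(c(3.25 + eps, 3.25, 4.8, 75, 70, 70),
                 list(list(molecule = molA, frac = c(0, 0, 0))))
  neatC <- relax(c(3.25 + eps, 3.25, 4.8, 75, 70, 70),
                 list(list(molecule = molC, frac = c(0, 0, 0))))
  coAC <- relax(c(3.4 + eps, 3.4, 9.0, 80, 80, 80),
                list(list(molecule = molA, frac = c(0, 0, 0)),
                     list(molecule = molC, frac = c(0.5 + eps, 0.5, 0.5))))
  dd <- coAC$value - neatA$value - neatC$value
  if (variant == "former" && dd >= 0)
    stop("fixture generation error: engineered cocrystal is not favourable (ddU = ",
         round(dd, 3), ")")
  if (variant == "non_former" && dd <= 5)
    stop("fixture generation error: engineered non-former has ddU = ",
         round(dd, 3), " <= 5")
  list(api = molA, coformer = molC, params = params,
       neat_A = neatA$structure, neat_C = neatC$structure,
       cocrystal = coAC$structure,
       U_A = neatA$value, U_C = neatC$value, U_AC = coAC$value, ddU_ref = dd)
}

#' Write fixture outputs to disk in pipeline formats
#'
#' Serialises a fixture to the same external formats the pipeline consumes:
#' CIF for structures, XYZ + sidecar CSV for molecules, YAML for parameters.
#'
#' @param kind fixture kind: `"rocksalt"`, `"cscl"`, `"diatomic-crystal"` or
#'   `"toy-cocrystal-pair"`.
#' @param out output directory.
#' @param seed integer seed (used by the cocrystal pair).
#' @param d nearest-neighbour distance for the ionic lattices.
#' @return `out`, invisibly.
#' @export
write_fixture <- function(kind, out, seed = 1, d = 2.5) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (kind %in% c("rocksalt", "cscl")) {
    write_cif(make_reference_lattice(kind, d), file.path(out, paste0(kind, ".cif")))
  } else if (kind == "diatomic-crystal") {
    fx <- make_diatomic_fixture()
    write_cif(fx$reference, file.path(out, "diatomic_reference.cif"))
    write_molecule_xyz(fx$molecule, file.path(out, "diatomic.xyz"))
  } else if (kind == "toy-cocrystal-pair") {
    fx <- make_toy_cocrystal_pair(seed)
    write_cif(fx$neat_A, file.path(out, "neat_A.cif"))
    write_cif(fx$neat_C, file.path(out, "neat_C.cif"))
    write_cif(fx$cocrystal, file.path(out, "cocrystal_AC.cif"))
    write_molecule_xyz(fx$api, file.path(out, "toyA.xyz"))
    write_molecule_xyz(fx$coformer, file.path(out, "toyC.xyz"))
  } else stop("unknown fixture kind: ", kind)
  invisible(out)
}
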