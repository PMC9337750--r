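# Global search: low-discrepancy candidate generation in chosen space groups,
# local lattice-energy minimisation under space-group constraints, and the
# refinement-stage selection filter.

#' Create a search configuration
#'
#' @param components list of `list(molecule, count)` giving each component of
#'   the composition and its stoichiometric count in the asymmetric unit
#'   (Z' = 1 per component; a 1:1 cocrystal is two entries with count 1).
#' @param spacegroups character vector of space-group symbols to sample.
#' @param n_candidates number of candidate minimisations (>= 1).
#' @param seed integer random seed; recorded in every output.
#' @param length_bounds cell-length bounds in angstrom.
#' @param density_bounds allowed density range in g/cm^3.
#' @param gtol gradient-infinity-norm convergence tolerance (kJ/mol per unit
#'   parameter step).
#' @param maxit minimiser iteration cap.
#' @param overlap_threshold candidates with an intermolecular contact below
#'   `overlap_threshold x` (sum of covalent radii) are discarded and replaced.
#' @return An object of class `ccs_searchconfig`.
#' @export
search_config <- function(components, spacegroups = c("P1", "P-1"),
                          n_candidates = 200, seed = 1,
                          length_bounds = c(2, 40),
                          density_bounds = c(0.4, 4.0),
                          gtol = 0.02, maxit = 1500,
                          overlap_threshold = 0.6) {
  counts <- vapply(components, function(cc) cc$count, 1)
  if (any(counts < 1)) stop("configuration error: component counts must be >= 1")
  if (n_candidates < 1) stop("configuration error: candidate count must be >= 1")
  if (density_bounds[1] > density_bounds[2])
    stop("configuration error: infeasible density bounds")
  structure(list(components = components, spacegroups = spacegroups,
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed),
                 length_bounds = length_bounds,
                 density_bounds = density_bounds,
                 gtol = gtol, maxit = as.integer(maxit),
                 overlap_threshold = overlap_threshold),
            class = "ccs_searchconfig")
}

#' Halton low-discrepancy sequence
#'
#' Deterministic quasi-random points in the unit hypercube with a seeded
#' Cranley-Patterson rotation so different seeds give shifted but equally
#' well-spread streams.
#'
#' @param n number of points.
#' @param dim dimensionality.
#' @param seed integer; controls the random shift (and a leap offset).
#' @return n x dim matrix in `[0, 1)`.
#' @export
halton_sequence <- function(n, dim, seed = 1) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107)
  if (dim > length(primes)) stop("Halton dimension too large")
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  shift <- runif(dim)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- matrix(0, n, dim)
  for (d in seq_len(dim))
    out[, d] <- (vapply(seq_len(n) + 20L, radical_inverse, 0, b = primes[d]) +
                 shift[d]) %% 1
  out
}

# free cell parameters by crystal system
.cell_free <- function(system) {
  switch(system,
         triclinic = c("a", "b", "c", "alpha", "beta", "gamma"),
         monoclinic = c("a", "b", "c", "beta"),
         orthorhombic = c("a", "b", "c"),
         stop("unsupported crystal system: ", system))
}

.cell_from_free <- function(vals, system) {
  p <- c(a = 1, b = 1, c = 1, alpha = 90, beta = 90, gamma = 90)
  p[.cell_free(system)] <- vals
  unit_cell(unname(p["a"]), unname(p["b"]), unname(p["c"]),
            unname(p["alpha"]), unname(p["beta"]), unname(p["gamma"]))
}

# parameter vector layout for one structure template
.par_layout <- function(sg, placements) {
  ncell <- length(.cell_free(sg$system))
  ntors <- vapply(placements, function(p) length(p$torsions), 1L)
  list(ncell = ncell, nmol = length(placements), ntors = ntors,
       total = ncell + sum(7 + ntors))
}

.structure_to_par <- function(structure) {
  lay <- .par_layout(structure$sg, structure$asym)
  cellv <- unlist(structure$cell[.cell_free(structure$sg$system)])
  par <- cellv
  for (p in structure$asym) par <- c(par, p$frac, p$quat, p$torsions)
  unname(par)
}

.par_to_structure <- function(par, template) {
  lay <- .par_layout(template$sg, template$asym)
  cell <- .cell_from_free(par[seq_len(lay$ncell)], template$sg$system)
  off <- lay$ncell
  placements <- template$asym
  for (i in seq_along(placements)) {
    placements[[i]]$frac <- par[off + 1:3] %% 1
    q <- par[off + 4:7]
    placements[[i]]$quat <- q / sqrt(sum(q^2))
    k <- lay$ntors[i]
    if (k > 0) placements[[i]]$torsions <- par[off + 7 + seq_len(k)]
    off <- off + 7 + k
  }
  crystal_structure(cell, template$sg, placements)
}

#' Generate trial crystal structures
#'
#' Samples candidate packings with a seeded Halton low-discrepancy sequence:
#' cell shape (respecting the crystal-system constraints of each requested
#' space group) scaled to a sampled density within bounds, molecular centroid
#' fractional positions, orientations uniform on the quaternion sphere
#' (Shoemake construction), and torsions on the LAM grid nodes. Candidates
#' failing the covalent-radius overlap pre-check are discarded and replaced;
#' the rejection count is attached as an attribute.
#'
#' @param config a [search_config()].
#' @param lamdbs named list of LAM databases keyed by molecule id (needed
#'   only for flexible molecules).
#' @return List of [crystal_structure()] trials of length
#'   `config$n_candidates`, with attribute `n_rejected`.
#' @export
generate_candidates <- function(config, lamdbs = list()) {
  groups <- lapply(config$spacegroups, space_group)
  placements0 <- lapply(config$components, function(cc) {
    reps <- lapply(seq_len(cc$count), function(i)
      list(molecule = cc$molecule, frac = c(0, 0, 0), quat = c(1, 0, 0, 0),
           torsions = if (is.null(cc$torsions)) numeric(0) else cc$torsions))
    reps
  })
  placements0 <- do.call(c, placements0)
  nmol <- length(placements0)
  ntors <- vapply(placements0, function(p) length(p$torsions), 1L)
  # halton dims: group pick(1) + shape(6: 3 ratios + 3 angles) + density(1)
  # + per molecule 3 + 3 (orientation) + torsions
  dim <- 1 + 6 + 1 + sum(6 + ntors)
  masses <- sum(vapply(placements0, function(p)
    sum(.element_lookup(p$molecule$elements, "mass")), 0))

  out <- vector("list", config$n_candidates)
  n_rejected <- 0L
  got <- 0L
  batch_start <- 0L
  rcov_cache <- NULL
  while (got < config$n_candidates) {
    nbatch <- max(config$n_candidates - got, 16L)
    H <- halton_sequence(nbatch, dim, seed = config$seed + 7L * batch_start)
    batch_start <- batch_start + 1L
    for (r in seq_len(nbatch)) {
      if (got >= config$n_candidates) break
      u <- H[r, ]
      sg <- groups[[1 + (floor(u[1] * length(groups)) %% length(groups))]]
      ratios <- 0.5 + 1.5 * u[2:4]          # relative cell edge ratios
      angles <- 60 + 60 * u[5:7]            # free angles in [60, 120)
      dens <- config$density_bounds[1] +
        u[8] * (config$density_bounds[2] - config$density_bounds[1])
      free <- .cell_free(sg$system)
      vals <- c(a = ratios[1], b = ratios[2], c = ratios[3],
                alpha = angles[1], beta = angles[2], gamma = angles[3])[free]
      cell <- tryCatch(.cell_from_free(vals, sg$system), error = function(e) NULL)
      if (is.null(cell)) { n_rejected <- n_rejected + 1L; next }
      # scale the cell so the expanded-cell density hits the sampled value
      vol_target <- masses * sg$n_ops / (dens * 0.602214076)
      s <- (vol_target / cell_volume(cell))^(1 / 3)
      vals[seq_len(3)] <- vals[seq_len(3)] * s
      if (any(vals[1:3] < config$length_bounds[1] |
              vals[1:3] > config$length_bounds[2])) {
        n_rejected <- n_rejected + 1L; next
      }
      cell <- .cell_from_free(vals, sg$system)
      placements <- placements0
      off <- 8
      for (i in seq_len(nmol)) {
        placements[[i]]$frac <- u[off + 1:3]
        v <- u[off + 4:6]
        placements[[i]]$quat <- c(sqrt(1 - v[1]) * sin(2 * pi * v[2]),
                                  sqrt(1 - v[1]) * cos(2 * pi * v[2]),
                                  sqrt(v[1]) * sin(2 * pi * v[3]),
                                  sqrt(v[1]) * cos(2 * pi * v[3]))
        k <- ntors[i]
        if (k > 0) {
          db <- lamdbs[[placements[[i]]$molecule$id]]
          if (is.null(db))
            stop("flexible molecule '", placements[[i]]$molecule$id,
                 "' has no LAM grid")
          node <- floor(u[off + 6 + seq_len(k)] * db$dims)
          placements[[i]]$torsions <- node * db$spacing
        }
        off <- off + 6 + k
      }
      st <- tryCatch(crystal_structure(cell, sg, placements),
                     error = function(e) NULL)
      if (is.null(st)) { n_rejected <- n_rejected + 1L; next }
      cont <- .cell_contents(st)
      rcov <- .element_lookup(cont$elements, "r_cov")
      ratio <- cpp_min_contact_ratio(cont$xyz, cont$mol_id, rcov,
                                     cell_matrix(cell), 6)
      if (ratio < config$overlap_threshold) { n_rejected <- n_rejected + 1L; next }
      got <- got + 1L
      attr(st, "candidate_index") <- got
      out[[got]] <- st
    }
    if (batch_start > 500L)
      stop("candidate generation failed: too many overlap rejections")
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Locally minimise the lattice energy of a trial structure
#'
#' Quasi-Newton (L-BFGS-B) descent over the free cell parameters, molecular
#' centroids, orientation quaternions (projection-renormalised) and torsion
#' values, under the trial's space-group constraints. Numerical gradients are
#' used; exp-6 collapse during a line search maps to a large penalty so the
#' step is rejected.
#'
#' @param trial a [crystal_structure()].
#' @param lamdbs named list of LAM databases (for flexible molecules).
#' @param params a [potential_params()].
#' @param gtol gradient infinity-norm for the converged flag.
#' @param maxit iteration cap.
#' @return An object of class `ccs_minimum`: `list(structure, energy,
#'   converged, gnorm, value)` where `energy` is the [total_lattice_energy()]
#'   breakdown of the relaxed structure.
#' @export
minimize_structure <- function(trial, lamdbs = list(), params,
                               gtol = 0.02, maxit = 1500,
                               overlap_threshold = 0.6) {
  pm <- .pair_matrices(params, unlist(lapply(trial$asym, function(p)
    p$molecule$elements)))
  cont0 <- .cell_contents(trial)
  rcov <- .element_lookup(cont0$elements, "r_cov")
  par0 <- .structure_to_par(trial)
  # compiled whole-evaluation path: parameters -> torsion-resolved conformer
  # -> expanded cell -> energy (+ interpolated LAM intramolecular term)
  lay <- .par_layout(trial$sg, trial$asym)
  sysid <- match(trial$sg$system, c("triclinic", "monoclinic", "orthorhombic")) - 1L
  coords0 <- do.call(rbind, lapply(trial$asym, function(p) p$molecule$xyz))
  apm <- vapply(trial$asym, function(p) length(p$molecule$elements), 1L)
  elems <- unlist(lapply(trial$asym, function(p) p$molecule$elements))
  typev <- match(elems, pm$types) - 1L
  qv <- unlist(lapply(trial$asym, function(p) p$molecule$charges))
  rcv <- .element_lookup(elems, "r_cov")
  opsR <- do.call(rbind, lapply(trial$sg$ops, `[[`, "R"))
  opst <- do.call(rbind, lapply(trial$sg$ops, `[[`, "t"))
  alpha <- params$ewald_accuracy / params$cutoff
  kcut <- 2 * alpha * params$ewald_accuracy
  do_elec <- any(qv != 0)
  # torsion metadata (molecule-local 0-based indices) and LAM grid tables
  tor_atoms <- integer(0); tor_mov_len <- integer(0); tor_moving <- integer(0)
  lam_offsets <- integer(lay$nmol); lam_meta_off <- integer(lay$nmol)
  lam_vals <- numeric(0); lam_dims <- integer(0); lam_spacing <- numeric(0)
  for (mi in seq_along(trial$asym)) {
    p <- trial$asym[[mi]]
    k <- length(p$torsions)
    lam_offsets[mi] <- -1L
    lam_meta_off[mi] <- length(lam_dims)
    if (k > 0) {
      mol <- p$molecule
      for (t in mol$torsions[seq_len(k)]) {
        tor_atoms <- c(tor_atoms, t - 1L)
        moving <- .torsion_side(length(mol$elements), mol$bonds, t[2], t[3]) - 1L
        tor_mov_len <- c(tor_mov_len, length(moving))
        tor_moving <- c(tor_moving, moving)
      }
      db <- lamdbs[[mol$id]]
      if (!is.null(db)) {
        lam_offsets[mi] <- length(lam_vals)
        lam_vals <- c(lam_vals, db$energies)
        lam_dims <- c(lam_dims, db$dims)
        lam_spacing <- c(lam_spacing, db$spacing)
      }
    }
  }
  ntors_v <- vapply(trial$asym, function(p) length(p$torsions), 1L)
  ev <- function(p, want_grad, central = FALSE) {
    cpp_flex_energy(p, sysid, lay$ncell, coords0, apm, ntors_v, typev, qv,
                    rcv, opsR, opst, pm$A, pm$B, pm$C, params$cutoff,
                    params$tail_correction, alpha, kcut, do_elec,
                    overlap_threshold, tor_atoms, tor_mov_len, tor_moving,
                    lam_offsets, lam_vals, lam_dims, lam_spacing,
                    lam_meta_off, want_grad, central)
  }
  fn <- function(p) ev(p, FALSE)$value
  grfn <- function(p) ev(p, TRUE)$gradient
  grfn_polish <- function(p) ev(p, TRUE, central = TRUE)$gradient
  e0 <- fn(par0)
  if (e0 >= 1e8) {
    return(structure(list(structure = trial, energy = NULL, converged = FALSE,
                          gnorm = Inf, value = Inf,
                          reason = "overlap at start"),
                     class = "ccs_minimum"))
  }
  lay <- .par_layout(trial$sg, trial$asym)
  lower <- rep(-Inf, lay$total); upper <- rep(Inf, lay$total)
  free <- .cell_free(trial$sg$system)
  nlen <- sum(free %in% c("a", "b", "c"))
  lower[seq_len(nlen)] <- 1.0; upper[seq_len(nlen)] <- 80
  if (lay$ncell > nlen) {   # free angles
    lower[(nlen + 1):lay$ncell] <- 40; upper[(nlen + 1):lay$ncell] <- 140
  }
  # Descent strategy: L-BFGS-B with the cheap one-sided gradient, then a
  # central-difference polish. One-sided noise can both stall a run above
  # the tolerance and poison the curvature memory, so unconverged runs are
  # restarted from scratch (fresh Hessian) — a restarted cycle typically
  # finishes in a handful of iterations.
  run_seg <- function(par, gradfn, factr) tryCatch(
    optim(par, fn, gradfn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = maxit, factr = factr)),
    error = function(e) NULL)
  gr <- if (!is.null(grfn)) grfn else function(p) .num_gradient(fn, p)
  par <- par0
  value <- e0
  g <- NULL
  for (round in 1:2) {
    res <- run_seg(par, gr, 1e5)
    if (!is.null(res) && is.finite(res$value) && res$value <= value) {
      par <- res$par; value <- res$value
    }
    g <- .num_gradient(fn, par, value)
    if (max(abs(g)) <= gtol) break
    res2 <- run_seg(par, grfn_polish, 1e4)
    improved <- FALSE
    if (!is.null(res2) && is.finite(res2$value) && res2$value <= value) {
      improved <- res2$value < value - 1e-10
      par <- res2$par; value <- res2$value
    }
    g <- .num_gradient(fn, par, value)
    if (max(abs(g)) <= gtol || !improved) break
  }
  if (!is.finite(value) || value >= 1e7) {
    return(structure(list(structure = trial, energy = NULL, converged = FALSE,
                          gnorm = Inf, value = Inf,
                          reason = "minimisation failed"),
                     class = "ccs_minimum"))
  }
  st <- .par_to_structure(par, trial)
  en <- tryCatch(total_lattice_energy(st, lamdbs, params),
                 error = function(e) NULL)
  if (is.null(en)) {
    return(structure(list(structure = st, energy = NULL, converged = FALSE,
                          gnorm = Inf, value = Inf, reason = "energy failure"),
                     class = "ccs_minimum"))
  }
  structure(list(structure = st, energy = en, converged = max(abs(g)) <= gtol,
                 gnorm = max(abs(g)), value = en$U_total, reason = NULL),
            class = "ccs_minimum")
}

.num_gradient <- function(fn, par, f0 = NULL, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    hi <- h * max(1, abs(par[i]))
    p1 <- par; p1[i] <- p1[i] + hi
    p2 <- par; p2[i] <- p2[i] - hi
    (fn(p1) - fn(p2)) / (2 * hi)
  }, 0)
}

#' @export
print.ccs_minimum <- function(x, ...) {
  if (is.null(x$energy)) {
    cat("<local minimum> failed:", x$reason, "\n")
  } else {
    cat(sprintf("<local minimum> U_total = %.4f kJ/mol (converged: %s, |g| = %.2e)\n",
                x$value, x$converged, x$gnorm))
  }
  invisible(x)
}

#' Run a global lattice-energy search
#'
#' Generates `config$n_candidates` trial structures and locally minimises
#' each; all converged minima with density inside the configured bounds are
#' returned with full provenance. The run is deterministic for a fixed seed
#' and independent of how candidates are chunked over workers.
#'
#' @param config a [search_config()].
#' @param lamdbs named list of LAM databases keyed by molecule id.
#' @param params a [potential_params()].
#' @param progress logical, print a line every 100 candidates.
#' @return List of `ccs_minimum` objects (possibly empty, with a warning).
#' @export
global_search <- function(config, lamdbs = list(), params, progress = FALSE) {
  trials <- generate_candidates(config, lamdbs)
  minima <- vector("list", length(trials))
  kept <- 0L
  for (i in seq_along(trials)) {
    m <- minimize_structure(trials[[i]], lamdbs, params,
                            gtol = config$gtol, maxit = config$maxit,
                            overlap_threshold = config$overlap_threshold)
    if (progress && i %% 100 == 0)
      message("  candidate ", i, "/", length(trials))
    if (is.null(m$energy) || !m$converged) next
    dens <- crystal_density(m$structure)
    if (dens < config$density_bounds[1] || dens > config$density_bounds[2]) next
    m$provenance <- list(seed = config$seed, candidate_index = i)
    m$density <- dens
    kept <- kept + 1L
    minima[[kept]] <- m
  }
  minima <- minima[seq_len(kept)]
  if (kept == 0L) warning("global search produced no converged minima")
  minima
}

#' Refinement-stage selection filter
#'
#' Keeps all structures within `window` kJ/mol (inclusive) of the global
#' minimum; if more than `cap` survive, the `cap` lowest-energy entries are
#' kept (stable sort, input order breaks ties).
#'
#' @param minima list of `ccs_minimum` (or a clustered landscape's entries).
#' @param window energy window in kJ/mol (default 20).
#' @param cap maximum number kept (default 500).
#' @return The selected subset, sorted by energy.
#' @export
refinement_filter <- function(minima, window = 20, cap = 500) {
  if (length(minima) == 0) return(minima)
  E <- vapply(minima, function(m) m$value, 0)
  keep <- which(E - min(E) <= window)
  ord <- keep[order(E[keep])]   # stable: order() preserves input order on ties
  if (length(ord) > cap) ord <- ord[seq_len(cap)]
  minima[ord]
}
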