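# Local approximate model (LAM) database: intramolecular energy and atomic
# charges tabulated over a periodic torsion grid from a pluggable
# conformational-energy oracle, then interpolated at negligible cost. The
# database is the pipeline's efficiency mechanism: built once per molecule,
# persisted, and reused across any number of searches.

#' Create a conformational-energy oracle
#'
#' Wraps a function `(molecule, torsion values in degrees) -> list(energy =
#' kJ/mol, charges = per-atom e)` with an evaluation counter. The oracle is
#' the pluggable stand-in for isolated-molecule electronic-structure
#' calculations; it must be deterministic in its inputs.
#'
#' @param fn the evaluation function.
#' @param id identifier recorded in database provenance.
#' @return An object of class `ccs_oracle` with `$eval()`, `$count()` and
#'   `$reset()`.
#' @export
conformational_oracle <- function(fn, id = "oracle") {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  obj <- list(
    id = id,
    eval = function(molecule, torsions) {
      env$n <- env$n + 1L
      res <- fn(molecule, torsions)
      if (is.null(res$charges)) res$charges <- molecule$charges
      res
    },
    count = function() env$n,
    reset = function() { env$n <- 0L; invisible(NULL) }
  )
  class(obj) <- "ccs_oracle"
  obj
}

#' Identify flexible torsions by energy probing
#'
#' Each candidate torsion declared on the molecule is perturbed by +/- `probe`
#' degrees from the reference conformation. A torsion is flexible iff the
#' larger of the two perturbation energies (relative to the reference) is at
#' most `threshold`; stiffer torsions are frozen at their reference values.
#'
#' @param molecule a [molecule()] with declared candidate torsions.
#' @param oracle a [conformational_oracle()].
#' @param probe perturbation in degrees (default 15).
#' @param threshold flexibility cutoff in kJ/mol (default 20).
#' @return Integer indices (into `molecule$torsions`) of flexible torsions.
#' @export
identify_flexible_torsions <- function(molecule, oracle, probe = 15,
                                       threshold = 20) {
  if (length(molecule$torsions) == 0) return(integer(0))
  ref_vals <- vapply(molecule$torsions, function(t)
    dihedral_angle(molecule$xyz[t[1], ], molecule$xyz[t[2], ],
                   molecule$xyz[t[3], ], molecule$xyz[t[4], ]), 0)
  e0 <- .oracle_try(oracle, molecule, ref_vals, "reference")$energy
  flex <- integer(0)
  for (k in seq_along(molecule$torsions)) {
    dE <- vapply(c(probe, -probe), function(d) {
      v <- ref_vals
      v[k] <- v[k] + d
      .oracle_try(oracle, molecule, v, paste0("torsion ", k))$energy - e0
    }, 0)
    if (max(dE) <= threshold) flex <- c(flex, k)
  }
  flex
}

.oracle_try <- function(oracle, molecule, torsions, label) {
  tryCatch(oracle$eval(molecule, torsions),
           error = function(e) stop("oracle failure at ", label, " (",
                                    paste(round(torsions, 2), collapse = ","),
                                    " deg): ", conditionMessage(e)))
}

#' Build a LAM database on a uniform torsion grid
#'
#' Evaluates the oracle once per grid node over the periodic torsion space
#' (nodes at 0, s, 2s, ..., 360-s degrees per torsion) and stores the
#' intramolecular energy, re-referenced so the grid minimum is zero, together
#' with per-atom charges. Optionally one refinement pass halves the spacing
#' along any axis where adjacent nodes differ by more than `delta_star`.
#'
#' @param molecule a [molecule()].
#' @param torsions integer indices of the flexible torsions to grid.
#' @param oracle a [conformational_oracle()].
#' @param spacing grid spacing in degrees, one value or one per torsion; each
#'   must divide 360 evenly.
#' @param delta_star convergence criterion in kJ/mol (default 5): with
#'   `refine = TRUE`, any axis whose adjacent-node energy gap exceeds it is
#'   re-gridded at half the spacing.
#' @param refine logical, do the one-shot refinement pass.
#' @return An object of class `ccs_lamdb`.
#' @export
build_lam_grid <- function(molecule, torsions, oracle, spacing = 60,
                           delta_star = 5, refine = FALSE) {
  nt <- length(torsions)
  spacing <- rep_len(spacing, max(nt, 1))
  if (any(360 %% spacing != 0))
    stop("configuration error: spacing must divide 360 evenly")
  db <- .lam_tabulate(molecule, torsions, oracle, spacing, delta_star)
  if (refine && nt > 0) {
    gaps <- .lam_axis_gaps(db)
    if (any(gaps > delta_star)) {
      spacing2 <- ifelse(gaps > delta_star, spacing / 2, spacing)
      if (any(360 %% spacing2 != 0)) spacing2 <- spacing / 2
      db <- .lam_tabulate(molecule, torsions, oracle, spacing2, delta_star)
    }
  }
  db
}

.lam_tabulate <- function(molecule, torsions, oracle, spacing, delta_star) {
  nt <- length(torsions)
  if (nt == 0) {
    res <- .oracle_try(oracle, molecule, numeric(0), "rigid reference")
    return(structure(list(molecule_id = molecule$id, torsions = integer(0),
                          spacing = numeric(0), dims = integer(0),
                          energies = 0, e_ref = res$energy,
                          charges = matrix(res$charges, ncol = 1),
                          delta_star = delta_star, version = 1L,
                          provenance = list(oracle = oracle$id)),
                     class = "ccs_lamdb"))
  }
  axes <- lapply(spacing[seq_len(nt)], function(s) seq(0, 360 - s, by = s))
  dims <- vapply(axes, length, 1L)
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  n_nodes <- nrow(grid)
  energies <- numeric(n_nodes)
  charges <- matrix(0, length(molecule$charges), n_nodes)
  for (i in seq_len(n_nodes)) {
    res <- .oracle_try(oracle, molecule, grid[i, ], paste0("node ", i))
    energies[i] <- res$energy
    charges[, i] <- res$charges
  }
  e_min <- min(energies)
  structure(list(molecule_id = molecule$id,
                 torsions = as.integer(torsions),
                 spacing = spacing[seq_len(nt)], dims = dims,
                 energies = energies - e_min, e_ref = e_min,
                 charges = charges, delta_star = delta_star, version = 1L,
                 provenance = list(oracle = oracle$id)),
            class = "ccs_lamdb")
}

# largest adjacent-node energy difference along each torsion axis
.lam_axis_gaps <- function(db) {
  nt <- length(db$dims)
  arr <- array(db$energies, dim = db$dims)
  vapply(seq_len(nt), function(ax) {
    shifted <- .roll_axis(arr, ax)
    max(abs(arr - shifted))
  }, 0)
}

.roll_axis <- function(arr, ax) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- c(2:d[ax], 1L)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' @export
print.ccs_lamdb <- function(x, ...) {
  cat("<LAM database>", x$molecule_id, ":", length(x$energies), "nodes over",
      length(x$dims), "torsion(s), spacing",
      paste(x$spacing, collapse = "/"), "deg\n")
  invisible(x)
}

#' Interpolate intramolecular energy and charges from a LAM database
#'
#' Multilinear interpolation on the periodic torsion grid: exact at nodes,
#' periodic with period 360 degrees in every torsion, and free of oracle
#' calls (the reuse contract).
#'
#' @param db a [build_lam_grid()] database.
#' @param values numeric torsion values in degrees; length must match the
#'   database dimensionality.
#' @return `list(energy = kJ/mol relative to the grid minimum,
#'   charges = per-atom e)`.
#' @export
evaluate_lam <- function(db, values) {
  nt <- length(db$dims)
  if (length(values) != nt)
    stop("dimensionality mismatch: database has ", nt, " torsion(s), query has ",
         length(values))
  if (nt == 0) return(list(energy = 0, charges = db$charges[, 1]))
  # corner weights for multilinear interpolation on the periodic grid
  lo <- integer(nt); fr <- numeric(nt)
  for (k in seq_len(nt)) {
    pos <- (values[k] %% 360) / db$spacing[k]
    lo[k] <- floor(pos)
    fr[k] <- pos - lo[k]
  }
  energy <- 0
  charges <- numeric(nrow(db$charges))
  for (corner in seq_len(2^nt) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(nt)]
    idx <- (lo + bits) %% db$dims  # periodic wrap
    w <- prod(ifelse(bits == 1, fr, 1 - fr))
    if (w == 0) next
    flat <- sum(idx * cumprod(c(1, db$dims[-nt]))) + 1
    energy <- energy + w * db$energies[flat]
    charges <- charges + w * db$charges[, flat]
  }
  list(energy = energy, charges = charges)
}

#' Persist and reload a LAM database
#'
#' The database is written as a directory holding `meta.json` (identifiers,
#' torsions, spacing, version, provenance) and `nodes.csv` (per-node energy
#' and charges). `load_lam(save_lam(db))` is the identity, and a loaded
#' database answers [evaluate_lam()] with zero oracle calls.
#'
#' @param db a `ccs_lamdb`.
#' @param path directory to create or read.
#' @return `save_lam`: `path` invisibly. `load_lam`: the database.
#' @export
save_lam <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- db[c("molecule_id", "torsions", "spacing", "dims", "e_ref",
               "delta_star", "version", "provenance")]
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  nodes <- data.frame(node = seq_along(db$energies), energy = db$energies)
  ch <- t(db$charges)
  colnames(ch) <- paste0("q", seq_len(ncol(ch)))
  write.csv(cbind(nodes, ch), file.path(path, "nodes.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_lam
#' @export
load_lam <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (is.null(meta$version) || meta$version != 1L)
    stop("LAM database version mismatch: expected 1, found ",
         if (is.null(meta$version)) "none" else meta$version)
  nodes <- read.csv(file.path(path, "nodes.csv"))
  qcols <- grep("^q", names(nodes))
  charges <- t(as.matrix(nodes[, qcols, drop = FALSE]))
  dimnames(charges) <- NULL
  structure(list(molecule_id = meta$molecule_id,
                 torsions = as.integer(meta$torsions),
                 spacing = as.numeric(meta$spacing),
                 dims = as.integer(meta$dims),
                 energies = nodes$energy, e_ref = meta$e_ref,
                 charges = charges,
                 delta_star = meta$delta_star, version = 1L,
                 provenance = meta$provenance),
            class = "ccs_lamdb")
}
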