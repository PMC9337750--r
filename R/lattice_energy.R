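# exp-6 repulsion-dispersion + Ewald point-charge electrostatics +
# LAM-interpolated intramolecular energy. Energies are reported in kJ/mol per
# asymmetric-unit formula (cell energy divided by the operator count).

#' Create an exp-6 potential parameter set
#'
#' Per-element Buckingham coefficients `U(r) = A exp(-B r) - C / r^6` with
#' cross terms from combining rules (geometric mean for A and C, arithmetic
#' mean for B) unless overridden per pair. Electrostatics are point charges in
#' vacuum (relative permittivity fixed at 1), summed by Ewald.
#'
#' @param elements named list: each entry `list(A = kJ/mol, B = 1/angstrom,
#'   C = kJ angstrom^6/mol)` keyed by element symbol.
#' @param pairs optional named list of per-pair overrides, keys like
#'   `"C-H"` (order-insensitive), values `list(A, B, C)`.
#' @param cutoff real-space cutoff in angstrom.
#' @param tail_correction logical; add the uniform-density dispersion tail.
#' @param ewald_accuracy dimensionless parameter controlling the Ewald
#'   splitting: `alpha = ewald_accuracy / cutoff`, reciprocal cutoff
#'   `2 * alpha * ewald_accuracy`.
#' @param provenance free-text note on where the numbers come from.
#' @return An object of class `ccs_params`.
#' @export
potential_params <- function(elements, pairs = list(), cutoff = 15,
                             tail_correction = TRUE, ewald_accuracy = 4.8,
                             provenance = "user-supplied") {
  stopifnot(cutoff > 0, length(elements) > 0)
  for (el in names(elements)) {
    p <- elements[[el]]
    if (any(unlist(p[c("A", "B", "C")]) < 0))
      stop("exp-6 coefficients must be non-negative (element ", el, ")")
  }
  obj <- structure(list(elements = elements, pairs = pairs, cutoff = cutoff,
                        tail_correction = tail_correction,
                        ewald_accuracy = ewald_accuracy,
                        provenance = provenance),
                   class = "ccs_params")
  obj$hash <- .params_hash(obj)
  obj
}

.params_hash <- function(p) {
  s <- paste(capture.output(str(p[c("elements", "pairs", "cutoff",
                                    "tail_correction")], digits.d = 12)),
             collapse = "")
  # small rolling hash; only used to detect mixing of parameter sets
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d", h)
}

#' Load a potential parameter file (YAML)
#'
#' File layout: a top-level `elements` map of element blocks with `A`, `B`,
#' `C`; optional `pairs` map of overrides; optional `cutoff`,
#' `tail_correction`. Units are kJ/mol and angstrom, declared in-file.
#'
#' @param path YAML file.
#' @return A [potential_params()] object.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  potential_params(elements = y$elements,
                   pairs = if (is.null(y$pairs)) list() else y$pairs,
                   cutoff = if (is.null(y$cutoff)) 15 else y$cutoff,
                   tail_correction = if (is.null(y$tail_correction)) TRUE
                                     else y$tail_correction,
                   provenance = if (is.null(y$provenance)) path else y$provenance)
}

#' Default exp-6 parameters for C, H, N, O
#'
#' A small documented Buckingham set in the Williams tradition of
#' atom-atom potentials for organic crystals (A in kJ/mol, B in 1/angstrom,
#' C in kJ angstrom^6/mol). Suitable for qualitative packing energetics;
#' screening studies should supply their own validated set via
#' [read_params()].
#'
#' @return A [potential_params()] object.
#' @export
default_params <- function() {
  read_params(system.file("params", "default.yaml", package = "cocryscreen"))
}

# build pair matrices over the element types present
.pair_matrices <- function(params, elements) {
  types <- unique(elements)
  nt <- length(types)
  A <- B <- C <- matrix(0, nt, nt)
  get_el <- function(el) {
    p <- params$elements[[el]]
    if (is.null(p)) stop("no exp-6 parameters for element ", el)
    p
  }
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    key1 <- paste0(types[i], "-", types[j]); key2 <- paste0(types[j], "-", types[i])
    ov <- params$pairs[[key1]]
    if (is.null(ov)) ov <- params$pairs[[key2]]
    if (!is.null(ov)) {
      A[i, j] <- ov$A; B[i, j] <- ov$B; C[i, j] <- ov$C
    } else {
      pi_ <- get_el(types[i]); pj <- get_el(types[j])
      A[i, j] <- sqrt(pi_$A * pj$A)
      B[i, j] <- (pi_$B + pj$B) / 2
      C[i, j] <- sqrt(pi_$C * pj$C)
    }
  }
  list(types = types, A = A, B = B, C = C)
}

#' exp-6 (Buckingham) intermolecular energy
#'
#' Sum of `A exp(-B r) - C/r^6` over all intermolecular atom pairs within the
#' real-space cutoff (periodic images included), with an optional analytic
#' dispersion tail correction, per asymmetric-unit formula.
#'
#' @param structure a [crystal_structure()].
#' @param params a [potential_params()].
#' @return Energy in kJ/mol per asymmetric-unit formula.
#' @export
exp6_energy <- function(structure, params) {
  cont <- .cell_contents(structure)
  pm <- .pair_matrices(params, cont$elements)
  type <- match(cont$elements, pm$types) - 1L
  M <- cell_matrix(structure$cell)
  E <- cpp_exp6_energy(cont$xyz, cont$mol_id, type, pm$A, pm$B, pm$C, M,
                       params$cutoff, params$tail_correction)
  E / structure$sg$n_ops
}

#' Ewald-summed point-charge electrostatic energy
#'
#' Real-space, reciprocal-space and self terms of the Ewald decomposition of
#' the intermolecular Coulomb sum; intramolecular pairs are excluded. The
#' cell must be charge-neutral.
#'
#' @inheritParams exp6_energy
#' @return Energy in kJ/mol per asymmetric-unit formula.
#' @export
ewald_energy <- function(structure, params = NULL) {
  cont <- .cell_contents(structure)
  if (abs(sum(cont$charges)) > 1e-8)
    stop("Ewald summation requires a charge-neutral cell (net charge ",
         format(sum(cont$charges)), " e)")
  if (all(cont$charges == 0)) return(0)
  cutoff <- if (is.null(params)) 15 else params$cutoff
  acc <- if (is.null(params)) 4.8 else params$ewald_accuracy
  alpha <- acc / cutoff
  kcut <- 2 * alpha * acc
  M <- cell_matrix(structure$cell)
  E <- cpp_ewald_energy(cont$xyz, cont$mol_id, cont$charges, M, alpha,
                        cutoff, kcut)
  E / structure$sg$n_ops
}

#' Total lattice energy with breakdown
#'
#' `U_total = U_exp6 + U_electrostatic + dU_intra`, where the intramolecular
#' term is interpolated from the molecule's LAM database at the placement's
#' torsion values (zero for rigid molecules).
#'
#' @param structure a [crystal_structure()].
#' @param lamdb a single [build_lam_grid()] database, a named list of
#'   databases keyed by molecule id, or `NULL` for rigid molecules.
#' @param params a [potential_params()].
#' @return An object of class `ccs_energy`: list with `U_exp6`,
#'   `U_electrostatic`, `dU_intra`, `U_total` (kJ/mol per asymmetric-unit
#'   formula).
#' @export
total_lattice_energy <- function(structure, lamdb = NULL, params) {
  U6 <- tryCatch(exp6_energy(structure, params),
                 error = function(e) stop("exp-6 stage: ", conditionMessage(e)))
  Ue <- tryCatch(ewald_energy(structure, params),
                 error = function(e) stop("electrostatics stage: ",
                                          conditionMessage(e)))
  Ui <- 0
  for (p in structure$asym) {
    if (length(p$torsions) == 0) next
    db <- lamdb
    if (!is.null(db) && !inherits(db, "ccs_lamdb")) db <- lamdb[[p$molecule$id]]
    if (is.null(db))
      stop("intramolecular stage: no LAM database for flexible molecule '",
           p$molecule$id, "'")
    Ui <- Ui + evaluate_lam(db, p$torsions)$energy
  }
  structure(list(U_exp6 = U6, U_electrostatic = Ue, dU_intra = Ui,
                 U_total = U6 + Ue + Ui),
            class = "ccs_energy")
}

#' @export
print.ccs_energy <- function(x, ...) {
  cat(sprintf("U_exp6 = %.4f  U_elec = %.4f  dU_intra = %.4f  U_total = %.4f kJ/mol\n",
              x$U_exp6, x$U_electrostatic, x$dU_intra, x$U_total))
  invisible(x)
}
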