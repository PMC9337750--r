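#' @useDynLib cocryscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif rnorm setNames
#' @importFrom utils head read.csv write.csv capture.output str
NULL

# ---- Molecule ---------------------------------------------------------------

#' Create a molecule
#'
#' A molecule is a set of atoms with Cartesian coordinates (angstrom), a bond
#' list, optional rotatable-torsion definitions and per-atom partial charges
#' (elementary charge units). Coordinates are stored centred on the centroid;
#' crystal structures place molecules by centroid position and orientation
#' quaternion, so the stored geometry is the reference conformation.
#'
#' @param id character identifier.
#' @param elements character vector of element symbols.
#' @param xyz numeric n x 3 matrix of Cartesian coordinates in angstrom.
#' @param bonds integer m x 2 matrix of 1-based atom index pairs. A single
#'   atom needs no bonds; otherwise the bond graph must be connected.
#' @param charges numeric per-atom partial charges; defaults to zeros.
#' @param torsions list of length-4 integer vectors (i, j, k, l) declaring
#'   candidate rotatable torsions about the j-k bond. Indices must be bonded
#'   in chain: i-j, j-k and k-l must all be bonds.
#' @return An object of class `ccs_molecule`.
#' @export
molecule <- function(id, elements, xyz, bonds = NULL, charges = NULL,
                     torsions = list()) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(elements)
  if (nrow(xyz) != n || ncol(xyz) != 3)
    stop("xyz must be a ", n, " x 3 matrix")
  if (is.null(charges)) charges <- rep(0, n)
  if (length(charges) != n)
    stop("charge list length (", length(charges), ") must equal atom count (", n, ")")
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n))
    stop("bond indices out of range")
  # connectivity is only checkable when a bond list is supplied (CIF carries none)
  if (n > 1 && nrow(bonds) > 0 && !.graph_connected(n, bonds))
    stop("bond graph is not connected")
  has_bond <- function(a, b) {
    any((bonds[, 1] == a & bonds[, 2] == b) | (bonds[, 1] == b & bonds[, 2] == a))
  }
  for (t in torsions) {
    t <- as.integer(t)
    if (length(t) != 4 || any(t < 1 | t > n))
      stop("torsion must be 4 valid atom indices")
    if (!(has_bond(t[1], t[2]) && has_bond(t[2], t[3]) && has_bond(t[3], t[4])))
      stop("torsion atoms must be bonded in chain")
  }
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  structure(list(id = id, elements = as.character(elements), xyz = xyz,
                 bonds = bonds, charges = as.numeric(charges),
                 torsions = lapply(torsions, as.integer)),
            class = "ccs_molecule")
}

.graph_connected <- function(n, bonds) {
  if (n <= 1) return(TRUE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' @export
print.ccs_molecule <- function(x, ...) {
  cat("<molecule>", x$id, ":", length(x$elements), "atoms,",
      nrow(x$bonds), "bonds,", length(x$torsions), "candidate torsions\n")
  invisible(x)
}

# Apply torsion values (degrees) to a molecule's reference geometry.
# For torsion (i,j,k,l) the atoms on the l side of bond j-k are rotated about
# the j->k axis until the dihedral i-j-k-l equals the requested value.
#' Set torsion angles on a molecule
#'
#' Returns a copy of the molecule whose declared torsions are rotated to the
#' given dihedral values (degrees). Atoms on the far side of each torsion's
#' central bond are moved; the rest of the molecule is untouched.
#'
#' @param mol a [molecule()].
#' @param values numeric vector of dihedral targets in degrees, one per
#'   declared torsion (or per `which` entry).
#' @param which integer indices into `mol$torsions`; defaults to all.
#' @return The molecule with updated coordinates.
#' @export
set_torsions <- function(mol, values, which = seq_along(mol$torsions)) {
  stopifnot(length(values) == length(which))
  xyz <- mol$xyz
  for (q in seq_along(which)) {
    t <- mol$torsions[[which[q]]]
    i <- t[1]; j <- t[2]; k <- t[3]; l <- t[4]
    cur <- dihedral_angle(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ])
    # rotating the far side about j->k by +x decreases the signed dihedral
    delta <- (cur - values[q]) * pi / 180
    axis <- xyz[k, ] - xyz[j, ]
    axis <- axis / sqrt(sum(axis^2))
    moving <- .torsion_side(nrow(xyz), mol$bonds, j, k)
    R <- .axis_angle_matrix(axis, delta)
    piv <- xyz[k, ]
    xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, piv) %*% t(R), 2, piv, "+")
  }
  mol$xyz <- sweep(xyz, 2, colMeans(xyz))
  mol
}

# atoms reachable from k when bond j-k is cut (excluding j's side)
.torsion_side <- function(n, bonds, j, k) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i1 <- bonds[b, 1]; i2 <- bonds[b, 2]
    if ((i1 == j && i2 == k) || (i1 == k && i2 == j)) next
    adj[[i1]] <- c(adj[[i1]], i2); adj[[i2]] <- c(adj[[i2]], i1)
  }
  seen <- logical(n); queue <- k; seen[k] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen & seq_len(n) != k) -> rest
  c(rest)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 numeric vectors.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

.axis_angle_matrix <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         3, 3, byrow = TRUE)
}

# ---- Unit cell --------------------------------------------------------------

#' Create a unit cell
#'
#' @param a,b,c cell lengths in angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `ccs_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("invalid cell: lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "ccs_cell")
  M <- cell_matrix(cell)
  if (!is.finite(det(M)) || det(M) <= 0)
    stop("invalid cell: metric tensor not positive-definite")
  cell
}

#' Lattice-vector matrix of a cell
#'
#' Rows are the lattice vectors in the standard crystallographic frame:
#' a along x, b in the x-y plane, right-handed.
#'
#' @param cell a [unit_cell()].
#' @return 3 x 3 numeric matrix (angstrom).
#' @export
cell_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("invalid cell: metric tensor not positive-definite")
  rbind(c(cell$a, 0, 0),
        c(cell$b * cg, cell$b * sg, 0),
        c(cx, cy, sqrt(cz2)))
}

#' Unit-cell volume
#'
#' Computed as the square root of the metric-tensor determinant; for a
#' monoclinic cell this reduces to a*b*c*sin(beta).
#'
#' @param cell a [unit_cell()].
#' @return Volume in cubic angstrom.
#' @export
cell_volume <- function(cell) {
  M <- cell_matrix(cell)
  g <- M %*% t(M)
  v2 <- det(g)
  if (v2 <= 0) stop("invalid cell: metric tensor not positive-definite")
  sqrt(v2)
}

#' Convert between fractional and Cartesian coordinates
#'
#' @param cell a [unit_cell()].
#' @param points numeric n x 3 matrix (or length-3 vector) of positions.
#' @param direction `"to-fractional"` or `"to-Cartesian"`.
#' @return n x 3 matrix of converted positions.
#' @export
transform_coordinates <- function(cell, points,
                                  direction = c("to-fractional", "to-Cartesian")) {
  direction <- match.arg(direction)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  M <- cell_matrix(cell)
  if (direction == "to-Cartesian") points %*% M else points %*% solve(M)
}

#' @export
print.ccs_cell <- function(x, ...) {
  cat(sprintf("<cell> a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

# ---- Space group ------------------------------------------------------------

#' Create a space group from explicit operators or a Hermann-Mauguin symbol
#'
#' Operators are given as `"x,y,z"`-style triplets (rotation part must be a
#' signed permutation-like integer matrix; translations are fractions).
#' The operator set is checked for closure under composition modulo lattice
#' translations and must contain the identity.
#'
#' @param symbol Hermann-Mauguin symbol (e.g. `"P21/c"`). If `ops` is NULL the
#'   symbol is looked up in the built-in table ([spacegroup_table()]).
#' @param ops optional character vector of xyz operator triplets.
#' @return An object of class `ccs_spacegroup` with fields `symbol`,
#'   `ops` (list of `list(R, t)`), `n_ops` and `system`.
#' @export
space_group <- function(symbol, ops = NULL) {
  if (is.null(ops)) {
    tab <- spacegroup_table()
    key <- .normalize_sg_symbol(symbol)
    if (!key %in% names(tab))
      stop("unknown space-group symbol '", symbol, "'; known: ",
           paste(names(tab), collapse = ", "))
    entry <- tab[[key]]
    ops <- entry$xyz
    system <- entry$system
  } else {
    system <- "triclinic"
  }
  parsed <- lapply(ops, parse_xyz_op)
  if (!.ops_closed(parsed))
    stop("invalid space group: operator set not closed under composition")
  structure(list(symbol = symbol, ops = parsed, n_ops = length(parsed),
                 system = system, xyz = vapply(parsed, format_xyz_op, "")),
            class = "ccs_spacegroup")
}

.normalize_sg_symbol <- function(s) toupper(gsub("[ _]", "", s))

#' Built-in space-group operator table
#'
#' General-position operators for a default set of space groups that dominate
#' organic crystal statistics. The set is configurable: any group can be used
#' by passing explicit operators to [space_group()].
#'
#' @return Named list: each entry has `xyz` (operator triplets) and `system`.
#' @export
spacegroup_table <- function() {
  sg <- function(system, ...) list(xyz = c(...), system = system)
  list(
    "P1"   = sg("triclinic", "x,y,z"),
    "P-1"  = sg("triclinic", "x,y,z", "-x,-y,-z"),
    "P21"  = sg("monoclinic", "x,y,z", "-x,y+1/2,-z"),
    "P21/C" = sg("monoclinic", "x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z",
                 "x,-y+1/2,z+1/2"),
    "P21/N" = sg("monoclinic", "x,y,z", "-x+1/2,y+1/2,-z+1/2", "-x,-y,-z",
                 "x+1/2,-y+1/2,z+1/2"),
    "C2/C" = sg("monoclinic", "x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
                "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2", "-x+1/2,-y+1/2,-z",
                "x+1/2,-y+1/2,z+1/2"),
    "P212121" = sg("orthorhombic", "x,y,z", "-x+1/2,-y,z+1/2",
                   "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
    "PCA21" = sg("orthorhombic", "x,y,z", "-x,-y,z+1/2", "-x+1/2,y,z+1/2",
                 "x+1/2,-y,z"),
    "PNA21" = sg("orthorhombic", "x,y,z", "-x,-y,z+1/2", "-x+1/2,y+1/2,z+1/2",
                 "x+1/2,-y+1/2,z"),
    "PBCA" = sg("orthorhombic", "x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z",
                "-x,y+1/2,-z+1/2", "-x,-y,-z", "x+1/2,y,-z+1/2",
                "-x+1/2,y+1/2,z", "x,-y+1/2,z+1/2"),
    "PBCN" = sg("orthorhombic", "x,y,z", "-x+1/2,-y+1/2,z+1/2",
                "x+1/2,-y+1/2,-z", "-x,y,-z+1/2", "-x,-y,-z",
                "x+1/2,y+1/2,-z+1/2", "-x+1/2,y+1/2,z", "x,-y,z+1/2"),
    "C2"   = sg("monoclinic", "x,y,z", "-x,y,-z", "x+1/2,y+1/2,z",
                "-x+1/2,y+1/2,-z"),
    "CC"   = sg("monoclinic", "x,y,z", "x,-y,z+1/2", "x+1/2,y+1/2,z",
                "x+1/2,-y+1/2,z+1/2"),
    "P21/M" = sg("monoclinic", "x,y,z", "-x,y+1/2,-z", "-x,-y,-z",
                 "x,-y+1/2,z"),
    "PNMA" = sg("orthorhombic", "x,y,z", "-x+1/2,-y,z+1/2",
                "x+1/2,-y+1/2,-z+1/2", "-x,y+1/2,-z", "-x,-y,-z",
                "x+1/2,y,-z+1/2", "-x+1/2,y+1/2,z+1/2", "x,-y+1/2,z")
  )
}

#' Parse an xyz symmetry operator triplet
#' @param s string like `"-x+1/2,y,z+1/2"`.
#' @return `list(R = 3x3 integer rotation part, t = length-3 translation)`.
#' @export
parse_xyz_op <- function(s) {
  parts <- strsplit(gsub(" ", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed operator triplet: ", s)
  R <- matrix(0L, 3, 3); tvec <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[terms != ""]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      if (term %in% c("x", "y", "z")) {
        R[r, match(term, c("x", "y", "z"))] <- sign
      } else if (grepl("/", term)) {
        num <- as.numeric(strsplit(term, "/")[[1]])
        tvec[r] <- tvec[r] + sign * num[1] / num[2]
      } else {
        tvec[r] <- tvec[r] + sign * as.numeric(term)
      }
    }
  }
  list(R = R, t = tvec %% 1)
}

#' Format a parsed operator back to an xyz triplet
#' @param op `list(R, t)` as from [parse_xyz_op()].
#' @return Character triplet.
#' @export
format_xyz_op <- function(op) {
  axes <- c("x", "y", "z")
  rows <- character(3)
  for (r in 1:3) {
    s <- ""
    for (cc in 1:3) {
      if (op$R[r, cc] == 1) s <- paste0(s, "+", axes[cc])
      if (op$R[r, cc] == -1) s <- paste0(s, "-", axes[cc])
    }
    tv <- op$t[r] %% 1
    if (abs(tv) > 1e-9) {
      fr <- .as_fraction(tv)
      s <- paste0(s, "+", fr)
    }
    s <- sub("^\\+", "", s)
    rows[r] <- s
  }
  paste(rows, collapse = ",")
}

.as_fraction <- function(x) {
  for (d in c(2, 3, 4, 6)) {
    n <- x * d
    if (abs(n - round(n)) < 1e-9) return(paste0(round(n), "/", d))
  }
  format(x)
}

.ops_closed <- function(ops) {
  key <- function(R, t) paste(c(R, round((t %% 1) * 12)), collapse = ",")
  keys <- vapply(ops, function(o) key(o$R, o$t), "")
  if (!any(vapply(ops, function(o) all(o$R == diag(3)) && all(abs(o$t %% 1) < 1e-9), TRUE)))
    return(FALSE)
  for (o1 in ops) for (o2 in ops) {
    R <- o1$R %*% o2$R
    t <- (o1$R %*% o2$t + o1$t) %% 1
    if (!key(R, t) %in% keys) return(FALSE)
  }
  TRUE
}

#' @export
print.ccs_spacegroup <- function(x, ...) {
  cat("<space group>", x$symbol, "(", x$n_ops, "operators,", x$system, ")\n")
  invisible(x)
}

# ---- Crystal structure ------------------------------------------------------

#' Create a crystal structure
#'
#' A structure is a unit cell, a space group and an asymmetric unit given as a
#' list of molecule placements. Each placement positions a molecule by its
#' centroid (fractional coordinates, wrapped to `[0, 1)`), a unit orientation
#' quaternion and, for flexible molecules, torsion values in degrees.
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] (or symbol, looked up in the built-in table).
#' @param placements list of `list(molecule, frac, quat, torsions)`; `quat`
#'   defaults to the identity and `torsions` to the reference conformation.
#' @param energy optional named list of energy annotations (kJ/mol per
#'   asymmetric-unit formula).
#' @return An object of class `ccs_structure`.
#' @export
crystal_structure <- function(cell, sg, placements, energy = NULL) {
  if (is.character(sg)) sg <- space_group(sg)
  placements <- lapply(placements, function(p) {
    if (is.null(p$quat)) p$quat <- c(1, 0, 0, 0)
    qn <- sqrt(sum(p$quat^2))
    if (abs(qn - 1) > 1e-10) p$quat <- p$quat / qn
    if (is.null(p$torsions)) p$torsions <- numeric(0)
    p$frac <- as.numeric(p$frac) %% 1
    p
  })
  ids <- vapply(placements, function(p) p$molecule$id, "")
  structure(list(cell = cell, sg = sg, asym = placements,
                 z_prime = as.numeric(table(ids)[unique(ids)]),
                 energy = energy),
            class = "ccs_structure")
}

#' @export
print.ccs_structure <- function(x, ...) {
  cat("<crystal structure>", x$sg$symbol, "with", length(x$asym),
      "molecule(s) in the asymmetric unit\n")
  print(x$cell)
  if (!is.null(x$energy$U_total))
    cat(sprintf("  U_total = %.4f kJ/mol per formula\n", x$energy$U_total))
  invisible(x)
}

.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# conformer geometry of a placement: torsions applied, rotated by quaternion,
# centred on the origin (row-per-atom Cartesian offsets)
.placement_local_coords <- function(p) {
  mol <- p$molecule
  if (length(p$torsions) > 0) mol <- set_torsions(mol, p$torsions)
  R <- .quat_to_mat(p$quat)
  mol$xyz %*% t(R)
}

#' Expand a structure's asymmetric unit to the full unit cell
#'
#' Applies every space-group operator to every asymmetric-unit molecule.
#' Molecules are mapped whole: the operator acts on the centroid (wrapped to
#' `[0, 1)`) and on the atom offsets around it, so no molecule is split
#' across cell boundaries.
#'
#' @param structure a [crystal_structure()].
#' @return List of molecule images, each `list(component, image, elements,
#'   xyz, charges)` with `xyz` Cartesian (angstrom). The number of images is
#'   `n_ops x` the number of asymmetric-unit molecules.
#' @export
expand_symmetry <- function(structure) {
  M <- cell_matrix(structure$cell)
  Minv <- solve(M)
  out <- list()
  idx <- 0L
  for (ci in seq_along(structure$asym)) {
    p <- structure$asym[[ci]]
    local <- .placement_local_coords(p)
    for (oi in seq_along(structure$sg$ops)) {
      op <- structure$sg$ops[[oi]]
      fc <- (as.numeric(op$R %*% p$frac) + op$t) %% 1
      ctr_cart <- as.numeric(matrix(fc, 1) %*% M)
      # operator's Cartesian action on offsets (row vectors): Minv' R' M'... via
      # cart' = cart %*% (Minv %*% t(R) %*% M) since frac rows transform as f %*% t(R)
      Q <- Minv %*% t(op$R) %*% M
      atoms <- local %*% Q
      atoms <- sweep(atoms, 2, ctr_cart, "+")
      idx <- idx + 1L
      out[[idx]] <- list(component = ci, image = oi,
                         elements = p$molecule$elements,
                         xyz = atoms, charges = p$molecule$charges,
                         molecule = p$molecule)
    }
  }
  out
}

# flat per-atom arrays for the full cell (used by the energy kernels)
.cell_contents <- function(structure) {
  images <- expand_symmetry(structure)
  xyz <- do.call(rbind, lapply(images, `[[`, "xyz"))
  list(xyz = xyz,
       charges = unlist(lapply(images, `[[`, "charges")),
       elements = unlist(lapply(images, `[[`, "elements")),
       mol_id = rep(seq_along(images),
                    vapply(images, function(im) length(im$elements), 1L)),
       n_images = length(images))
}

# ---- element data -----------------------------------------------------------

#' Atomic masses and covalent radii for common elements
#' @return data.frame with columns element, mass (g/mol), r_cov (angstrom).
#' @export
element_data <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "F", "S", "Cl", "Na", "Cs", "X", "Y"),
    mass = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06, 35.45,
             22.990, 132.905, 15.0, 15.0),
    r_cov = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.05, 1.02, 1.66, 2.44, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

.element_lookup <- function(elements, what) {
  ed <- element_data()
  m <- match(elements, ed$element)
  if (anyNA(m)) {
    # unknown elements fall back to mid-weight defaults
    vals <- ed[[what]][m]
    vals[is.na(vals)] <- if (what == "mass") 30 else 1.0
    return(vals)
  }
  ed[[what]][m]
}

#' Crystal density
#' @param structure a [crystal_structure()].
#' @return Density in g/cm^3 of the symmetry-expanded cell.
#' @export
crystal_density <- function(structure) {
  cont <- .cell_contents(structure)
  mass <- sum(.element_lookup(cont$elements, "mass"))
  # g/mol / (A^3 * N_A) -> g/cm^3 ; 1 A^3 = 1e-24 cm^3
  mass / (cell_volume(structure$cell) * 0.602214076)
}
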