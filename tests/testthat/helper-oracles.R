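# Shared independent oracles and small builders used across test files.

# Evjen direct summation of an ionic lattice's electrostatic energy:
# neutral-cube summation with fractional weights for shared boundary sites.
# Returns the Madelung constant referred to the nearest-neighbour distance d.
evjen_madelung <- function(structure, d, shells = 10) {
  cont <- cocryscreen:::.cell_contents(structure)
  M <- cell_matrix(structure$cell)
  n_pairs <- sum(cont$charges > 0)
  E <- 0
  for (i in seq_along(cont$charges)) {
    qi <- cont$charges[i]
    for (na in -shells:shells) for (nb in -shells:shells) for (nc in -shells:shells) {
      w <- prod(ifelse(abs(c(na, nb, nc)) == shells, 0.5, 1))
      shift <- na * M[1, ] + nb * M[2, ] + nc * M[3, ]
      for (j in seq_along(cont$charges)) {
        if (na == 0 && nb == 0 && nc == 0 && i == j) next
        r <- sqrt(sum((cont$xyz[j, ] + shift - cont$xyz[i, ])^2))
        E <- E + 0.5 * w * qi * cont$charges[j] / r
      }
    }
  }
  -E * d / n_pairs
}

# vectorised Evjen sum (much faster); same construction as above
evjen_madelung_fast <- function(structure, d, shells = 12) {
  cont <- cocryscreen:::.cell_contents(structure)
  M <- cell_matrix(structure$cell)
  n_pairs <- sum(cont$charges > 0)
  grid <- expand.grid(na = -shells:shells, nb = -shells:shells,
                      nc = -shells:shells)
  w <- apply(abs(grid) == shells, 1, function(z) prod(ifelse(z, 0.5, 1)))
  shifts <- as.matrix(grid) %*% M
  E <- 0
  N <- length(cont$charges)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      r <- sqrt((shifts[, 1] + cont$xyz[j, 1] - cont$xyz[i, 1])^2 +
                (shifts[, 2] + cont$xyz[j, 2] - cont$xyz[i, 2])^2 +
                (shifts[, 3] + cont$xyz[j, 3] - cont$xyz[i, 3])^2)
      home <- abs(shifts[, 1]) + abs(shifts[, 2]) + abs(shifts[, 3]) < 1e-9
      keep <- !(home & i == j)
      E <- E + 0.5 * cont$charges[i] * cont$charges[j] *
        sum(w[keep] / r[keep])
    }
  }
  -E * d / n_pairs
}

# Full direct-summation Madelung oracle: neutral-cube Evjen sum, plus the
# standard cell second-moment (trace quadrupole) correction that connects a
# shape-dependent direct sum to the tinfoil Ewald limit, plus Richardson
# extrapolation in 1/L^2 (the observed convergence order of the cube sum).
oracle_madelung <- function(structure, d, L = c(10, 12)) {
  corrected <- function(Lk) {
    m_cube <- evjen_madelung_fast(structure, d, Lk)
    cont <- cocryscreen:::.cell_contents(structure)
    V <- cell_volume(structure$cell)
    qr2 <- sum(cont$charges * rowSums(cont$xyz^2))
    m_cube + (2 * pi / (3 * V)) * (-qr2) * d
  }
  f1 <- corrected(L[1]); f2 <- corrected(L[2])
  f2 + (f2 - f1) * (1 / L[2]^2) / ((1 / L[1]^2) - (1 / L[2]^2))
}

# a 4-atom chain molecule with one declared torsion (1-2-3-4)
make_chain_molecule <- function(id = "chain", charges = c(0.1, -0.1, -0.1, 0.1)) {
  xyz <- rbind(c(-1.5, 0.9, 0), c(-0.75, 0, 0), c(0.75, 0, 0), c(1.5, 0.9, 0.0))
  molecule(id, c("C", "C", "C", "C"), xyz,
           bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
           charges = charges, torsions = list(c(1L, 2L, 3L, 4L)))
}

# expand a structure into an equivalent explicit P1 description
as_p1_structure <- function(structure) {
  images <- expand_symmetry(structure)
  M <- cell_matrix(structure$cell)
  placements <- lapply(images, function(im) {
    ctr <- colMeans(im$xyz)
    mol <- molecule(paste0(im$molecule$id, "_img"), im$elements,
                    sweep(im$xyz, 2, ctr), bonds = im$molecule$bonds,
                    charges = im$charges)
    list(molecule = mol,
         frac = as.numeric(ctr %*% solve(M)) %% 1,
         quat = c(1, 0, 0, 0))
  })
  crystal_structure(structure$cell, "P1", placements)
}

# independent Kabsch superposition used as the RMSD oracle
oracle_kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A0 - B0 %*% t(R))^2)))
}
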