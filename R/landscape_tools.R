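# Duplicate detection by COMPACK-style packing similarity (RMSD over an
# n-molecule coordination cluster), landscape assembly, and global-minimum
# extraction.

#' Clustering configuration for packing similarity
#'
#' @param n cluster size in molecules (default 15).
#' @param rmsd_threshold heavy-atom RMSD below which two packings match (A).
#' @param energy_tol energy pre-filter: only pairs within this many kJ/mol
#'   are compared.
#' @param dist_tol centroid-distance tolerance for molecule matching
#'   (fraction, default 0.2 = 20 percent).
#' @param angle_tol orientation tolerance in degrees for molecule matching.
#' @param beam beam width of the correspondence search.
#' @return An object of class `ccs_clusterconfig`.
#' @export
cluster_config <- function(n = 15, rmsd_threshold = 1.0, energy_tol = 1.0,
                           dist_tol = 0.2, angle_tol = 20, beam = 4) {
  stopifnot(n >= 1, rmsd_threshold > 0, energy_tol > 0)
  structure(list(n = as.integer(n), rmsd_threshold = rmsd_threshold,
                 energy_tol = energy_tol, dist_tol = dist_tol,
                 angle_tol = angle_tol, beam = as.integer(beam)),
            class = "ccs_clusterconfig")
}

# all molecule images in a supercell around the home cell, with centroids
.supercell_molecules <- function(structure, reach = 2L) {
  images <- expand_symmetry(structure)
  M <- cell_matrix(structure$cell)
  out <- list()
  k <- 0L
  for (na in -reach:reach) for (nb in -reach:reach) for (nc in -reach:reach) {
    shift <- na * M[1, ] + nb * M[2, ] + nc * M[3, ]
    for (im in images) {
      k <- k + 1L
      heavy <- im$elements != "H"
      xyz <- sweep(im$xyz, 2, shift, "+")
      out[[k]] <- list(component = im$component, image = im$image,
                       xyz = xyz[heavy, , drop = FALSE],
                       elements = im$elements[heavy],
                       centroid = colMeans(xyz[heavy, , drop = FALSE]))
    }
  }
  out
}

# n-molecule coordination cluster around a chosen central molecule
.coordination_cluster <- function(mols, central_idx, n) {
  ctr <- mols[[central_idx]]$centroid
  d <- vapply(mols, function(m) sqrt(sum((m$centroid - ctr)^2)), 0)
  ord <- order(d)
  sel <- ord[seq_len(min(n, length(ord)))]
  list(mols = mols[sel], d = d[sel])
}

# Kabsch superposition: rotation R and translation mapping B onto A (rows)
.kabsch <- function(A, B, allow_inversion = FALSE) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, if (allow_inversion) 1 else d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, shift_a = ca, shift_b = cb,
       apply = function(X) sweep(sweep(X, 2, cb) %*% t(R), 2, ca, "+"))
}

.rmsd_of <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Packing similarity of two crystal structures
#'
#' Builds an `n`-molecule coordination cluster around a central molecule in
#' each structure, searches molecule-to-molecule correspondences within the
#' distance tolerance (beam-limited greedy matching over symmetry-inequivalent
#' central-molecule choices in `s2`, with and without inversion), and returns
#' the heavy-atom RMSD of the best rigid superposition covering all `n`
#' molecules. Hydrogen atoms are excluded.
#'
#' @param s1,s2 [crystal_structure()] objects of the same composition.
#' @param cfg a [cluster_config()].
#' @return RMSD in angstrom, or `NA_real_` if no correspondence covers the
#'   full cluster (no-match). The result carries attribute `complete`
#'   indicating whether the beam search exhausted all central choices.
#' @export
packing_rmsd <- function(s1, s2, cfg = cluster_config()) {
  comp1 <- sort(vapply(s1$asym, function(p) p$molecule$id, ""))
  comp2 <- sort(vapply(s2$asym, function(p) p$molecule$id, ""))
  if (!identical(comp1, comp2))
    stop("packing_rmsd requires structures of the same composition")
  # the correspondence search is directional; symmetrise over both orders
  r12 <- .packing_rmsd_dir(s1, s2, cfg)
  r21 <- .packing_rmsd_dir(s2, s1, cfg)
  cand <- list(r12, r21)
  vals <- vapply(cand, function(x) if (is.na(x)) Inf else as.numeric(x), 0)
  if (all(!is.finite(vals))) {
    out <- NA_real_
  } else {
    pick <- cand[[which.min(vals)]]
    out <- as.numeric(pick)
    attr(out, "matched") <- attr(pick, "matched")
  }
  attr(out, "complete") <- TRUE
  out
}

.packing_rmsd_dir <- function(s1, s2, cfg) {
  mols1 <- .supercell_molecules(s1)
  mols2 <- .supercell_molecules(s2)
  # central molecule of s1: home-cell image of component 1, first operator,
  # taken from the copy closest to the supercell centroid for stability
  all_ctr1 <- colMeans(do.call(rbind, lapply(mols1, `[[`, "centroid")))
  cand1 <- which(vapply(mols1, function(m)
    m$component == 1L && m$image == 1L, TRUE))
  c1 <- cand1[which.min(vapply(mols1[cand1], function(m)
    sum((m$centroid - all_ctr1)^2), 0))]
  clu1 <- .coordination_cluster(mols1, c1, cfg$n)

  all_ctr2 <- colMeans(do.call(rbind, lapply(mols2, `[[`, "centroid")))
  # symmetry-inequivalent central choices in s2: one per operator image of
  # the same component, nearest copy to the supercell centre
  best <- NA_real_
  images2 <- unique(vapply(mols2, function(m)
    if (m$component == 1L) m$image else NA_integer_, 1L))
  images2 <- images2[!is.na(images2)]
  for (img in images2) {
    cand2 <- which(vapply(mols2, function(m)
      m$component == 1L && m$image == img, TRUE))
    c2 <- cand2[which.min(vapply(mols2[cand2], function(m)
      sum((m$centroid - all_ctr2)^2), 0))]
    # wider pool than n: the partner of a shell-boundary molecule in s1 can
    # lie just outside the n-shell of s2
    clu2 <- .coordination_cluster(mols2, c2, cfg$n + 12L)
    for (inv in c(FALSE, TRUE)) {
      r <- .match_clusters(clu1, clu2, cfg, inv)
      if (!is.na(r) && (is.na(best) || as.numeric(r) < as.numeric(best)))
        best <- r
    }
  }
  attr(best, "complete") <- TRUE
  best
}

# align on central molecules, then greedily map remaining molecules
.match_clusters <- function(clu1, clu2, cfg, inv) {
  m1 <- clu1$mols; m2 <- clu2$mols
  if (length(m2) < length(m1)) return(NA_real_)
  if (inv) {
    # point inversion of the whole cluster through the central centroid
    ctr <- m2[[1]]$centroid
    X2 <- lapply(m2, function(m)
      list(xyz = sweep(-sweep(m$xyz, 2, ctr), 2, ctr, "+"),
           component = m$component))
  } else {
    X2 <- lapply(m2, function(m) list(xyz = m$xyz, component = m$component))
  }
  fit0 <- .kabsch(m1[[1]]$xyz, X2[[1]]$xyz)
  moved <- lapply(X2, function(m) fit0$apply(m$xyz))
  ctr1 <- lapply(m1, `[[`, "centroid")
  ctrm <- lapply(moved, colMeans)
  used <- logical(length(m2))
  used[1] <- TRUE
  pairs <- list(list(1L, 1L))
  ok <- TRUE
  for (i in seq_along(m1)[-1]) {
    di <- clu1$d[i]
    tol <- max(0.75, cfg$dist_tol * di)
    cands <- which(!used & vapply(X2, `[[`, 1L, "component") == m1[[i]]$component)
    if (!length(cands)) { ok <- FALSE; break }
    dd <- vapply(cands, function(j) sqrt(sum((ctr1[[i]] - ctrm[[j]])^2)), 0)
    ordc <- cands[order(dd)]
    ordd <- sort(dd)
    hit <- NA_integer_
    for (b in seq_len(min(cfg$beam, length(ordc)))) {
      if (ordd[b] > tol) break
      hit <- ordc[b]; break
    }
    if (is.na(hit)) { ok <- FALSE; break }
    used[hit] <- TRUE
    pairs[[length(pairs) + 1]] <- list(i, hit)
  }
  if (!ok) return(NA_real_)
  A <- do.call(rbind, lapply(pairs, function(p) m1[[p[[1]]]]$xyz))
  B <- do.call(rbind, lapply(pairs, function(p) X2[[p[[2]]]]$xyz))
  fit <- .kabsch(A, B)
  out <- .rmsd_of(A, fit$apply(B))
  attr(out, "matched") <- list(A = A, B = B)
  out
}

#' Cluster a list of minima into a landscape of unique structures
#'
#' Greedy pass in ascending energy order: an entry is a duplicate of an
#' earlier keeper iff their energies differ by at most the pre-filter
#' tolerance AND their packing RMSD is at or below the match threshold; the
#' lower-energy member is kept. Idempotent.
#'
#' @param minima list of `ccs_minimum` objects sharing one composition.
#' @param cfg a [cluster_config()].
#' @param composition label stored on the landscape.
#' @return An object of class `ccs_landscape` with entries sorted ascending
#'   by `U_total`.
#' @export
cluster_landscape <- function(minima, cfg = cluster_config(),
                              composition = NULL) {
  if (length(minima) == 0)
    return(structure(list(composition = composition, entries = list(),
                          settings = cfg), class = "ccs_landscape"))
  if (is.null(composition)) {
    ids <- vapply(minima[[1]]$structure$asym, function(p) p$molecule$id, "")
    composition <- paste(ids, collapse = "+")
  }
  E <- vapply(minima, function(m) m$value, 0)
  ord <- order(E)
  keepers <- list()
  for (i in ord) {
    dup <- FALSE
    for (k in keepers) {
      if (abs(minima[[i]]$value - k$value) > cfg$energy_tol) next
      r <- tryCatch(packing_rmsd(k$structure, minima[[i]]$structure, cfg),
                    error = function(e) NA_real_)
      if (!is.na(r) && r <= cfg$rmsd_threshold) { dup <- TRUE; break }
    }
    if (!dup) keepers[[length(keepers) + 1]] <- minima[[i]]
  }
  structure(list(composition = composition, entries = keepers,
                 settings = cfg), class = "ccs_landscape")
}

#' @export
print.ccs_landscape <- function(x, ...) {
  cat("<landscape>", x$composition %||% "?", ":", length(x$entries),
      "unique minima\n")
  if (length(x$entries))
    cat(sprintf("  global minimum U_total = %.4f kJ/mol\n",
                x$entries[[1]]$value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a landscape (energy vs density)
#' @param x a `ccs_landscape`.
#' @param ... unused.
#' @return data.frame with one row per unique minimum.
#' @export
as.data.frame.ccs_landscape <- function(x, ...) {
  if (length(x$entries) == 0)
    return(data.frame(rank = integer(0), U_total = numeric(0),
                      U_exp6 = numeric(0), U_elec = numeric(0),
                      dU_intra = numeric(0), density = numeric(0),
                      spacegroup = character(0)))
  data.frame(
    rank = seq_along(x$entries),
    U_total = vapply(x$entries, function(e) e$value, 0),
    U_exp6 = vapply(x$entries, function(e) e$energy$U_exp6, 0),
    U_elec = vapply(x$entries, function(e) e$energy$U_electrostatic, 0),
    dU_intra = vapply(x$entries, function(e) e$energy$dU_intra, 0),
    density = vapply(x$entries, function(e) e$density %||%
                       crystal_density(e$structure), 0),
    spacegroup = vapply(x$entries, function(e) e$structure$sg$symbol, "")
  )
}

#' Save a landscape as a JSON index plus per-structure CIF files
#'
#' @param landscape a `ccs_landscape`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(landscape)
  cifs <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    cifs[i] <- sprintf("structure_%03d.cif", i)
    write_cif(landscape$entries[[i]]$structure, file.path(dir, cifs[i]))
  }
  df$cif_path <- cifs
  idx <- list(composition = landscape$composition,
              settings = unclass(landscape$settings),
              entries = df)
  jsonlite::write_json(idx, file.path(dir, "landscape.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(df[, c("rank", "U_total", "density")],
                   file.path(dir, "energy_density.csv"), row.names = FALSE)
  invisible(dir)
}

#' Global minimum of a landscape
#'
#' Returns the first (lowest-energy) entry. Under the `"experimental"` policy
#' an externally supplied structure competes with the CSP best and whichever
#' has the lower lattice energy is returned.
#'
#' @param landscape a `ccs_landscape`.
#' @param experimental optional `list(structure, U_total)` (or a
#'   `ccs_minimum`) for an experimentally determined form.
#' @param policy `"csp"` (default) or `"experimental"`.
#' @return `list(structure, U_total, source)`.
#' @export
global_minimum <- function(landscape, experimental = NULL,
                           policy = c("csp", "experimental")) {
  policy <- match.arg(policy)
  if (length(landscape$entries) == 0)
    stop("empty landscape: widen the search (more candidates or space groups)")
  best <- landscape$entries[[1]]
  out <- list(structure = best$structure, U_total = best$value, source = "csp")
  if (policy == "experimental" && !is.null(experimental)) {
    ue <- experimental$U_total %||% experimental$value
    if (ue < out$U_total)
      out <- list(structure = experimental$structure, U_total = ue,
                  source = "experimental")
  }
  out
}
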