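# Crystal data model: cell metrics, coordinate transforms, space-group
# symmetry and structure expansion.

test_that("cell volume matches the metric-tensor determinant and known cells", {
  # unit cube
  expect_equal(cell_volume(unit_cell(1, 1, 1)), 1.0, tolerance = 1e-12)

  # indexed monoclinic cell of a known 2:1 cocrystal phase
  v <- cell_volume(unit_cell(27.0723, 5.1939, 24.1059, 90, 94.343, 90))
  expect_lt(abs(v - 3379.80), 0.1)
  # monoclinic closed form a*b*c*sin(beta)
  expect_equal(v, 27.0723 * 5.1939 * 24.1059 * sin(94.343 * pi / 180),
               tolerance = 1e-10)

  # random triclinic cells against an independent metric-tensor oracle
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 3, 20); b <- runif(1, 3, 20); cc <- runif(1, 3, 20)
    al <- runif(1, 70, 110); be <- runif(1, 70, 110); ga <- runif(1, 70, 110)
    cell <- tryCatch(unit_cell(a, b, cc, al, be, ga), error = function(e) NULL)
    if (is.null(cell)) next
    d2r <- pi / 180
    G <- matrix(c(a^2, a * b * cos(ga * d2r), a * cc * cos(be * d2r),
                  a * b * cos(ga * d2r), b^2, b * cc * cos(al * d2r),
                  a * cc * cos(be * d2r), b * cc * cos(al * d2r), cc^2), 3, 3)
    expect_equal(cell_volume(cell), sqrt(det(G)), tolerance = 1e-9)
    expect_gt(cell_volume(cell), 0)
    # cyclic relabeling invariance
    cell2 <- unit_cell(b, cc, a, be, ga, al)
    expect_equal(cell_volume(cell2), cell_volume(cell), tolerance = 1e-9)
  }
})

test_that("invalid cells are rejected", {
  expect_error(unit_cell(-1, 1, 1), "positive")
  expect_error(unit_cell(1, 1, 1, alpha = 190), "angles")
  # angle combination with no positive-definite metric
  expect_error(unit_cell(1, 1, 1, 150, 150, 150), "positive-definite")
})

test_that("coordinate transforms are exact inverses", {
  cell <- unit_cell(8, 10, 12)
  f <- transform_coordinates(cell, c(4, 5, 6), "to-fractional")
  expect_equal(as.numeric(f), c(0.5, 0.5, 0.5), tolerance = 1e-12)

  mono <- unit_cell(7, 9, 11, beta = 103)
  cart <- transform_coordinates(mono, c(1, 0, 0), "to-Cartesian")
  expect_equal(sqrt(sum(cart^2)), 7, tolerance = 1e-10)

  set.seed(7)
  tri <- unit_cell(6.2, 7.7, 9.1, 81, 95, 101)
  pts <- matrix(runif(300, -20, 20), ncol = 3)
  back <- transform_coordinates(tri,
            transform_coordinates(tri, pts, "to-fractional"), "to-Cartesian")
  expect_lt(max(abs(back - pts)), 1e-10)
})

test_that("space-group table entries form closed groups with the right multiplicity", {
  mult <- c("P1" = 1, "P-1" = 2, "P21" = 2, "P21/c" = 4, "P21/n" = 4,
            "C2/c" = 8, "P212121" = 4, "Pca21" = 4, "Pna21" = 4, "Pbca" = 8,
            "Pbcn" = 8, "C2" = 4, "Cc" = 4, "P21/m" = 4, "Pnma" = 8)
  for (sym in names(mult)) {
    sg <- space_group(sym)
    expect_identical(sg$n_ops, as.integer(mult[[sym]]), label = sym)
  }
  expect_error(space_group("F9/q"), "unknown")
  # a non-closed operator set is rejected
  expect_error(space_group("broken", ops = c("x,y,z", "x+1/4,y,z")),
               "not closed")
  # operator parser round-trips
  op <- parse_xyz_op("-x+1/2,y,z+3/4")
  expect_identical(format_xyz_op(op), "-x+1/2,y,z+3/4")
})

test_that("molecule construction enforces its invariants", {
  expect_error(molecule("m", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        charges = 1), "charge list length")
  expect_error(molecule("m", c("C", "C", "C"),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 5)),
                        bonds = rbind(c(1, 2))), "not connected")
  expect_error(molecule("m", c("C", "C", "C", "C"),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                        bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
                        torsions = list(c(1, 3, 2, 4))), "bonded in chain")
  m <- make_chain_molecule()
  expect_length(m$torsions, 1)
  # coordinates are centred on the centroid
  expect_equal(colMeans(m$xyz), c(0, 0, 0), tolerance = 1e-12)
})

test_that("set_torsions drives the dihedral to the requested value", {
  m <- make_chain_molecule()
  for (target in c(-120, -60, 30, 90, 179)) {
    m2 <- set_torsions(m, target)
    got <- dihedral_angle(m2$xyz[1, ], m2$xyz[2, ], m2$xyz[3, ], m2$xyz[4, ])
    expect_equal(got, target, tolerance = 1e-8)
    # bond lengths preserved by the rotation
    d <- function(x, i, j) sqrt(sum((x[i, ] - x[j, ])^2))
    for (b in 1:3)
      expect_equal(d(m2$xyz, b, b + 1), d(m$xyz, b, b + 1), tolerance = 1e-9)
  }
})

test_that("expand_symmetry produces |operators| x Z' whole-molecule images", {
  mol <- molecule("dimer", c("C", "O"), rbind(c(-0.7, 0, 0), c(0.7, 0, 0)),
                  bonds = rbind(c(1, 2)))
  place <- list(list(molecule = mol, frac = c(0.13, 0.27, 0.41),
                     quat = c(0.9, 0.1, 0.3, findq <- sqrt(1 - 0.9^2 - 0.1^2 - 0.3^2))))
  # P1: output identical to the asymmetric unit
  s1 <- crystal_structure(unit_cell(6, 7, 8, 80, 85, 95), "P1", place)
  im1 <- expand_symmetry(s1)
  expect_length(im1, 1)

  # P21/c: four images
  s2 <- crystal_structure(unit_cell(6, 7, 8, beta = 98), "P21/c", place)
  im2 <- expand_symmetry(s2)
  expect_length(im2, 4)

  # every image preserves the bond length (whole-molecule mapping)
  for (im in im2)
    expect_equal(sqrt(sum((im$xyz[1, ] - im$xyz[2, ])^2)), 1.4,
                 tolerance = 1e-9)

  # Z' = 2: twice as many images
  s3 <- crystal_structure(unit_cell(6, 7, 8, beta = 98), "P21/c",
                          c(place, list(list(molecule = mol,
                                             frac = c(0.6, 0.1, 0.8)))))
  expect_length(expand_symmetry(s3), 8)
})

test_that("P-1 expansion agrees with direct operator application atom by atom", {
  mol <- molecule("dimer", c("N", "N"), rbind(c(-0.55, 0, 0), c(0.55, 0, 0)),
                  bonds = rbind(c(1, 2)))
  cell <- unit_cell(5.5, 6.5, 7.5, 84, 92, 101)
  s <- crystal_structure(cell, "P-1",
                         list(list(molecule = mol, frac = c(0.2, 0.3, 0.4))))
  images <- expand_symmetry(s)
  expect_length(images, 2)
  M <- cell_matrix(cell)
  # oracle: apply each operator to every atom's fractional coordinates
  atom_frac <- sweep(mol$xyz, 2, as.numeric(matrix(c(0.2, 0.3, 0.4), 1) %*% M),
                     "+") %*% solve(M)
  for (k in 1:2) {
    op <- s$sg$ops[[k]]
    oracle <- t(apply(atom_frac, 1, function(f) as.numeric(op$R %*% f + op$t)))
    oracle_cart <- oracle %*% M
    got <- images[[k]]$xyz
    # compare pairwise distances (positions may differ by whole-cell wraps)
    expect_equal(dist(got)[1], dist(oracle_cart)[1], tolerance = 1e-9)
    # and the wrapped centroids agree
    oc <- (colMeans(oracle) %% 1)
    gc <- (as.numeric(colMeans(got) %*% solve(M))) %% 1
    expect_equal(gc, oc, tolerance = 1e-9)
  }
})

test_that("crystal structures normalise quaternions and wrap centroids", {
  mol <- molecule("pt", "C", matrix(0, 1, 3))
  s <- crystal_structure(unit_cell(5, 5, 5), "P1",
                         list(list(molecule = mol, frac = c(1.25, -0.5, 2),
                                   quat = c(2, 0, 0, 0))))
  expect_equal(s$asym[[1]]$frac, c(0.25, 0.5, 0))
  expect_equal(sqrt(sum(s$asym[[1]]$quat^2)), 1, tolerance = 1e-12)
})
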