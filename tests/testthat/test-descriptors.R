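test_that("d_OOP is zero for a planar heme and exact for a shifted iron", {
  ref <- test_ref()
  expect_equal(as.numeric(out_of_plane_displacement(ref)), 0)
  x <- ref$xyz
  x["FE", 3] <- 0.30
  expect_equal(abs(as.numeric(out_of_plane_displacement(x))), 0.30,
               tolerance = 1e-9)
})

test_that("d_OOP uses the least-squares nitrogen plane (symmetric ruffle case)", {
  ref <- test_ref()
  x <- ref$xyz
  ## nitrogens displaced +0.1/-0.1 alternately: centroid plane stays z = 0
  x[c("NA", "NC"), 3] <- 0.1
  x[c("NB", "ND"), 3] <- -0.1
  x["FE", 3] <- 0.25
  expect_equal(abs(as.numeric(out_of_plane_displacement(x))), 0.25,
               tolerance = 1e-9)
})

test_that("d_OOP is rigid-motion invariant and independent of nitrogen labeling", {
  ref <- test_ref()
  x <- ref$xyz
  x["FE", 3] <- 0.22
  moved <- sweep(x %*% t(random_rotation(seed = 14)), 2, c(2, 2, 2), "+")
  expect_equal(abs(as.numeric(out_of_plane_displacement(moved))), 0.22,
               tolerance = 1e-9)
  ## permute the nitrogen labels: magnitude unchanged
  xp <- x
  xp[c("NA", "NB", "NC", "ND"), ] <- x[c("NC", "ND", "NA", "NB"), ]
  expect_equal(abs(as.numeric(out_of_plane_displacement(xp))), 0.22,
               tolerance = 1e-9)
})

test_that("d_OOP sign convention follows the axial-ligand direction when given", {
  ref <- test_ref()
  x <- ref$xyz
  x["FE", 3] <- 0.3
  d_up <- out_of_plane_displacement(x, toward = c(0, 0, 2.3))
  d_dn <- out_of_plane_displacement(x, toward = c(0, 0, -2.3))
  expect_equal(as.numeric(d_up), 0.3, tolerance = 1e-9)
  expect_equal(as.numeric(d_dn), -0.3, tolerance = 1e-9)
  expect_true(attr(d_up, "sign_fixed"))
  expect_false(attr(out_of_plane_displacement(x), "sign_fixed"))
})

test_that("collinear nitrogens raise a degenerate-plane error", {
  x <- test_ref()$xyz
  x["NA", ] <- c(1, 0, 0); x["NB", ] <- c(2, 0, 0)
  x["NC", ] <- c(3, 0, 0); x["ND", ] <- c(4, 0, 0)
  expect_error(out_of_plane_displacement(x), "degenerate plane")
})

test_that("torsion signs follow IUPAC and flip under mirror reflection", {
  skip_if_not_installed("bio3d")
  set.seed(6)
  for (rep in 1:10) {
    pts <- matrix(rnorm(12), 4, 3)
    mine <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    oracle <- bio3d::torsion.xyz(as.vector(t(pts)))
    expect_equal(mine, as.numeric(oracle), tolerance = 1e-6)
    mirrored <- pts %*% diag(c(1, 1, -1))
    flipped <- torsion_angle(mirrored[1, ], mirrored[2, ],
                             mirrored[3, ], mirrored[4, ])
    expect_equal(flipped, -mine, tolerance = 1e-6)
  }
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "collinear")
})

test_that("propionate dihedrals hit their targets and classify up/down", {
  ref <- test_ref(); basis <- test_basis()
  h <- make_distorted_heme(ref = ref, basis = basis)
  for (case in list(c(-90, 90), c(-135.5, 10), c(179, -179))) {
    hp <- add_propionate_stubs(h, case[1], case[2])
    pro <- propionate_dihedrals(hp)
    expect_equal(pro$dihedral1, case[1], tolerance = 1e-6)
    expect_equal(pro$dihedral2, case[2], tolerance = 1e-6)
    expect_identical(pro$orientation1, if (case[1] < 0) "up" else "down")
    expect_identical(pro$orientation2, if (case[2] < 0) "up" else "down")
  }
  ## trans-planar chain: 180 degrees -> "down" under the boundary rule
  hp <- add_propionate_stubs(h, 180, -90)
  expect_equal(abs(propionate_dihedrals(hp)$dihedral1), 180,
               tolerance = 1e-6)
  expect_identical(propionate_dihedrals(hp)$orientation1, "down")
  ## missing sidechain atoms give NA, not an error
  pro0 <- propionate_dihedrals(h)
  expect_true(is.na(pro0$dihedral1) && is.na(pro0$orientation2))
})

test_that("single-sphere SASA matches the closed form", {
  a <- sasa_areas(matrix(0, 1, 3), "C")
  expect_equal(a, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  ## two far-apart atoms are both fully exposed
  b <- sasa_areas(matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE),
                  c("N", "O"))
  expect_equal(b, 4 * pi * (c(1.55, 1.52) + 1.4)^2, tolerance = 1e-6)
  ## a symmetric dimer buries both partners equally
  ## equal up to the point-lattice discretization (the golden-spiral
  ## lattice is not reflection-symmetric)
  d <- sasa_areas(matrix(c(0, 0, 0, 2.0, 0, 0), 2, 3, byrow = TRUE),
                  c("C", "C"))
  expect_equal(d[1], d[2], tolerance = 5e-3)
  expect_lt(d[1], 4 * pi * 3.1^2)
})

test_that("coverage is 0 in isolation and monotone as occluders accumulate", {
  ref <- test_ref(); basis <- test_basis()
  h <- make_distorted_heme(ref = ref, basis = basis)
  expect_equal(coverage(h), 0)
  expect_equal(coverage(h, data.frame(element = character(), x = numeric(),
                                      y = numeric(), z = numeric())), 0)
  fx <- make_complex_fixture(h, shell_radius = 6.0, shell_n = 400)
  shell <- fx$atoms
  sizes <- c(50, 150, 400)
  cvg <- vapply(sizes, function(n)
    coverage(h, shell[seq_len(n), ], n_points = 480), 0)
  expect_true(all(diff(cvg) >= -1e-12))
  expect_true(all(cvg >= 0 & cvg <= 1))
  expect_gt(cvg[3], cvg[1])
})

test_that("a single neighboring atom reduces but cannot eliminate coverage", {
  ref <- test_ref(); basis <- test_basis()
  h <- make_distorted_heme(ref = ref, basis = basis)
  one <- data.frame(element = "C", x = 0, y = 0, z = 3.5)
  cv <- coverage(h, one, n_points = 480)
  expect_gt(cv, 0)
  expect_lt(cv, 0.2)
})

test_that("descriptor_set bundles all descriptor fields", {
  ref <- test_ref(); basis <- test_basis()
  h <- add_propionate_stubs(
    make_distorted_heme(c(doming = 0.2), ref, basis), -90, 90)
  ds <- descriptor_set(h, bonds = TRUE)
  expect_named(ds, c("d_oop", "dihedral1", "dihedral2", "orientation1",
                     "orientation2", "coverage", "bond_geometry"),
               ignore.order = TRUE)
  expect_identical(ds$orientation1, "up")
  expect_identical(nrow(ds$bond_geometry$lengths), 32L)
})
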