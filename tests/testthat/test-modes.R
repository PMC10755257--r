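## independent eigenvalue oracle: characteristic polynomial by Lagrange
## interpolation of det(A - t I), roots via polyroot
charpoly_eigvals <- function(A) {
  n <- nrow(A)
  ts <- seq(-2, 2, length.out = n + 1) * max(1, max(abs(A)))
  dets <- vapply(ts, function(t) det(A - diag(t, n)), 0)
  coefs <- solve(outer(ts, 0:n, `^`), dets)
  sort(Re(polyroot(coefs)))
}

test_that("a two-atom spring has mass-weighted eigenvalues {0, 2k/m}", {
  k <- 1.7; r0 <- 1.2; m <- 3.5
  ff <- list(energy = function(xyz) {
    0.5 * k * (sqrt(sum((xyz[1, ] - xyz[2, ])^2)) - r0)^2
  })
  xyz <- matrix(c(0, 0, 0, r0, 0, 0), 2, 3, byrow = TRUE)
  H <- build_hessian(ff, xyz, step = 1e-4)
  sol <- solve_secular_equation(H, c(m, m))
  expect_equal(max(sol$values), 2 * k / m, tolerance = 1e-6)
  expect_lt(max(abs(sol$values[1:5])), 1e-6 * max(sol$values))
})

test_that("secular eigenvalues match the characteristic-polynomial oracle", {
  ## two-atom spring plus distinct harmonic pins on every coordinate, so
  ## all six eigenvalues are simple and polyroot is well-conditioned
  k <- 0.8; r0 <- 1.0; m <- c(2, 5)
  w <- c(0.11, 0.23, 0.31, 0.43, 0.54, 0.62)
  ff <- list(energy = function(xyz)
    0.5 * k * (sqrt(sum((xyz[1, ] - xyz[2, ])^2)) - r0)^2 +
    0.5 * sum(w * as.vector(t(xyz))^2))
  xyz <- matrix(c(0, 0, 0, r0, 0, 0), 2, 3, byrow = TRUE)
  H <- build_hessian(ff, xyz, step = 1e-4)
  m3 <- rep(m, each = 3)
  W <- H / sqrt(outer(m3, m3))
  ## tolerance limited by the Vandermonde interpolation in the oracle
  expect_equal(solve_secular_equation(H, m)$values,
               charpoly_eigvals((W + t(W)) / 2), tolerance = 1e-6)
})

test_that("doubling all force constants doubles every nonzero eigenvalue", {
  ref <- test_ref()
  s1 <- solve_secular_equation(
    build_hessian(force_field(ref), ref$xyz),
    mass_table()[ref$elements])
  s2 <- solve_secular_equation(
    build_hessian(force_field(ref, k_stretch = 2, k_bend = 0.6,
                              k_oop = 0.2), ref$xyz),
    mass_table()[ref$elements])
  nz <- s1$values > 1e-6
  expect_equal(s2$values[nz] / s1$values[nz], rep(2, sum(nz)),
               tolerance = 1e-7)
})

test_that("the force field is minimized at the reference and rigid-motion invariant", {
  ref <- test_ref()
  ff <- force_field(ref)
  expect_lt(max(abs(ff_gradient(ff, ref$xyz))), 1e-6)
  set.seed(42)
  d <- ref$xyz + matrix(rnorm(75, 0, 0.05), 25, 3)
  e0 <- ff$energy(d)
  moved <- sweep(d %*% t(random_rotation(seed = 5)), 2, c(1, 2, 3), "+")
  expect_equal(ff$energy(moved), e0, tolerance = 1e-9)
  expect_gt(e0, ff$energy(ref$xyz))
})

test_that("the secular solution has a 6-dimensional rigid null space and 69 internal modes", {
  ref <- test_ref()
  sol <- solve_secular_equation(build_hessian(force_field(ref), ref$xyz),
                                mass_table()[ref$elements])
  nzero <- sum(abs(sol$values) < 1e-6 * max(sol$values))
  expect_identical(nzero, 6L)
  expect_identical(sum(sol$values > 1e-6 * max(sol$values)), 69L)
  ## eigenvector orthonormality
  V <- sol$vectors
  expect_lt(max(abs(crossprod(V) - diag(75))), 1e-8)
})

test_that("the basis has 12 named modes, unit self-inner products, tiny cross terms", {
  basis <- test_basis()
  expect_identical(colnames(basis$vectors), mode_names())
  g <- basis$gram
  expect_true(all(abs(diag(g)) >= 0.99))
  expect_lt(max(abs(g - diag(diag(g)))), 0.10)
  expect_true(validate_mode_basis(basis))
})

test_that("saddling matches the analytic B2u template", {
  basis <- test_basis()
  m <- hemeNSD:::vec_to_xyz(basis$vectors[, "saddling"])
  ## out-of-plane: no in-plane components
  expect_lt(max(abs(m[, 1:2])), 1e-8)
  ## beta-carbon z alternate in sign around the ring with 4-fold pattern
  betas <- m[c("C2A", "C3A", "C2B", "C3B", "C2C", "C3C", "C2D", "C3D"), 3]
  signs <- unname(sign(betas))
  expect_equal(signs[1:2], -signs[3:4])
  expect_equal(signs[1:2], signs[5:6])
  ## cosine with the sparse template (unit z on beta carbons, alternating)
  tmpl <- numeric(75)
  rows <- match(c("C2A", "C3A", "C2B", "C3B", "C2C", "C3C", "C2D", "C3D"),
                porphyrin_atoms())
  tmpl[3 * (rows - 1) + 3] <- rep(c(1, -1), each = 2, times = 2)
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  expect_gt(abs(sum(tmpl * basis$vectors[, "saddling"])), 0.9)
})

test_that("out-of-plane modes are purely z and in-plane modes purely xy", {
  basis <- test_basis()
  for (nm in mode_names()) {
    m <- hemeNSD:::vec_to_xyz(basis$vectors[, nm])
    if (nm %in% oop_mode_names()) expect_lt(max(abs(m[, 1:2])), 1e-8)
    else expect_lt(max(abs(m[, 3])), 1e-8)
  }
})

test_that("mode shapes are stable under 20% force-constant perturbation", {
  ref <- test_ref()
  basis <- test_basis()
  for (ffp in list(force_field(ref, k_stretch = 1.2),
                   force_field(ref, k_bend = 0.24))) {
    bp <- build_mode_basis(ref, ffp)
    for (nm in mode_names()) {
      cs <- abs(sum(basis$vectors[, nm] * bp$vectors[, nm]))
      expect_gt(cs, 0.95)
    }
  }
})

test_that("mode basis save/load round-trips below 1e-9", {
  basis <- test_basis()
  tf <- withr::local_tempfile(fileext = ".txt")
  save_mode_basis(basis, tf)
  b2 <- load_mode_basis(tf)
  expect_lt(max(abs(b2$vectors - basis$vectors)), 1e-9)
  expect_identical(b2$provenance, "loaded")
  expect_identical(b2$symmetry, basis$symmetry)
})

test_that("a mode-basis file with 11 modes is rejected", {
  basis <- test_basis()
  tf <- withr::local_tempfile(fileext = ".txt")
  save_mode_basis(basis, tf)
  lines <- readLines(tf)
  first_block <- grep("^mode ", lines)[1]
  writeLines(lines[-(first_block:(first_block + 25))], tf)
  expect_error(load_mode_basis(tf), "12 mode blocks")
})

test_that("shuffled atom order in a basis file loads to the identical basis", {
  basis <- test_basis()
  tf <- withr::local_tempfile(fileext = ".txt")
  save_mode_basis(basis, tf)
  lines <- readLines(tf)
  set.seed(9)
  perm <- sample(25)
  heads <- grep("^mode ", lines)
  for (h in heads) lines[(h + 1):(h + 25)] <- lines[h + perm]
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, tf2)
  b2 <- load_mode_basis(tf2)
  expect_lt(max(abs(b2$vectors - basis$vectors)), 1e-9)
})

test_that("non-finite force-field energy surfaces as an evaluation error", {
  ff <- list(energy = function(xyz) NaN)
  xyz <- matrix(rnorm(6), 2, 3)
  expect_error(build_hessian(ff, xyz, step = 1e-4), "non-finite")
})
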