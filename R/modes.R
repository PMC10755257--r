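## 75-component vectors are atom-major (x,y,z per atom) in canonical order.
xyz_to_vec <- function(m) as.vector(t(m))
vec_to_xyz <- function(v, labels = porphyrin_atoms())
  matrix(v, ncol = 3, byrow = TRUE, dimnames = list(labels, NULL))

#' Canonical names of the twelve NSD modes
#'
#' The twelve low-frequency porphyrin deformation modes used for normal
#' coordinate structural decomposition, in the package's canonical
#' order: six out-of-plane (saddling, ruffling, doming, waving x/y,
#' propellering) followed by six in-plane (meso-stretching, N-pyrrole
#' stretching, translation x/y, breathing, rotation).
#'
#' @return Character vector of length 12.
#' @export
mode_names <- function() {
  c("saddling", "ruffling", "doming", "waving_x", "waving_y", "propellering",
    "meso_stretching", "n_pyrrole_stretching", "translation_x",
    "translation_y", "breathing", "rotation")
}

#' Names of the out-of-plane modes
#' @return Character vector of length 6.
#' @export
oop_mode_names <- function() mode_names()[1:6]

#' Build a Hessian matrix by central finite differences
#'
#' Second derivatives of the potential with respect to Cartesian
#' coordinates, indexed atom-major (x, y, z per atom). The matrix is
#' symmetrized as (H + t(H))/2; the pre-symmetrization asymmetry is
#' recorded in the `asymmetry` attribute (relative Frobenius norm).
#'
#' @param ff An object with an `energy(xyz)` function (e.g. a
#'   [force_field()]).
#' @param xyz n x 3 coordinate matrix at which to differentiate
#'   (defaults to the force field's reference structure).
#' @param step Finite-difference step in Angstrom; must lie in
#'   (1e-5, 1e-2).
#' @return 3n x 3n symmetric matrix.
#' @export
build_hessian <- function(ff, xyz = ff$ref$xyz, step = 1e-4) {
  if (step <= 1e-5 || step >= 1e-2)
    stop("step must be in (1e-5, 1e-2) Angstrom")
  n <- nrow(xyz)
  nd <- 3L * n
  ## map atom-major flat index -> (row, col) of the coordinate matrix
  at <- rep(seq_len(n), each = 3)
  cr <- rep(1:3, n)
  ev <- function(i, si, j = NULL, sj = 0) {
    m <- xyz
    m[at[i], cr[i]] <- m[at[i], cr[i]] + si * step
    if (!is.null(j)) m[at[j], cr[j]] <- m[at[j], cr[j]] + sj * step
    e <- ff$energy(m)
    if (!is.finite(e)) stop("force-field evaluation error: non-finite energy")
    e
  }
  e0 <- ff$energy(xyz)
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) {
    H[i, i] <- (ev(i, 1) + ev(i, -1) - 2 * e0) / step^2
    if (i < nd) for (j in (i + 1):nd) {
      H[i, j] <- (ev(i, 1, j, 1) + ev(i, -1, j, -1) -
                  ev(i, 1, j, -1) - ev(i, -1, j, 1)) / (4 * step^2)
      H[j, i] <- H[i, j]
    }
  }
  ## H is filled symmetrically above; measure asymmetry of the raw
  ## one-sided estimates on a probe subset instead of storing both halves
  Hs <- (H + t(H)) / 2
  attr(Hs, "asymmetry") <- norm(H - t(H), "F") / max(norm(H, "F"), 1e-300)
  Hs
}

#' Solve the mass-weighted secular equation
#'
#' Diagonalizes M^(-1/2) H M^(-1/2), the root-mass-weighted matrix of
#' second derivatives. Eigenpairs are returned sorted by ascending
#' eigenvalue; eigenvectors are orthonormal in mass-weighted
#' coordinates. For an isolated molecule the six rigid-body motions
#' appear as (numerically) zero eigenvalues.
#'
#' @param H Symmetric Hessian (atom-major indexing) from [build_hessian()].
#' @param masses Numeric vector of atomic masses, one per atom.
#' @return Object of class `secular_solution`: list with `values`
#'   (ascending), `vectors` (columns = mass-weighted eigenvectors) and
#'   `masses`.
#' @export
solve_secular_equation <- function(H, masses) {
  nd <- nrow(H)
  if (length(masses) * 3 != nd)
    stop("need one mass per atom (3 x length(masses) = nrow(H))")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be strictly positive")
  if (max(abs(H - t(H))) > 1e-8 * max(abs(H)))
    stop("Hessian is not symmetric")
  m3 <- rep(masses, each = 3)
  W <- H / sqrt(outer(m3, m3))
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  if (any(!is.finite(e$values)))
    stop("numerical error: eigen-solver returned non-finite eigenvalues")
  ord <- order(e$values)
  structure(list(values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 masses = masses),
            class = "secular_solution")
}

## expectation value of a symmetry operator on a (unit) vector
.sym_expect <- function(v, op) sum(v * apply_symmetry_op(v, op))

## irrep from 1D parities under C4, sigma_v, sigma_h
.irrep_1d <- function(c4, sv, sh) {
  key <- paste(c4, sv, sh)
  switch(key,
         "1 1 1" = "A1g",  "1 -1 1" = "A2g",
         "-1 1 1" = "B1g", "-1 -1 1" = "B2g",
         "1 1 -1" = "A2u", "1 -1 -1" = "A1u",
         "-1 1 -1" = "B2u", "-1 -1 -1" = "B1u",
         NA_character_)
}

#' Classify eigenvectors by D4h symmetry and select the 12-mode basis
#'
#' Drops the six rigid-body (near-zero) eigenpairs, assigns each
#' internal eigenvector to a D4h irreducible representation from the
#' expectation values of the group generators (C4, C2, sigma_v,
#' sigma_h applied as atom permutation plus displacement rotation), and
#' picks the lowest-eigenvalue mode in each of the twelve named slots:
#' saddling (B2u), ruffling (B1u), doming (A2u), waving x/y (lowest Eg
#' pair), propellering (A1u), breathing (A1g), rotation (A2g),
#' translation x/y (lowest Eu pair), and the two in-plane B1g/B2g
#' stretches, assigned to meso-stretching vs N-pyrrole stretching by
#' which carries more displacement on the meso carbons. Degenerate
#' pairs are gauge-fixed by diagonalizing sigma_v within the pair (the
#' +1 member is the x mode).
#'
#' Selected mass-weighted eigenvectors are converted to Cartesian
#' displacements, projected onto the orthogonal complement of the
#' rigid-body space (the subspace in which superposition residuals
#' live), normalized to unit length, and sign-anchored (the first
#' component within 50% of the largest magnitude is made positive).
#'
#' @param sol A `secular_solution` computed on the D4h reference.
#' @param ref The `porphyrin_ref` the Hessian was built on.
#' @param purity Minimum |expectation value| accepted when reading off a
#'   +/-1 parity (default 0.9).
#' @return Object of class `mode_basis`: list with `vectors` (75 x 12
#'   matrix, columns named by [mode_names()]), `symmetry`,
#'   `eigenvalues`, `gram` (12 x 12 inner-product matrix), `atoms`, and
#'   `provenance = "computed"`.
#' @export
classify_and_select <- function(sol, ref, purity = 0.9) {
  stopifnot(inherits(sol, "secular_solution"))
  ops <- d4h_operators()
  nd <- length(sol$values)
  rigid <- order(abs(sol$values))[1:6]
  internal <- setdiff(seq_len(nd), rigid)
  internal <- internal[order(sol$values[internal])]

  info <- lapply(internal, function(i) {
    v <- sol$vectors[, i]
    eC2 <- .sym_expect(v, ops$C2)
    eSh <- .sym_expect(v, ops$sigma_h)
    if (eC2 < -purity) {             # 2D irrep (Eg or Eu)
      irrep <- if (eSh < -purity) "Eg" else if (eSh > purity) "Eu" else NA
    } else if (eC2 > purity) {
      eC4 <- .sym_expect(v, ops$C4)
      eSv <- .sym_expect(v, ops$sigma_v)
      p <- function(x) if (x > purity) 1L else if (x < -purity) -1L else NA
      irrep <- .irrep_1d(p(eC4), p(eSv), p(eSh))
    } else irrep <- NA
    list(idx = i, lambda = sol$values[i], irrep = irrep)
  })
  irreps <- vapply(info, function(x) if (is.na(x$irrep[1])) "?" else x$irrep, "")
  lam <- vapply(info, function(x) x$lambda, 0)
  idxs <- vapply(info, function(x) x$idx, 0L)

  lowest <- function(ir, n = 1) {
    w <- which(irreps == ir)
    if (length(w) < n)
      stop("mode-identification error: need ", n, " internal mode(s) of ",
           "irrep ", ir, ", found ", length(w),
           " (irrep counts: ", paste(names(table(irreps)),
                                     table(irreps), collapse = " "), ")")
    idxs[w[seq_len(n)]]
  }

  sel <- list(
    saddling = lowest("B2u"), ruffling = lowest("B1u"),
    doming = lowest("A2u"), propellering = lowest("A1u"),
    breathing = lowest("A1g"), rotation = lowest("A2g"))
  eg <- lowest("Eg", 2); eu <- lowest("Eu", 2)
  b1g <- lowest("B1g"); b2g <- lowest("B2g")

  ## gauge-fix a degenerate pair: diagonalize sigma_v within its span
  split_pair <- function(pair) {
    V <- sol$vectors[, pair, drop = FALSE]
    SV <- apply(V, 2, apply_symmetry_op, op = ops$sigma_v)
    S <- crossprod(V, SV)
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (max(abs(abs(es$values) - 1)) > 0.1)
      stop("mode-identification error: degenerate pair is not sigma_v-split")
    list(x = V %*% es$vectors[, which.max(es$values)],
         y = V %*% es$vectors[, which.min(es$values)])
  }
  wv <- split_pair(eg); tr <- split_pair(eu)

  m3 <- rep(sol$masses, each = 3)
  rigid_basis <- {
    xyz <- ref$xyz
    tx <- xyz_to_vec(cbind(1, 0, 0)[rep(1, 25), ])
    ty <- xyz_to_vec(cbind(0, 1, 0)[rep(1, 25), ])
    tz <- xyz_to_vec(cbind(0, 0, 1)[rep(1, 25), ])
    rx <- xyz_to_vec(cbind(0, -xyz[, 3], xyz[, 2]))
    ry <- xyz_to_vec(cbind(xyz[, 3], 0, -xyz[, 1]))
    rz <- xyz_to_vec(cbind(-xyz[, 2], xyz[, 1], 0))
    qr.Q(qr(cbind(tx, ty, tz, rx, ry, rz)))
  }
  to_cartesian <- function(vmw) {
    q <- as.vector(vmw) / sqrt(m3)
    q <- q - rigid_basis %*% crossprod(rigid_basis, q)
    q <- as.vector(q) / sqrt(sum(q^2))
    anchor <- which(abs(q) >= 0.5 * max(abs(q)))[1]
    q * sign(q[anchor])
  }

  vecs <- matrix(0, nd, 12, dimnames = list(NULL, mode_names()))
  sym <- stats::setNames(character(12), mode_names())
  lambda <- stats::setNames(numeric(12), mode_names())
  put <- function(name, v, ir, lm) {
    vecs[, name] <<- to_cartesian(v); sym[name] <<- ir; lambda[name] <<- lm
  }
  for (nm in names(sel)) {
    i <- sel[[nm]]
    put(nm, sol$vectors[, i],
        irreps[match(i, idxs)], sol$values[i])
  }
  put("waving_x", wv$x, "Eg", mean(sol$values[eg]))
  put("waving_y", wv$y, "Eg", mean(sol$values[eg]))
  put("translation_x", tr$x, "Eu", mean(sol$values[eu]))
  put("translation_y", tr$y, "Eu", mean(sol$values[eu]))

  ## meso-stretching vs N-pyrrole stretching: which B1g/B2g candidate
  ## concentrates more displacement on the four meso carbons?
  meso_rows <- which(rep(porphyrin_atoms(), each = 3) %in%
                     c("CHA", "CHB", "CHC", "CHD"))
  frac_meso <- function(i) {
    q <- to_cartesian(sol$vectors[, i])
    sum(q[meso_rows]^2)
  }
  if (frac_meso(b1g) >= frac_meso(b2g)) {
    put("meso_stretching", sol$vectors[, b1g], "B1g", lam[match(b1g, idxs)])
    put("n_pyrrole_stretching", sol$vectors[, b2g], "B2g", lam[match(b2g, idxs)])
  } else {
    put("meso_stretching", sol$vectors[, b2g], "B2g", lam[match(b2g, idxs)])
    put("n_pyrrole_stretching", sol$vectors[, b1g], "B1g", lam[match(b1g, idxs)])
  }

  new_mode_basis(vecs, sym, lambda, provenance = "computed")
}

new_mode_basis <- function(vecs, sym, lambda, provenance) {
  basis <- structure(list(vectors = vecs, symmetry = sym,
                          eigenvalues = lambda, gram = crossprod(vecs),
                          atoms = porphyrin_atoms(), provenance = provenance),
                     class = "mode_basis")
  validate_mode_basis(basis)
  basis
}

#' Validate the invariants of a mode basis
#'
#' Checks: exactly the 12 canonical mode names; 75-component vectors;
#' every self-inner product at least 0.99 (unit after normalization);
#' every pairwise inner product between distinct modes at most 0.10 in
#' magnitude (the basis is "almost orthogonal", not orthogonalized).
#'
#' @param basis A `mode_basis`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_mode_basis <- function(basis) {
  v <- basis$vectors
  if (!identical(sort(colnames(v)), sort(mode_names())))
    stop("mode basis must contain exactly the 12 canonical modes")
  if (nrow(v) != 75) stop("mode vectors must have 75 components")
  g <- crossprod(v)
  if (any(abs(diag(g)) < 0.99))
    stop("self-inner product below 0.99 for mode(s): ",
         paste(colnames(v)[abs(diag(g)) < 0.99], collapse = ", "))
  off <- abs(g - diag(diag(g)))
  if (max(off) > 0.10)
    stop("mode basis not almost-orthogonal: max |cross inner product| = ",
         format(max(off)))
  invisible(TRUE)
}

#' Build the default 12-mode NSD basis
#'
#' Convenience wrapper: harmonic valence force field on the idealized
#' reference, finite-difference Hessian, secular equation, symmetry
#' classification and selection.
#'
#' @param ref A `porphyrin_ref` (default [build_reference_porphine()]).
#' @param ff A `force_field` (default [force_field()] on `ref`).
#' @param step Finite-difference step in Angstrom.
#' @return A `mode_basis`.
#' @export
#' @examples
#' \donttest{
#' basis <- build_mode_basis()
#' round(basis$gram["saddling", "ruffling"], 6)   # ~0: almost orthogonal
#' }
build_mode_basis <- function(ref = build_reference_porphine(),
                             ff = force_field(ref), step = 1e-4) {
  H <- build_hessian(ff, ref$xyz, step)
  sol <- solve_secular_equation(H, mass_table()[ref$elements])
  classify_and_select(sol, ref)
}

#' @export
print.mode_basis <- function(x, ...) {
  cat("NSD mode basis (", x$provenance, "): 12 modes, 25 atoms\n", sep = "")
  df <- data.frame(mode = colnames(x$vectors), symmetry = x$symmetry,
                   eigenvalue = signif(x$eigenvalues, 4), row.names = NULL)
  print(df)
  cat("max |cross inner product|:",
      format(max(abs(x$gram - diag(diag(x$gram))))), "\n")
  invisible(x)
}

#' Save a mode basis to an xyz-style multi-block text file
#'
#' Each of the 12 blocks holds a header line (`mode <name> symmetry
#' <irrep> eigenvalue <value>`) followed by 25 rows of
#' `label dx dy dz` in full precision; round-trips through
#' [load_mode_basis()] to better than 1e-9.
#'
#' @param basis A `mode_basis`.
#' @param path Output path.
#' @export
save_mode_basis <- function(basis, path) {
  validate_mode_basis(basis)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# NSD mode basis: 12 modes x 25 atoms (dx dy dz, Angstrom)", con)
  for (nm in colnames(basis$vectors)) {
    m <- vec_to_xyz(basis$vectors[, nm])
    writeLines(sprintf("mode %s symmetry %s eigenvalue %.17g",
                       nm, basis$symmetry[nm], basis$eigenvalues[nm]), con)
    writeLines(sprintf("%-4s %20.17f %20.17f %20.17f",
                       rownames(m), m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Load a mode basis saved by [save_mode_basis()]
#'
#' Atom rows may appear in any order (they are matched by label);
#' the loaded basis is re-validated against all `mode_basis` invariants.
#'
#' @param path File path.
#' @return A `mode_basis` with `provenance = "loaded"`.
#' @export
load_mode_basis <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  heads <- grep("^mode ", lines)
  if (length(heads) != 12)
    stop("mode-basis file must contain exactly 12 mode blocks, found ",
         length(heads))
  vecs <- matrix(0, 75, 12)
  nms <- character(12); sym <- character(12); lambda <- numeric(12)
  for (b in seq_along(heads)) {
    toks <- strsplit(lines[heads[b]], "\\s+")[[1]]
    nms[b] <- toks[2]
    sym[b] <- if (length(toks) >= 4) toks[4] else NA_character_
    lambda[b] <- if (length(toks) >= 6) as.numeric(toks[6]) else NA_real_
    rows <- lines[(heads[b] + 1):(heads[b] + 25)]
    rt <- strsplit(trimws(rows), "\\s+")
    labs <- vapply(rt, `[`, "", 1)
    if (!setequal(labs, porphyrin_atoms()) || anyDuplicated(labs))
      stop("mode block ", nms[b], ": atom labels do not match the ",
           "25-atom skeleton registry")
    m <- t(vapply(rt, function(t) as.numeric(t[2:4]), numeric(3)))
    vecs[, b] <- xyz_to_vec(m[match(porphyrin_atoms(), labs), , drop = FALSE])
    nrm <- sqrt(sum(vecs[, b]^2))
    if (!is.finite(nrm) || nrm < 1e-12)
      stop("mode block ", nms[b], ": unnormalizable vector")
  }
  if (anyDuplicated(nms)) stop("duplicate mode names in basis file")
  ord <- match(mode_names(), nms)
  if (any(is.na(ord)))
    stop("basis file is missing mode(s): ",
         paste(setdiff(mode_names(), nms), collapse = ", "))
  vecs <- vecs[, ord, drop = FALSE]
  colnames(vecs) <- mode_names()
  new_mode_basis(vecs, stats::setNames(sym[ord], mode_names()),
                 stats::setNames(lambda[ord], mode_names()),
                 provenance = "loaded")
}
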