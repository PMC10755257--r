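#' Harmonic valence force field on the porphyrin skeleton
#'
#' A model potential whose minimum is the reference structure, used only
#' to obtain normal-mode *shapes* (eigenvalues are never used
#' downstream). Three term types, all harmonic about their reference
#' values: bond stretches over the bonded-pair graph, angle bends at
#' every pair of bonds sharing an atom, and out-of-plane bends (the
#' distance of each atom from the plane of three reference neighbors),
#' which supply the out-of-plane restoring forces a planar conjugated
#' macrocycle owes to its pi system.
#'
#' @param ref A `porphyrin_ref` from [build_reference_porphine()].
#' @param k_stretch,k_bend,k_oop Force constants in internal units
#'   (energy/A^2, energy/rad^2, energy/A^2). Defaults 1.0 / 0.3 / 0.1.
#' @param cutoff Bonded-pair cutoff in Angstrom used to generate terms.
#' @return Object of class `force_field`: list with `energy(xyz)` (xyz a
#'   25 x 3 matrix), term tables, and the generating parameters.
#' @export
force_field <- function(ref, k_stretch = 1.0, k_bend = 0.3, k_oop = 0.1,
                        cutoff = 2.2) {
  stopifnot(inherits(ref, "porphyrin_ref"))
  atoms <- porphyrin_atoms()
  g <- bonded_pairs(ref, cutoff)
  ba <- bond_lengths_and_angles(ref, g)
  nb <- bond_neighbors(g)

  bi <- match(g$atom1, atoms); bj <- match(g$atom2, atoms)
  r0 <- ba$lengths$length
  ai <- match(ba$angles$atom1, atoms)
  av <- match(ba$angles$vertex, atoms)
  ak <- match(ba$angles$atom2, atoms)
  th0 <- ba$angles$angle * pi / 180

  ## out-of-plane terms: central atom i, plane atoms (j, k, l), weight w.
  ## The plane-atom rule must commute with the D4h group action so the
  ## potential keeps the full symmetry: Fe averages over the four cyclic
  ## nitrogen triples, 3-coordinate atoms use their neighbors, beta
  ## carbons use (adjacent alpha, adjacent beta, ring N) and meso
  ## carbons use (both alpha neighbors, Fe).
  oop_rows <- list()
  for (i in seq_along(atoms)) {
    a <- atoms[i]
    ns <- match(nb[[a]], atoms)
    if (length(ns) >= 4) {
      for (s in seq_along(ns)) {
        tri <- ns[(c(s, s + 1, s + 2) - 1) %% length(ns) + 1]
        oop_rows[[length(oop_rows) + 1]] <- c(i, tri, 1 / length(ns))
      }
    } else if (length(ns) == 3) {
      oop_rows[[length(oop_rows) + 1]] <- c(i, ns, 1)
    } else {
      third <- if (startsWith(a, "CH")) "FE"
               else paste0("N", substr(a, 3, 3))
      oop_rows[[length(oop_rows) + 1]] <-
        c(i, ns, match(third, atoms), 1)
    }
  }
  oopm <- do.call(rbind, oop_rows)
  oop <- oopm[, 1:4, drop = FALSE]
  oop_w <- oopm[, 5]

  energy <- function(xyz) {
    db <- xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE]
    r <- sqrt(rowSums(db * db))
    e <- 0.5 * k_stretch * sum((r - r0)^2)

    u1 <- xyz[ai, , drop = FALSE] - xyz[av, , drop = FALSE]
    u2 <- xyz[ak, , drop = FALSE] - xyz[av, , drop = FALSE]
    cs <- rowSums(u1 * u2) / sqrt(rowSums(u1 * u1) * rowSums(u2 * u2))
    th <- acos(pmax(-1, pmin(1, cs)))
    e <- e + 0.5 * k_bend * sum((th - th0)^2)

    ctr <- xyz[oop[, 1], , drop = FALSE]
    a <- xyz[oop[, 2], , drop = FALSE]
    b <- xyz[oop[, 3], , drop = FALSE] - a
    cc <- xyz[oop[, 4], , drop = FALSE] - a
    nrm <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    h <- rowSums((ctr - a) * nrm) / sqrt(rowSums(nrm * nrm))
    e + 0.5 * k_oop * sum(oop_w * h * h)
  }

  structure(list(energy = energy, ref = ref,
                 bonds = g, angles = ba$angles, oop_planes = oop,
                 constants = c(k_stretch = k_stretch, k_bend = k_bend,
                               k_oop = k_oop, cutoff = cutoff)),
            class = "force_field")
}

#' Numerical gradient of a force field (central differences)
#'
#' Used to verify that the potential is minimized at the reference.
#'
#' @param ff A `force_field`.
#' @param xyz 25 x 3 coordinate matrix.
#' @param step Finite-difference step (Angstrom).
#' @return Numeric vector of length 75 (canonical atom-major x,y,z order).
#' @export
ff_gradient <- function(ff, xyz, step = 1e-5) {
  n <- length(xyz)
  g <- numeric(n)
  for (i in seq_len(n)) {
    xp <- xyz; xp[i] <- xp[i] + step
    xm <- xyz; xm[i] <- xm[i] - step
    g[i] <- (ff$energy(xp) - ff$energy(xm)) / (2 * step)
  }
  ## xyz matrices are column-major; reorder to atom-major (x,y,z per atom)
  as.vector(t(matrix(g, nrow = 25)))
}
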