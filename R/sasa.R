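#' Van der Waals radii used for solvent-accessible surface areas
#'
#' Bondi-type radii (Angstrom) for the elements retained in the SASA
#' calculation (C, N, O, S, Fe). Iron, absent from the Bondi set, is
#' assigned 2.00 A, a common metalloprotein choice.
#'
#' @return Named numeric vector (element -> radius in Angstrom).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, Fe = 2.00)
}

## deterministic quasi-uniform unit sphere points (golden-spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over each atom's van der Waals sphere: test
#' points are placed quasi-uniformly on the expanded sphere of radius
#' r_vdw + probe, and the accessible fraction is the share of points
#' not buried inside any neighboring atom's expanded sphere.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param elements Character vector of element symbols (length n); atoms
#'   with elements outside `radii` are dropped with an error.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Number of sphere test points per atom (default 960).
#' @param radii Named radii table (default [vdw_radii()]).
#' @return Numeric vector of per-atom areas (Angstrom^2), one per row
#'   of `xyz`.
#' @export
sasa_areas <- function(xyz, elements, probe = 1.4, n_points = 960,
                       radii = vdw_radii()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(elements) == n)
  r <- radii[elements]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  re <- unname(r) + probe
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  ## neighbor prefilter via squared-distance matrix (small systems)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    p <- sweep(pts * re[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(free)) break
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      free <- free & (dd >= re[j]^2)
    }
    out[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  out
}
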