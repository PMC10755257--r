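#' Out-of-plane displacement of the heme iron
#'
#' Distance of the FE atom from the least-squares plane of the four
#' pyrrole nitrogens. The plane is obtained from the eigenvectors of
#' the 3 x 3 variance-covariance matrix of the nitrogen coordinates:
#' the first two eigenvectors span the plane and the displacement is
#' the inner product of the FE position (relative to the nitrogen
#' centroid) with the normalized third eigenvector.
#'
#' The third eigenvector's sign is arbitrary. When `toward` is given
#' (e.g. the coordinates of the first axial ligand's coordinating
#' atom), the normal is oriented so that positive values point toward
#' it and the result carries `sign_fixed = TRUE`; otherwise the raw
#' signed value is returned with `sign_fixed = FALSE` and only the
#' magnitude is meaningful.
#'
#' @param x A `heme_entry`, `porphyrin_ref`, or a coordinate matrix
#'   containing rows named FE, NA, NB, NC, ND.
#' @param toward Optional length-3 coordinate fixing the positive
#'   direction of the plane normal.
#' @return Numeric scalar (Angstrom) with attribute `sign_fixed`.
#' @export
#' @examples
#' ref <- build_reference_porphine()
#' out_of_plane_displacement(ref)   # 0: planar, Fe in-plane
out_of_plane_displacement <- function(x, toward = NULL) {
  xyz <- if (inherits(x, "porphyrin_ref") || inherits(x, "heme_entry")) x$xyz
         else as.matrix(x)
  need <- c("FE", "NA", "NB", "NC", "ND")
  if (!all(need %in% rownames(xyz)))
    stop("need FE and the four pyrrole nitrogens")
  N <- xyz[c("NA", "NB", "NC", "ND"), , drop = FALSE]
  ctr <- colMeans(N)
  Nc <- sweep(N, 2, ctr)
  C <- crossprod(Nc) / nrow(Nc)          # variance-covariance matrix
  e <- eigen(C, symmetric = TRUE)        # values descending
  if (e$values[2] < 1e-12)
    stop("degenerate plane: collinear nitrogen atoms")
  v3 <- e$vectors[, 3]
  if (!is.null(toward)) {
    s <- sum((toward - ctr) * v3)
    if (abs(s) > 0) v3 <- v3 * sign(s)
  }
  d <- sum((xyz["FE", ] - ctr) * v3)
  attr(d, "sign_fixed") <- !is.null(toward)
  d
}

#' Signed torsion (dihedral) angle of four points
#'
#' Standard IUPAC convention: looking down the B-C bond, the angle is
#' positive for a clockwise rotation of the far bond; the value lies in
#' (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 Length-3 coordinates of the four atoms A-B-C-D.
#' @return Angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("undefined torsion: three collinear atoms")
  m <- c(n1[2] * b2[3] - n1[3] * b2[2],
         n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

#' Classify a propionate dihedral as "up" or "down"
#'
#' Negative dihedrals are "up", positive are "down". The measure-zero
#' boundary of exactly 0 degrees is assigned "down" (half-open
#' convention), as is 180.
#'
#' @param phi Dihedral angle in degrees (may be NA).
#' @return "up", "down" or NA.
#' @export
propionate_orientation <- function(phi) {
  ifelse(is.na(phi), NA_character_, ifelse(phi < 0, "up", "down"))
}

#' Propionate sidechain dihedrals and orientations of a heme
#'
#' dihedral1 is the C1A-C2A-CAA-CBA torsion, dihedral2 the
#' C4D-C3D-CAD-CBD torsion. A dihedral is NA when any of its four atoms
#' is missing from the entry.
#'
#' @param heme A `heme_entry` (skeleton plus sidechain atoms), or any
#'   coordinate matrix whose rownames include the required atoms.
#' @return List with `dihedral1`, `dihedral2` (degrees, in (-180, 180])
#'   and `orientation1`, `orientation2` ("up"/"down"/NA).
#' @export
propionate_dihedrals <- function(heme) {
  xyz <- heme_all_xyz(heme)
  tors <- function(atoms) {
    if (!all(atoms %in% rownames(xyz))) return(NA_real_)
    torsion_angle(xyz[atoms[1], ], xyz[atoms[2], ],
                  xyz[atoms[3], ], xyz[atoms[4], ])
  }
  d1 <- tors(c("C1A", "C2A", "CAA", "CBA"))
  d2 <- tors(c("C4D", "C3D", "CAD", "CBD"))
  list(dihedral1 = d1, dihedral2 = d2,
       orientation1 = propionate_orientation(d1),
       orientation2 = propionate_orientation(d2))
}

## all atoms of a heme entry (skeleton + sidechains) as one named matrix
heme_all_xyz <- function(heme) {
  if (inherits(heme, "heme_entry")) {
    xyz <- heme$xyz
    if (!is.null(heme$sidechain) && nrow(heme$sidechain)) {
      sc <- as.matrix(heme$sidechain[, c("x", "y", "z")])
      rownames(sc) <- heme$sidechain$label
      xyz <- rbind(xyz, sc)
    }
    xyz
  } else as.matrix(heme)
}

## element per atom of a heme entry, aligned with heme_all_xyz()
heme_all_elements <- function(heme) {
  if (inherits(heme, "heme_entry")) {
    el <- porphyrin_elements()
    if (!is.null(heme$sidechain) && nrow(heme$sidechain))
      el <- c(el, heme$sidechain$element)
    el
  } else {
    guess_element(rownames(heme_all_xyz(heme)))
  }
}

## crude element from an atom label (first alpha character run, C/N/O/S/FE)
guess_element <- function(labels) {
  up <- toupper(labels)
  ifelse(up == "FE", "Fe", substr(up, 1, 1))
}

#' Heme coverage by the protein (buried fraction of skeleton SASA)
#'
#' Fraction of the porphyrin skeleton's solvent-accessible surface that
#' the surrounding complex buries:
#' `c = (sum S_heme,i - sum S_complex,i) / sum S_heme,i`,
#' summed over the 25 skeleton atoms. `S_heme` is computed on the heme
#' in isolation (all heme atoms present), `S_complex` on the full
#' complex; in both calculations only C, N, O, S and Fe atoms are used.
#'
#' @param heme A `heme_entry`.
#' @param complex_atoms Optional data.frame of the surrounding atoms
#'   (columns `element`, `x`, `y`, `z`), excluding the heme itself.
#'   NULL or empty means the isolated heme, giving coverage 0.
#' @param probe,n_points,radii SASA parameters, see [sasa_areas()].
#' @return Coverage in \[0, 1\].
#' @export
coverage <- function(heme, complex_atoms = NULL, probe = 1.4,
                     n_points = 960, radii = vdw_radii()) {
  xyz <- heme_all_xyz(heme)
  el <- heme_all_elements(heme)
  keep <- el %in% names(radii)
  xyz <- xyz[keep, , drop = FALSE]; el <- el[keep]
  skel <- match(porphyrin_atoms(), rownames(xyz))
  if (any(is.na(skel))) stop("incomplete skeleton")

  s_heme <- sasa_areas(xyz, el, probe, n_points, radii)
  tot_heme <- sum(s_heme[skel])
  if (tot_heme <= 0) stop("division by zero: isolated heme has no surface")

  if (is.null(complex_atoms) || !nrow(complex_atoms)) return(0)
  ca <- complex_atoms[complex_atoms$element %in% names(radii), , drop = FALSE]
  if (!nrow(ca)) return(0)
  all_xyz <- rbind(xyz, as.matrix(ca[, c("x", "y", "z")]))
  all_el <- c(el, ca$element)
  s_complex <- sasa_areas(all_xyz, all_el, probe, n_points, radii)
  cvg <- (tot_heme - sum(s_complex[skel])) / tot_heme
  min(max(cvg, 0), 1)
}

#' All structural descriptors of one heme
#'
#' Bundles the out-of-plane iron displacement, the two propionate
#' dihedrals with orientations, the coverage, and (optionally) the bond
#' length/angle tables.
#'
#' @param heme A `heme_entry`.
#' @param complex_atoms See [coverage()].
#' @param bonds If TRUE, include the bonded-pair length/angle tables.
#' @param ... Passed to [coverage()].
#' @return List of class `descriptor_set`.
#' @export
descriptor_set <- function(heme, complex_atoms = NULL, bonds = FALSE, ...) {
  pro <- propionate_dihedrals(heme)
  lig <- heme$ligands
  toward <- NULL
  if (!is.null(lig) && !is.null(lig$ligands) && nrow(lig$ligands) >= 1)
    toward <- as.numeric(lig$ligands[1, c("x", "y", "z")])
  out <- c(list(d_oop = out_of_plane_displacement(heme, toward = toward)),
           pro,
           list(coverage = coverage(heme, complex_atoms, ...)))
  if (bonds) out$bond_geometry <- bond_lengths_and_angles(heme$xyz)
  structure(out, class = "descriptor_set")
}
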