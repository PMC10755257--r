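#' Atom registry of the Fe-porphyrin skeleton
#'
#' The 25 heavy atoms used for distortion analysis: the iron, the four
#' pyrrole nitrogens, the sixteen pyrrole carbons (alpha carbons C1x/C4x,
#' beta carbons C2x/C3x for rings A--D) and the four meso carbons
#' (CHA--CHD). The order returned here is the canonical atom order used
#' for all 75-component coordinate and mode vectors in the package.
#'
#' @return Character vector of length 25 with the canonical atom names.
#' @export
porphyrin_atoms <- function() {
  c("FE",
    "NA", "NB", "NC", "ND",
    "C1A", "C2A", "C3A", "C4A",
    "C1B", "C2B", "C3B", "C4B",
    "C1C", "C2C", "C3C", "C4C",
    "C1D", "C2D", "C3D", "C4D",
    "CHA", "CHB", "CHC", "CHD")
}

#' Elements of the skeleton atoms, in canonical order
#' @return Character vector of length 25 ("Fe", "N" or "C").
#' @export
porphyrin_elements <- function() {
  c("Fe", rep("N", 4), rep("C", 20))
}

#' Atomic masses used for the mass-weighted secular equation
#'
#' Standard atomic weights (unified amu) for the elements occurring in
#' the heavy-atom model. Hydrogens are not part of the model.
#'
#' @return Named numeric vector (element -> mass in amu).
#' @export
mass_table <- function() {
  c(Fe = 55.845, N = 14.007, C = 12.011, O = 15.999, S = 32.06)
}

#' Names of the propionate sidechain atoms used by the dihedral descriptors
#' @return Character vector.
#' @export
propionate_atoms <- function() c("CAA", "CBA", "CAD", "CBD")

## rotate ring-A template coordinates by k * 90 degrees about z
.rot_z <- function(xy, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xy %*% t(R)
}

#' Build the idealized planar D4h Fe-porphine reference structure
#'
#' Constructs the 25-atom skeleton with Fe at the origin, the pyrrole
#' nitrogens on the +/-x and +/-y axes and the meso carbons on the
#' diagonals. All atoms lie exactly in the z = 0 plane and the structure
#' is invariant under 90 degree rotation combined with the ring
#' relabeling A->B->C->D.
#'
#' The pyrrole closure has one free parameter beyond the five bond
#' lengths; it is fixed by the Calpha-N-Calpha angle. The default of 108
#' degrees keeps every non-bonded skeleton distance above the 2.2 A
#' bonded cutoff, so the bonded-pair graph is the stable 32-pair set.
#'
#' @param fe_n Fe-N bond length (Angstrom).
#' @param n_ca N-Calpha bond length (Angstrom).
#' @param ca_cb Calpha-Cbeta bond length (Angstrom).
#' @param cb_cb Cbeta-Cbeta bond length (Angstrom).
#' @param ca_cm Calpha-Cmeso bond length (Angstrom).
#' @param ca_n_ca Calpha-N-Calpha angle at the pyrrole nitrogen (degrees).
#' @return An object of class `porphyrin_ref`: list with `xyz` (25 x 3
#'   matrix, rownames the canonical atom names), `elements`, `params`
#'   and `provenance`.
#' @export
#' @examples
#' ref <- build_reference_porphine()
#' max(abs(ref$xyz[, 3]))                # exactly planar
#' sqrt(sum(ref$xyz["NA", ]^2))          # the Fe-N parameter
build_reference_porphine <- function(fe_n = 2.00, n_ca = 1.38, ca_cb = 1.44,
                                     cb_cb = 1.35, ca_cm = 1.39,
                                     ca_n_ca = 108) {
  p <- c(fe_n = fe_n, n_ca = n_ca, ca_cb = ca_cb, cb_cb = cb_cb,
         ca_cm = ca_cm, ca_n_ca = ca_n_ca)
  if (any(!is.finite(p)) || any(p[1:5] <= 0) || ca_n_ca <= 0 || ca_n_ca >= 180)
    stop("all bond parameters must be positive and the angle in (0, 180)")

  half <- ca_n_ca / 2 * pi / 180
  xa <- fe_n + n_ca * cos(half)       # alpha carbons
  ya <- n_ca * sin(half)
  yb <- cb_cb / 2                     # beta carbons
  dx2 <- ca_cb^2 - (ya - yb)^2
  if (dx2 <= 0)
    stop("cannot close the macrocycle: Calpha-Cbeta too short for this angle")
  xb <- xa + sqrt(dx2)
  disc <- 2 * ca_cm^2 - (xa - ya)^2   # meso carbon on the diagonal (h, -h)
  if (disc <= 0)
    stop("cannot close the macrocycle: Calpha-Cmeso too short to bridge rings")
  h <- ((xa + ya) + sqrt(disc)) / 2

  ## ring A template (on +x axis); C1A adjacent to CHA on the (+x,-y) diagonal
  ringA <- rbind(
    NA_ = c(fe_n, 0, 0),
    C1A = c(xa, -ya, 0),
    C2A = c(xb, -yb, 0),
    C3A = c(xb,  yb, 0),
    C4A = c(xa,  ya, 0))
  xyz <- matrix(NA_real_, 25, 3, dimnames = list(porphyrin_atoms(), NULL))
  xyz["FE", ] <- 0
  for (k in 0:3) {
    ring <- LETTERS[k + 1]
    rot <- .rot_z(ringA, 90 * k)
    xyz[paste0("N", ring), ] <- rot[1, ]
    xyz[paste0(c("C1", "C2", "C3", "C4"), ring), ] <- rot[2:5, ]
    xyz[paste0("CH", ring), ] <- .rot_z(matrix(c(h, -h, 0), 1, 3), 90 * k)
  }

  ## exact closure check: every realized bond must match its parameter
  stopifnot(abs(dist3(xyz["C1A", ], xyz["CHA", ]) - ca_cm) < 1e-9,
            abs(dist3(xyz["C4D", ], xyz["CHA", ]) - ca_cm) < 1e-9)

  structure(list(xyz = xyz, elements = porphyrin_elements(),
                 params = p, provenance = "built-in"),
            class = "porphyrin_ref")
}

#' @export
print.porphyrin_ref <- function(x, ...) {
  cat("Idealized D4h Fe-porphine reference (", x$provenance, ")\n", sep = "")
  cat("  25 atoms; Fe-N =", format(x$params["fe_n"]),
      "A; max |z| =", format(max(abs(x$xyz[, 3]))), "A\n")
  invisible(x)
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

## coerce a porphyrin_ref / heme_entry / plain matrix to skeleton coordinates
skeleton_xyz <- function(x) {
  xyz <- if (inherits(x, "porphyrin_ref") || inherits(x, "heme_entry")) x$xyz
         else as.matrix(x)
  if (is.null(rownames(xyz))) {
    if (nrow(xyz) != 25) stop("unnamed coordinate matrix must have 25 rows")
    rownames(xyz) <- porphyrin_atoms()
  }
  miss <- setdiff(porphyrin_atoms(), rownames(xyz))
  if (length(miss))
    stop("incomplete skeleton: missing atom(s) ", paste(miss, collapse = ", "))
  xyz <- xyz[porphyrin_atoms(), , drop = FALSE]
  if (any(!is.finite(xyz))) stop("incomplete skeleton: non-finite coordinates")
  xyz
}

#' Bonded-pair graph of a porphyrin skeleton
#'
#' All unordered pairs of skeleton atoms whose Euclidean distance in the
#' given structure does not exceed `cutoff`. With the idealized
#' reference and the 2.2 A rule this is the stable 32-pair set (4 Fe-N,
#' 8 N-Calpha, 8 Calpha-Cbeta, 4 Cbeta-Cbeta, 8 Calpha-Cmeso).
#'
#' @param x A `porphyrin_ref`, `heme_entry`, or a 25 x 3 coordinate
#'   matrix with the canonical atom names as rownames.
#' @param cutoff Distance cutoff in Angstrom (default 2.2).
#' @return Object of class `bond_graph`: data.frame with columns
#'   `atom1`, `atom2`, `length`; attribute `cutoff`.
#' @export
bonded_pairs <- function(x, cutoff = 2.2) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  xyz <- coerce_coords(x)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  g <- data.frame(atom1 = rownames(xyz)[idx[, 1]],
                  atom2 = rownames(xyz)[idx[, 2]],
                  length = d[idx], stringsAsFactors = FALSE)
  ord <- order(match(g$atom1, rownames(xyz)), match(g$atom2, rownames(xyz)))
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  structure(g, cutoff = cutoff, atoms = rownames(xyz),
            class = c("bond_graph", "data.frame"))
}

## skeleton coordinates for package objects; any named matrix passes through
coerce_coords <- function(x) {
  if (inherits(x, "porphyrin_ref") || inherits(x, "heme_entry"))
    return(skeleton_xyz(x))
  xyz <- as.matrix(x)
  if (is.null(rownames(xyz))) return(skeleton_xyz(xyz))   # 25-row convention
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  xyz
}

#' Bond lengths and bond angles of a skeleton
#'
#' One length per bonded pair and one angle per unordered pair of bonds
#' that share a common atom (the angle is measured at the shared atom).
#'
#' @param x Coordinates as in [bonded_pairs()].
#' @param graph A `bond_graph`; defaults to `bonded_pairs(x)`.
#' @return List with data.frames `lengths` (atom1, atom2, length) and
#'   `angles` (atom1, vertex, atom2, angle in degrees, in \[0, 180\]).
#' @export
bond_lengths_and_angles <- function(x, graph = bonded_pairs(x)) {
  xyz <- coerce_coords(x)
  lens <- data.frame(atom1 = graph$atom1, atom2 = graph$atom2,
                     length = mapply(function(a, b) dist3(xyz[a, ], xyz[b, ]),
                                     graph$atom1, graph$atom2),
                     stringsAsFactors = FALSE)
  if (any(lens$length < 1e-9)) stop("degenerate geometry: coincident atoms")
  nb <- bond_neighbors(graph)
  ang <- list()
  for (v in names(nb)) {
    ns <- nb[[v]]
    if (length(ns) < 2) next
    cmb <- utils::combn(ns, 2)
    for (j in seq_len(ncol(cmb))) {
      u1 <- xyz[cmb[1, j], ] - xyz[v, ]
      u2 <- xyz[cmb[2, j], ] - xyz[v, ]
      cs <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
      ang[[length(ang) + 1]] <- data.frame(
        atom1 = cmb[1, j], vertex = v, atom2 = cmb[2, j],
        angle = acos(max(-1, min(1, cs))) * 180 / pi,
        stringsAsFactors = FALSE)
    }
  }
  list(lengths = lens, angles = do.call(rbind, ang))
}

## adjacency list (in the graph's atom order) from a bond graph
bond_neighbors <- function(graph) {
  atoms <- attr(graph, "atoms")
  if (is.null(atoms)) atoms <- porphyrin_atoms()
  nb <- stats::setNames(vector("list", length(atoms)), atoms)
  for (i in seq_len(nrow(graph))) {
    a <- graph$atom1[i]; b <- graph$atom2[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) v[order(match(v, atoms))])
}

#' Write a structure to an xyz-format file
#'
#' Plain xyz: atom count, a comment line carrying the atom-label order,
#' then one `element x y z` row per atom.
#'
#' @param x `porphyrin_ref`, `heme_entry` or named coordinate matrix.
#' @param path Output file path.
#' @param comment Optional comment; atom labels are always appended.
#' @export
write_xyz <- function(x, path, comment = "") {
  xyz <- if (is.matrix(x)) x else x$xyz
  el <- if (is.matrix(x)) sub("[0-9].*$", "", rownames(xyz)) else x$elements
  lines <- c(nrow(xyz),
             trimws(paste(comment, "atoms:", paste(rownames(xyz), collapse = " "))),
             sprintf("%-2s %18.12f %18.12f %18.12f", el, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an xyz-format file written by [write_xyz()]
#' @param path File path.
#' @return List with `xyz` (named matrix) and `elements`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  labels <- strsplit(sub(".*atoms:", "", lines[2]), "\\s+")[[1]]
  labels <- labels[nzchar(labels)]
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(toks, `[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (length(labels) == n) rownames(xyz) <- labels
  list(xyz = xyz, elements = el)
}

## ---- D4h symmetry operations on the skeleton ------------------------------

## atom permutation under the C4 rotation (ring relabeling A->B->C->D):
## perm[i] = index receiving atom i's (rotated) position/displacement
.c4_perm <- function() {
  atoms <- porphyrin_atoms()
  img <- atoms
  shift <- c(A = "B", B = "C", C = "D", D = "A")
  for (i in seq_along(atoms)) {
    a <- atoms[i]
    ring <- substr(a, nchar(a), nchar(a))
    if (ring %in% names(shift))
      img[i] <- paste0(substr(a, 1, nchar(a) - 1), shift[ring])
  }
  match(img, atoms)
}

## atom permutation under sigma_v (reflection through the xz plane, y -> -y)
.sv_perm <- function() {
  atoms <- porphyrin_atoms()
  map <- c(FE = "FE", "NA" = "NA", NB = "ND", NC = "NC", ND = "NB",
           C1A = "C4A", C2A = "C3A", C3A = "C2A", C4A = "C1A",
           C1B = "C4D", C2B = "C3D", C3B = "C2D", C4B = "C1D",
           C1C = "C4C", C2C = "C3C", C3C = "C2C", C4C = "C1C",
           C1D = "C4B", C2D = "C3B", C3D = "C2B", C4D = "C1B",
           CHA = "CHB", CHB = "CHA", CHC = "CHD", CHD = "CHC")
  match(unname(map[atoms]), atoms)
}

## returns list of operators; each has $perm (atom images) and $mat (3x3)
d4h_operators <- function() {
  c4 <- .c4_perm()
  c2 <- c4[c4]
  sv <- .sv_perm()
  id <- seq_len(25)
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  list(
    C4 = list(perm = c4, mat = Rz90),
    C2 = list(perm = c2, mat = diag(c(-1, -1, 1))),
    sigma_v = list(perm = sv, mat = diag(c(1, -1, 1))),
    sigma_h = list(perm = id, mat = diag(c(1, 1, -1))),
    inversion = list(perm = c2, mat = -diag(3)))
}

## apply a symmetry operator to a 75-component displacement vector
apply_symmetry_op <- function(v, op) {
  m <- matrix(v, nrow = 3)              # columns = atoms, rows = x,y,z
  out <- matrix(0, 3, 25)
  out[, op$perm] <- op$mat %*% m
  as.vector(out)
}

## apply operator to a 25x3 coordinate matrix (configuration map)
apply_symmetry_xyz <- function(xyz, op) {
  out <- xyz
  out[op$perm, ] <- xyz %*% t(op$mat)
  out
}
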