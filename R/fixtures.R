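#' Synthesize a heme with known mode amplitudes
#'
#' Builds coordinates `reference + sum(amplitude_k * mode_k) + noise`,
#' optionally followed by a rigid transform, and wraps them as a
#' `heme_entry`. The injected ground truth is attached as the
#' `ground_truth` attribute, so recovery can be asserted exactly.
#'
#' @param amplitudes Named numeric vector of mode amplitudes in
#'   Angstrom; names must come from [mode_names()].
#' @param ref A `porphyrin_ref`.
#' @param basis A `mode_basis`.
#' @param sigma Standard deviation of isotropic Gaussian coordinate
#'   noise (Angstrom), default 0.
#' @param rotation Optional 3 x 3 rotation applied after distortion.
#' @param translation Optional length-3 translation (Angstrom).
#' @param seed Optional integer seed for the noise (local RNG state;
#'   global state is untouched).
#' @param comp_id Compound ID stored on the entry (default "HEM").
#' @return A `heme_entry` with attribute `ground_truth` (list:
#'   `amplitudes`, `sigma`).
#' @export
make_distorted_heme <- function(amplitudes = numeric(), ref, basis,
                                sigma = 0, rotation = NULL,
                                translation = NULL, seed = NULL,
                                comp_id = "HEM") {
  if (length(amplitudes)) {
    bad <- setdiff(names(amplitudes), mode_names())
    if (length(bad) || is.null(names(amplitudes)))
      stop("unknown mode name(s): ",
           paste(if (is.null(names(amplitudes))) "<unnamed>" else bad,
                 collapse = ", "))
  }
  if (sigma < 0) stop("sigma must be >= 0")
  d <- numeric(75)
  for (nm in names(amplitudes))
    d <- d + amplitudes[[nm]] * basis$vectors[, nm]
  xyz <- ref$xyz + vec_to_xyz(d)
  if (sigma > 0) {
    noise <- withr_seed(seed, function() matrix(stats::rnorm(75, 0, sigma),
                                                25, 3))
    xyz <- xyz + noise
  }
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  if (!is.null(translation)) xyz <- sweep(xyz, 2, translation, "+")
  rownames(xyz) <- porphyrin_atoms()
  structure(list(pdb_id = "SYNT", asym_id = "A", chain_id = "A",
                 residue_index = 1L, comp_id = comp_id, xyz = xyz,
                 sidechain = data.frame(label = character(),
                                        element = character(),
                                        x = numeric(), y = numeric(),
                                        z = numeric(),
                                        stringsAsFactors = FALSE),
                 metadata = NULL),
            class = "heme_entry",
            ground_truth = list(amplitudes = amplitudes, sigma = sigma))
}

## run fn with a local RNG state (seed NULL = use current stream)
withr_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Random rotation matrix (uniform over SO(3))
#' @param seed Optional integer seed (local RNG state).
#' @return 3 x 3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  withr_seed(seed, function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

#' Attach propionate sidechain stubs with prescribed dihedrals
#'
#' Adds CAA/CBA (ring A propionate) and CAD/CBD (ring D propionate) to
#' a heme entry such that the C1A-C2A-CAA-CBA and C4D-C3D-CAD-CBD
#' torsions equal the requested values exactly. Atom placement uses
#' the standard internal-coordinate (Z-matrix) construction with
#' C-C bonds of 1.52 A and tetrahedral-like 113 degree angles.
#'
#' @param heme A `heme_entry`.
#' @param dihedral1,dihedral2 Target torsions in degrees.
#' @return The entry with the four stub atoms appended to `sidechain`.
#' @export
add_propionate_stubs <- function(heme, dihedral1 = -90, dihedral2 = 90) {
  xyz <- heme$xyz
  ## CAA bonded to C2A: place via torsion CHA-ish frame (any reference
  ## giving a well-defined frame works; CBA then sets the dihedral)
  caa <- place_atom_zmatrix(xyz["C1A", ], xyz["C3A", ], xyz["C2A", ],
                            1.52, 122, 180)
  cba <- place_atom_zmatrix(xyz["C1A", ], xyz["C2A", ], caa,
                            1.52, 113, dihedral1)
  cad <- place_atom_zmatrix(xyz["C4D", ], xyz["C2D", ], xyz["C3D", ],
                            1.52, 122, 180)
  cbd <- place_atom_zmatrix(xyz["C4D", ], xyz["C3D", ], cad,
                            1.52, 113, dihedral2)
  stubs <- data.frame(label = c("CAA", "CBA", "CAD", "CBD"),
                      element = "C",
                      x = c(caa[1], cba[1], cad[1], cbd[1]),
                      y = c(caa[2], cba[2], cad[2], cbd[2]),
                      z = c(caa[3], cba[3], cad[3], cbd[3]),
                      stringsAsFactors = FALSE)
  heme$sidechain <- rbind(heme$sidechain, stubs)
  heme
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given positions A, B, C, places D with |CD| = `bond`, angle
#' B-C-D = `angle` and torsion A-B-C-D = `torsion`.
#'
#' @param pa,pb,pc Length-3 coordinates of the three frame atoms.
#' @param bond Bond length C-D (Angstrom).
#' @param angle Angle B-C-D in degrees.
#' @param torsion Torsion A-B-C-D in degrees.
#' @return Length-3 coordinates of D.
#' @export
place_atom_zmatrix <- function(pa, pb, pc, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- pc - pb
  bc <- bc / sqrt(sum(bc^2))
  ab <- pb - pa
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  pc + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a synthetic heme-protein complex fixture
#'
#' Places candidate axial-ligand atoms on the porphyrin normal at
#' declared iron distances and, optionally, a quasi-uniform spherical
#' shell of dummy occluding atoms around the heme (for SASA/coverage
#' tests). Each ligand becomes its own single-atom residue with a
#' distinct residue index; the shell is one residue of dummy carbons.
#'
#' @param heme A `heme_entry` centered like the reference (the normal
#'   is the +z axis of its nitrogen plane).
#' @param ligands data.frame with columns `element`, `distance`
#'   (Angstrom from FE), `face` (+1 or -1 for the two porphyrin
#'   faces), and optionally `comp` (default "LIG"), `atom`.
#' @param shell_radius Radius (or vector of radii, for nested shells)
#'   of the occluding dummy-atom shell, in Angstrom from FE; NULL for
#'   no shell. Each radius must clear the outermost heme atom by 0.5 A;
#'   van der Waals overlap between dummy atoms is deliberate (they are
#'   occluders, not physical atoms).
#' @param shell_n Number of shell atoms per radius (0 for none).
#' @param resolution,keywords Metadata tags written to the fixture.
#' @return Object of class `fixture_complex`: list with `heme`,
#'   `atoms` (data.frame of all non-heme atoms: atom, comp, chain,
#'   resno, entity, element, x, y, z), `resolution`, `keywords`.
#' @export
make_complex_fixture <- function(heme, ligands = NULL, shell_radius = NULL,
                                 shell_n = 0, resolution = 1.8,
                                 keywords = "OXIDOREDUCTASE") {
  fe <- heme$xyz["FE", ]
  rows <- list()
  resno <- 100L
  if (!is.null(ligands) && nrow(ligands)) {
    for (i in seq_len(nrow(ligands))) {
      if (ligands$distance[i] <= 0) stop("ligand distances must be > 0")
      face <- if ("face" %in% names(ligands)) ligands$face[i] else 1
      pos <- fe + c(0, 0, face * ligands$distance[i])
      rows[[length(rows) + 1]] <- data.frame(
        atom = if ("atom" %in% names(ligands) && !is.na(ligands$atom[i]))
                 ligands$atom[i] else toupper(ligands$element[i]),
        comp = if ("comp" %in% names(ligands) && !is.na(ligands$comp[i]))
                 ligands$comp[i] else "LIG",
        chain = "L", resno = resno, entity = "2",
        element = ligands$element[i],
        x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
      resno <- resno + 1L
    }
  }
  if (!is.null(shell_radius) && shell_n > 0) {
    hx <- heme_all_xyz(heme)
    rmax <- max(sqrt(rowSums(sweep(hx, 2, fe)^2)))
    if (any(shell_radius < rmax + 0.5))
      stop("shell radius collides with heme atoms (need > ",
           round(rmax + 0.5, 1), " A)")
    for (sr in shell_radius) {
      pts <- sweep(fibonacci_sphere(shell_n) * sr, 2, fe, "+")
      rows[[length(rows) + 1]] <- data.frame(
        atom = paste0("C", seq_len(shell_n)), comp = "SHL", chain = "S",
        resno = 900L + match(sr, shell_radius), entity = "3", element = "C",
        x = pts[, 1], y = pts[, 2], z = pts[, 3], stringsAsFactors = FALSE)
    }
  }
  atoms <- if (length(rows)) do.call(rbind, rows)
    else data.frame(atom = character(), comp = character(),
                    chain = character(), resno = integer(),
                    entity = character(), element = character(),
                    x = numeric(), y = numeric(), z = numeric(),
                    stringsAsFactors = FALSE)
  structure(list(heme = heme, atoms = atoms, resolution = resolution,
                 keywords = keywords),
            class = "fixture_complex")
}

#' Write a fixture complex as a minimal mmCIF file
#'
#' Emits one data block with `_entry`, `_struct_keywords`, `_refine`,
#' `_exptl`, `_entity` and a fixed-column-order `_atom_site` loop, so
#' extraction on the written file reproduces the fixture exactly.
#' Altloc/model duplication arguments exist to exercise the
#' primary-site selection rules.
#'
#' @param fx A `fixture_complex`.
#' @param path Output path.
#' @param pdb_id Data block name (default "SYNT").
#' @param altloc_atoms Named list: atom label -> character vector of
#'   altloc codes; the atom's record is written once per code (with a
#'   small x-offset per extra copy, so selection is observable).
#' @param extra_model If TRUE, duplicate all heme atoms as model 2
#'   records shifted by 5 A.
#' @param drop_atoms Atom labels omitted from the heme (to break the
#'   intactness rule on purpose).
#' @return `path`, invisibly.
#' @export
write_fixture_mmcif <- function(fx, path, pdb_id = "SYNT",
                                altloc_atoms = NULL, extra_model = FALSE,
                                drop_atoms = character()) {
  heme <- fx$heme
  hx <- heme_all_xyz(heme)
  hel <- heme_all_elements(heme)
  keep <- !(rownames(hx) %in% drop_atoms)
  hx <- hx[keep, , drop = FALSE]; hel <- hel[keep]

  rows <- list()
  add <- function(group, atom, alt, comp, asym, entity, chain, resno,
                  model, element, p) {
    rows[[length(rows) + 1]] <<- sprintf(
      "%-6s %d %-2s %-4s %s %-3s %s %s %s %d %.9f %.9f %.9f 1.00 0.00 %d",
      group, length(rows) + 1, element, atom, alt, comp, asym, entity,
      chain, resno, p[1], p[2], p[3], model)
  }
  for (i in seq_len(nrow(hx))) {
    lab <- rownames(hx)[i]
    alts <- if (!is.null(altloc_atoms) && lab %in% names(altloc_atoms))
      altloc_atoms[[lab]] else "."
    for (k in seq_along(alts)) {
      p <- hx[i, ] + c(0.05 * (k - 1), 0, 0)
      add("HETATM", lab, alts[k], heme$comp_id, "B", "1", heme$chain_id,
          heme$residue_index, 1L, toupper(hel[i]), p)
    }
    if (extra_model)
      add("HETATM", lab, ".", heme$comp_id, "B", "1", heme$chain_id,
          heme$residue_index, 2L, toupper(hel[i]), hx[i, ] + c(5, 0, 0))
  }
  if (nrow(fx$atoms)) for (i in seq_len(nrow(fx$atoms))) {
    a <- fx$atoms[i, ]
    add("ATOM", a$atom, ".", a$comp, a$chain, a$entity, a$chain, a$resno,
        1L, toupper(a$element), c(a$x, a$y, a$z))
  }

  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("data_", pdb_id),
    "#",
    sprintf("_entry.id %s", pdb_id),
    sprintf("_struct_keywords.pdbx_keywords '%s'", fx$keywords),
    if (!is.null(fx$resolution) && !is.na(fx$resolution))
      sprintf("_refine.ls_d_res_high %.2f", fx$resolution),
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_pdbx_database_status.recvd_initial_deposition_date 2020-01-01",
    "#",
    "loop_",
    "_entity.id",
    "_entity.pdbx_description",
    "_entity.pdbx_ec",
    "1 'PROTOPORPHYRIN IX CONTAINING FE' ?",
    "2 'synthetic axial ligand' 1.14.13.39",
    "3 'occluding shell' ?",
    "#",
    "loop_",
    "_entity_src_gen.entity_id",
    "_entity_src_gen.pdbx_gene_src_scientific_name",
    "2 'Physeter macrocephalus (sperm whale)'",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    unlist(rows),
    "#"), con)
  invisible(path)
}
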