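## shared, lazily built objects (the mode basis costs ~1 s to construct)
.cache <- new.env(parent = emptyenv())

test_ref <- function() {
  if (is.null(.cache$ref)) .cache$ref <- build_reference_porphine()
  .cache$ref
}

test_basis <- function() {
  if (is.null(.cache$basis)) .cache$basis <- build_mode_basis(test_ref())
  .cache$basis
}

## worst-case projection cross-talk of the basis onto mode `name`
crosstalk_bound <- function(basis, amplitudes) {
  g <- basis$gram
  offdiag <- abs(g - diag(diag(g)))
  sum(vapply(names(amplitudes), function(nm)
    abs(amplitudes[[nm]]) * max(offdiag[, nm]), 0))
}

## minimal hand-written mmCIF content builder for parser edge cases
cif_text <- function(atom_rows, header = character()) {
  c("data_TEST",
    header,
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
    "_atom_site.pdbx_PDB_model_num",
    atom_rows)
}

## atom row for cif_text
cif_row <- function(atom, x, y, z, comp = "HEM", alt = ".", asym = "B",
                    chain = "A", resno = 1, model = 1, element = "C",
                    group = "HETATM", entity = "1", id = 1) {
  sprintf("%s %d %s %s %s %s %s %s %s %d %.6f %.6f %.6f %d",
          group, id, element, atom, alt, comp, asym, entity, chain,
          resno, x, y, z, model)
}

## rows for a complete heme skeleton taken from a coordinate matrix
cif_skeleton_rows <- function(xyz, comp = "HEM", chain = "A", resno = 1,
                              asym = "B", ...) {
  el <- toupper(porphyrin_elements())
  vapply(seq_len(25), function(i)
    cif_row(porphyrin_atoms()[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
            comp = comp, chain = chain, resno = resno, asym = asym,
            element = el[i], id = i, ...), "")
}
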