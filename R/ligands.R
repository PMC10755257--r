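#' Identify the axial ligands of a heme
#'
#' A candidate ligand is any residue or small molecule (grouped by
#' chain + residue index) with at least one atom within `cutoff` of the
#' heme iron; its coordination distance is the minimum over its atoms
#' and the coordinating atom is the one achieving it. When more than
#' two candidates fall inside the cutoff, the two nearest are kept
#' (coordination number is capped at 2); ties break deterministically
#' by (distance, chain, residue index). The heme's own atoms never
#' count; waters and other small molecules do, unless excluded via
#' `exclude_comps`.
#'
#' @param heme A `heme_entry` (the FE coordinate is taken from it).
#' @param neighbors data.frame of surrounding atom records (columns
#'   `atom`, `comp`, `chain`, `resno`, `x`, `y`, `z`, optionally
#'   `entity`, `asym`), e.g. from [mmcif_atoms()]; the heme's own
#'   residue is removed automatically if present.
#' @param cutoff Iron-distance cutoff in Angstrom (default 3.1).
#' @param exclude_comps Compound IDs never counted as ligands
#'   (default none; pass e.g. "HOH" to drop waters).
#' @return Object of class `ligand_annotation`: list with `ligands`
#'   (data.frame sorted ascending by distance: comp, chain, resno,
#'   atom, distance, entity, x, y, z of the coordinating atom) and
#'   `coordination` (0, 1 or 2).
#' @export
find_axial_ligands <- function(heme, neighbors, cutoff = 3.1,
                               exclude_comps = character()) {
  fe <- skeleton_xyz(heme)["FE", ]
  nb <- neighbors
  ## drop the heme's own residue
  if (all(c("chain", "resno", "comp") %in% names(nb)))
    nb <- nb[!(nb$comp %in% heme$comp_id &
               nb$chain == heme$chain_id &
               nb$resno == heme$residue_index), , drop = FALSE]
  if (length(exclude_comps))
    nb <- nb[!(nb$comp %in% exclude_comps), , drop = FALSE]
  empty <- data.frame(comp = character(), chain = character(),
                      resno = integer(), atom = character(),
                      distance = numeric(), entity = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(nb) || !nrow(nb))
    return(structure(list(ligands = empty, coordination = 0L),
                     class = "ligand_annotation"))
  d <- sqrt((nb$x - fe[1])^2 + (nb$y - fe[2])^2 + (nb$z - fe[3])^2)
  key <- paste(nb$chain, nb$resno, sep = "\r")
  cand <- lapply(split(seq_len(nrow(nb)), key), function(idx) {
    k <- idx[which.min(d[idx])]
    data.frame(comp = nb$comp[k], chain = nb$chain[k], resno = nb$resno[k],
               atom = nb$atom[k], distance = d[k],
               entity = if ("entity" %in% names(nb)) nb$entity[k]
                        else NA_character_,
               x = nb$x[k], y = nb$y[k], z = nb$z[k],
               stringsAsFactors = FALSE)
  })
  lig <- do.call(rbind, cand)
  lig <- lig[lig$distance <= cutoff, , drop = FALSE]
  lig <- lig[order(lig$distance, lig$chain, lig$resno), , drop = FALSE]
  if (nrow(lig) > 2) lig <- lig[1:2, , drop = FALSE]
  rownames(lig) <- NULL
  structure(list(ligands = lig, coordination = nrow(lig)),
            class = "ligand_annotation")
}

#' @export
print.ligand_annotation <- function(x, ...) {
  cat("coordination number:", x$coordination, "\n")
  if (x$coordination)
    print(x$ligands[, c("comp", "chain", "resno", "atom", "distance")])
  invisible(x)
}

#' Normalize an organism name to its first two words
#'
#' Scientific names in structure files often carry strain or
#' common-name decorations; only the first two whitespace-delimited
#' words (genus + species) are kept. Single-word names pass unchanged;
#' NA and empty input return NA.
#'
#' @param raw Organism string (vectorized).
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_organism("Physeter macrocephalus (sperm whale)")
normalize_organism <- function(raw) {
  vapply(raw, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    words <- strsplit(trimws(s), "\\s+")[[1]]
    paste(words[seq_len(min(2, length(words)))], collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Truncate an EC number to its first three class labels
#'
#' "1.14.13.39" becomes "1.14.13"; shorter inputs are unchanged; NA and
#' empty input return NA.
#'
#' @param raw EC number string (vectorized).
#' @return Character vector of the same length.
#' @export
#' @examples
#' truncate_ec("1.14.13.39")
truncate_ec <- function(raw) {
  vapply(raw, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    labs <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    paste(labs[seq_len(min(3, length(labs)))], collapse = ".")
  }, "", USE.NAMES = FALSE)
}

#' Annotate axial ligands with entity-level metadata from an mmCIF
#'
#' Adds compound description, normalized organism and truncated EC
#' number per ligand, looked up by entity ID from `_entity`,
#' `_entity_src_gen` (falling back to `_entity_src_nat`). Optional
#' local UniProt/CATH mapping tables (TSV with columns `chain`, `id`)
#' can be joined on the ligand chain; no network access is ever used.
#'
#' @param annotation A `ligand_annotation`.
#' @param cif The `mmcif` object the neighbors came from.
#' @param uniprot_map,cath_map Optional data.frames (columns `chain`,
#'   `id`).
#' @return The annotation with columns `description`, `organism`, `ec`,
#'   `uniprot`, `cath` added to its `ligands` table.
#' @export
annotate_ligands <- function(annotation, cif, uniprot_map = NULL,
                             cath_map = NULL) {
  lig <- annotation$ligands
  n <- nrow(lig)
  ent <- mmcif_category(cif, "entity")
  src_gen <- mmcif_category(cif, "entity_src_gen")
  src_nat <- mmcif_category(cif, "entity_src_nat")
  look <- function(df, idcol, valcol, ids) {
    if (is.null(df) || !all(c(idcol, valcol) %in% names(df)))
      return(rep(NA_character_, length(ids)))
    v <- df[[valcol]][match(ids, df[[idcol]])]
    ifelse(is.na(v) | v %in% c(".", "?"), NA_character_, v)
  }
  desc <- look(ent, "id", "pdbx_description", lig$entity)
  ec <- look(ent, "id", "pdbx_ec", lig$entity)
  org <- look(src_gen, "entity_id", "pdbx_gene_src_scientific_name",
              lig$entity)
  org2 <- look(src_nat, "entity_id", "pdbx_organism_scientific", lig$entity)
  org[is.na(org)] <- org2[is.na(org)]
  join <- function(map, chains) {
    if (is.null(map)) return(rep(NA_character_, length(chains)))
    map$id[match(chains, map$chain)]
  }
  lig$description <- desc
  lig$organism <- normalize_organism(org)
  lig$ec <- truncate_ec(ec)
  lig$uniprot <- join(uniprot_map, lig$chain)
  lig$cath <- join(cath_map, lig$chain)
  annotation$ligands <- lig
  annotation
}
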