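#' Compound IDs recognized as hemes
#' @return Character vector: HEM, HEA, HEB, HEC, HEO.
#' @export
heme_comp_ids <- function() c("HEM", "HEA", "HEB", "HEC", "HEO")

#' Reduce duplicate atom records to the primary site
#'
#' Applies the selection rule for multi-model / alternate-location
#' data: only records from PDB model number 1 are used, and where
#' several alternate locations exist for one atom the '.' record is
#' kept if present, else the 'A' record; atoms present only with other
#' altloc codes are treated as missing.
#'
#' @param records data.frame of atom records (from [mmcif_atoms()]).
#' @return data.frame with at most one record per
#'   (asym, chain, resno, comp, atom) identity.
#' @export
select_primary_sites <- function(records) {
  if (!nrow(records)) return(records)
  first_model <- min(records$model, na.rm = TRUE)
  r <- records[records$model == first_model, , drop = FALSE]
  key <- paste(r$asym, r$chain, r$resno, r$comp, r$atom, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(r)), key), function(idx) {
    al <- r$altloc[idx]
    if (any(al == ".")) idx[which(al == ".")[1]]
    else if (any(al == "A")) idx[which(al == "A")[1]]
    else integer(0)
  }), use.names = FALSE)
  r[sort(keep), , drop = FALSE]
}

#' Extract heme entries from an mmCIF structure
#'
#' Locates residues with heme compound IDs (HEM, HEA, HEB, HEC, HEO),
#' applies the primary-site selection ([select_primary_sites()]) and
#' keeps only hemes whose iron + porphyrin ring data are intact (all 25
#' skeleton atoms with finite coordinates). Hemes failing the
#' intactness check are skipped; the skip log is attached as the
#' `skipped` attribute (data.frame with identity and reason).
#'
#' @param cif An `mmcif` object or a file path.
#' @param comp_ids Compound IDs to treat as hemes.
#' @param metadata If TRUE (default), attach entry metadata from
#'   [collect_entry_metadata()] to each entry.
#' @return List of `heme_entry` objects. Each has fields `pdb_id`,
#'   `asym_id`, `chain_id`, `residue_index`, `comp_id`, `xyz` (25 x 3,
#'   canonical order, coordinates bit-identical to the file),
#'   `sidechain` (data.frame of the residue's non-skeleton atoms) and
#'   `metadata`.
#' @export
find_hemes <- function(cif, comp_ids = heme_comp_ids(), metadata = TRUE) {
  if (is.character(cif)) cif <- read_mmcif(cif)
  atoms <- select_primary_sites(mmcif_atoms(cif))
  meta <- if (metadata) collect_entry_metadata(cif) else NULL
  pdb_id <- attr(cif, "data_block")

  hm <- atoms[atoms$comp %in% comp_ids, , drop = FALSE]
  entries <- list()
  skipped <- list()
  if (nrow(hm)) {
    key <- paste(hm$asym, hm$chain, hm$resno, hm$comp, sep = "\r")
    for (grp in split(seq_len(nrow(hm)), key)) {
      res <- hm[grp, , drop = FALSE]
      id <- res[1, c("asym", "chain", "resno", "comp")]
      present <- match(porphyrin_atoms(), res$atom)
      if (any(is.na(present))) {
        skipped[[length(skipped) + 1]] <- data.frame(
          pdb_id = pdb_id, asym_id = id$asym, chain_id = id$chain,
          residue_index = id$resno, comp_id = id$comp,
          reason = paste("incomplete skeleton: missing",
                         paste(porphyrin_atoms()[is.na(present)],
                               collapse = " ")),
          stringsAsFactors = FALSE)
        next
      }
      xyz <- as.matrix(res[present, c("x", "y", "z")])
      dimnames(xyz) <- list(porphyrin_atoms(), NULL)
      side <- res[-present, c("atom", "element", "x", "y", "z"), drop = FALSE]
      names(side)[1] <- "label"
      rownames(side) <- NULL
      entries[[length(entries) + 1]] <- structure(
        list(pdb_id = pdb_id, asym_id = id$asym, chain_id = id$chain,
             residue_index = id$resno, comp_id = id$comp,
             xyz = xyz, sidechain = side, entity = res$entity[1],
             metadata = meta),
        class = "heme_entry")
    }
  }
  ## deterministic order: asym, chain, residue index
  if (length(entries)) {
    ord <- order(vapply(entries, `[[`, "", "asym_id"),
                 vapply(entries, `[[`, "", "chain_id"),
                 vapply(entries, `[[`, 0L, "residue_index"))
    entries <- entries[ord]
  }
  attr(entries, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(pdb_id = character(), asym_id = character(),
                    chain_id = character(), residue_index = integer(),
                    comp_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  entries
}

#' @export
print.heme_entry <- function(x, ...) {
  cat("heme_entry:", x$comp_id, "in", x$pdb_id,
      sprintf("(asym %s, chain %s, residue %s)",
              x$asym_id, x$chain_id, x$residue_index), "\n")
  cat("  25 skeleton atoms +", nrow(x$sidechain), "sidechain atom(s)\n")
  invisible(x)
}

#' Collect per-entry metadata from an mmCIF header
#'
#' Structural keywords, resolution, experimental method and deposition
#' date. Missing categories map to explicit NA values, never a guess.
#' The resolution is taken from `_refine.ls_d_res_high`, falling back
#' to `_reflns.d_resolution_high`.
#'
#' @param cif An `mmcif` object or path.
#' @param function_map Optional data.frame (columns `keyword`,
#'   `fun`) mapping structural keywords to function labels; defaults
#'   to the table shipped with the package. Unmapped keywords yield NA.
#' @return List with `pdb_id`, `keywords`, `fun` (mapped function
#'   label), `resolution` (Angstrom), `method`, `deposition_date`.
#' @export
collect_entry_metadata <- function(cif, function_map = NULL) {
  if (is.character(cif)) cif <- read_mmcif(cif)
  kw <- mmcif_category(cif, "struct_keywords")
  keywords <- if (!is.null(kw) && "pdbx_keywords" %in% names(kw))
    kw$pdbx_keywords[1] else NA_character_
  refine <- mmcif_category(cif, "refine")
  reflns <- mmcif_category(cif, "reflns")
  res <- NA_real_
  if (!is.null(refine) && "ls_d_res_high" %in% names(refine))
    res <- suppressWarnings(as.numeric(refine$ls_d_res_high[1]))
  if (is.na(res) && !is.null(reflns) && "d_resolution_high" %in% names(reflns))
    res <- suppressWarnings(as.numeric(reflns$d_resolution_high[1]))
  ex <- mmcif_category(cif, "exptl")
  method <- if (!is.null(ex) && "method" %in% names(ex)) ex$method[1]
            else NA_character_
  st <- mmcif_category(cif, "pdbx_database_status")
  dep <- if (!is.null(st) && "recvd_initial_deposition_date" %in% names(st))
    st$recvd_initial_deposition_date[1] else NA_character_
  list(pdb_id = attr(cif, "data_block"),
       keywords = keywords,
       fun = map_function_keyword(keywords, function_map),
       resolution = res, method = method, deposition_date = dep)
}

#' Map a structural keyword to a function label
#'
#' Uses a user-editable keyword-to-function table (shipped as
#' `extdata/function_keywords.tsv`; matching is case-insensitive on the
#' keyword). Unknown keywords return NA (they pass through unmapped).
#'
#' @param keyword Keyword string (e.g. "OXIDOREDUCTASE").
#' @param map Optional replacement mapping data.frame with columns
#'   `keyword` and `fun`.
#' @return Function label or NA.
#' @export
map_function_keyword <- function(keyword, map = NULL) {
  if (is.null(map)) map <- default_function_map()
  if (is.na(keyword)) return(NA_character_)
  hit <- match(toupper(trimws(keyword)), toupper(map$keyword))
  if (is.na(hit)) NA_character_ else map$fun[hit]
}

default_function_map <- function() {
  path <- system.file("extdata", "function_keywords.tsv", package = "hemeNSD")
  if (!nzchar(path)) path <- "inst/extdata/function_keywords.tsv"
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Export heme entries to a CSV table
#'
#' One row per entry with identity, metadata, and (optionally) NSD and
#' descriptor columns when `ref`/`basis` are given. Writing the same
#' entries twice produces byte-identical files.
#'
#' @param hemes List of `heme_entry` objects.
#' @param path Output CSV path.
#' @param ref,basis Optional reference and mode basis to add the 12 NSD
#'   amplitude columns.
#' @return The table, invisibly.
#' @export
entries_to_csv <- function(hemes, path, ref = NULL, basis = NULL) {
  base <- do.call(rbind, lapply(hemes, function(h) {
    md <- h$metadata
    pro <- propionate_dihedrals(h)
    data.frame(pdb_id = h$pdb_id, asym_id = h$asym_id, chain_id = h$chain_id,
               residue_index = h$residue_index, comp_id = h$comp_id,
               resolution = if (is.null(md)) NA_real_ else md$resolution,
               method = if (is.null(md)) NA_character_ else md$method,
               keywords = if (is.null(md)) NA_character_ else md$keywords,
               protein_function = if (is.null(md)) NA_character_ else md$fun,
               deposition_date = if (is.null(md)) NA_character_
                                 else md$deposition_date,
               d_oop = as.numeric(out_of_plane_displacement(h)),
               dihedral1 = pro$dihedral1, dihedral2 = pro$dihedral2,
               orientation1 = pro$orientation1,
               orientation2 = pro$orientation2,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ref) && !is.null(basis))
    base <- cbind(base, nsd_table(hemes, ref, basis)[, mode_names()])
  utils::write.csv(base, path, row.names = FALSE, quote = TRUE)
  invisible(base)
}
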