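## Minimal mmCIF reader: parses every category (scalar key-value blocks
## and loop_ tables) of the first data block into character data frames.
## Covers the STAR subset that PDB-distributed mmCIF files use for the
## categories this package reads (_atom_site, _entity, _entity_src_*,
## _struct_keywords, _refine, _reflns, _exptl, _pdbx_database_status).

## split one line into STAR tokens, honoring '...' and "..." quoting and
## a trailing # comment
.cif_tokens <- function(line) {
  toks <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      repeat {
        k <- regexpr(ch, substr(line, j, n), fixed = TRUE)
        if (k < 0) { j <- n + 1L; break }       # unterminated: take rest
        j <- j + k - 1L
        nxt <- substr(line, j + 1L, j + 1L)
        if (nxt == "" || grepl("^\\s$", nxt)) break
        j <- j + 1L
      }
      toks <- c(toks, substr(line, i + 1L, min(j, n) - 1L))
      i <- j + 1L
    } else {
      m <- regexpr("[^\\s]+", substr(line, i, n), perl = TRUE)
      len <- attr(m, "match.length")
      toks <- c(toks, substr(line, i, i + len - 1L))
      i <- i + len
    }
  }
  toks
}

#' Read an mmCIF file into per-category tables
#'
#' Parses the first data block: every category becomes a character
#' data.frame (one row for scalar key-value categories, several for
#' `loop_` tables), with the item names (after the dot) as columns.
#' Multi-line semicolon text fields are supported.
#'
#' @param path Path to an mmCIF file.
#' @return Object of class `mmcif`: named list of data.frames plus a
#'   `data_block` attribute with the block name (usually the PDB id).
#' @export
read_mmcif <- function(path) {
  if (!file.exists(path)) stop("cannot read mmCIF file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^data_", lines)))
    stop("format error: no data block in ", path)

  ## fold semicolon text fields into single quoted tokens first
  out_lines <- character(length(lines)); oi <- 0L
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ";")) {
      val <- sub("^;", "", lines[i])
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[i], ";")) {
        val <- paste(val, lines[i]); i <- i + 1L
      }
      i <- i + 1L
      oi <- oi + 1L
      out_lines[oi] <- paste0("'", gsub("'", " ", trimws(val)), "'")
    } else {
      oi <- oi + 1L; out_lines[oi] <- lines[i]; i <- i + 1L
    }
  }
  lines <- out_lines[seq_len(oi)]

  block <- NULL
  cats <- list()     # category -> list(items = chr, values = chr)
  i <- 1L
  n <- length(lines)
  tok_stream <- function(start, stop_at_tag) {
    ## collect data tokens from line `start` until a control line
    vals <- character(); j <- start
    while (j <= n) {
      l <- trimws(lines[j])
      if (l == "" || startsWith(l, "#")) { j <- j + 1L; next }
      if (grepl("^(_|loop_|data_|stop_|save_)", l)) break
      vals <- c(vals, .cif_tokens(lines[j]))
      j <- j + 1L
    }
    list(values = vals, next_line = j)
  }
  while (i <= n) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#")) { i <- i + 1L; next }
    if (startsWith(l, "data_")) {
      if (!is.null(block)) break                 # first block only
      block <- sub("^data_", "", l); i <- i + 1L; next
    }
    if (l == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, .cif_tokens(trimws(lines[i]))[1]); i <- i + 1L
      }
      ts <- tok_stream(i, TRUE)
      i <- ts$next_line
      if (!length(tags)) next
      cat_name <- sub("\\..*$", "", sub("^_", "", tags[1]))
      items <- sub("^[^.]*\\.", "", tags)
      vals <- ts$values
      if (length(vals) %% length(tags) != 0) {
        vals <- vals[seq_len(length(vals) %/% length(tags) * length(tags))]
      }
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- items
      cats[[cat_name]] <- if (is.null(cats[[cat_name]])) df
                          else rbind(cats[[cat_name]], df)
      next
    }
    if (grepl("^_", l)) {
      toks <- .cif_tokens(l)
      tag <- toks[1]
      if (length(toks) >= 2) {
        val <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else {
        ts <- tok_stream(i + 1L, TRUE)
        val <- if (length(ts$values)) ts$values[1] else NA_character_
        i <- ts$next_line
      }
      cat_name <- sub("\\..*$", "", sub("^_", "", tag))
      item <- sub("^[^.]*\\.", "", tag)
      if (is.null(cats[[cat_name]]))
        cats[[cat_name]] <- data.frame(row.names = 1)
      cats[[cat_name]][[item]] <- val
      next
    }
    i <- i + 1L
  }
  structure(cats, data_block = block, class = "mmcif")
}

#' @export
print.mmcif <- function(x, ...) {
  cat("mmCIF data block:", attr(x, "data_block"), "-",
      length(x), "categories\n")
  for (nm in names(x))
    cat(" ", nm, ":", nrow(x[[nm]]), "row(s),", ncol(x[[nm]]), "item(s)\n")
  invisible(x)
}

## pull a category table; NULL if absent
mmcif_category <- function(cif, name) {
  if (name %in% names(cif)) cif[[name]] else NULL
}

## get a column with a default when the item is absent
.col_or <- function(df, item, default) {
  if (!is.null(df) && item %in% names(df)) df[[item]]
  else rep(default, if (is.null(df)) 0L else nrow(df))
}

#' Atom records of an mmCIF file as a typed data frame
#'
#' Extracts `_atom_site` with the identity fields the selection rules
#' need. Missing optional items get explicit defaults (model 1, altloc
#' '.').
#'
#' @param cif An `mmcif` object from [read_mmcif()] (or a path).
#' @return data.frame with columns `group`, `atom`, `altloc`, `comp`,
#'   `asym`, `entity`, `chain`, `resno`, `model`, `element`, `x`, `y`,
#'   `z`.
#' @export
mmcif_atoms <- function(cif) {
  if (is.character(cif)) cif <- read_mmcif(cif)
  as_ <- mmcif_category(cif, "atom_site")
  if (is.null(as_) || !nrow(as_)) stop("format error: no _atom_site table")
  need <- c("label_atom_id", "label_comp_id", "Cartn_x", "Cartn_y", "Cartn_z")
  if (!all(need %in% names(as_)))
    stop("format error: _atom_site lacks required item(s): ",
         paste(setdiff(need, names(as_)), collapse = ", "))
  n <- nrow(as_)
  resno_raw <- .col_or(as_, "auth_seq_id", NA_character_)
  if (all(is.na(resno_raw))) resno_raw <- .col_or(as_, "label_seq_id", NA)
  df <- data.frame(
    group  = .col_or(as_, "group_PDB", rep("ATOM", n)),
    atom   = as_$label_atom_id,
    altloc = .col_or(as_, "label_alt_id", rep(".", n)),
    comp   = as_$label_comp_id,
    asym   = .col_or(as_, "label_asym_id", rep("A", n)),
    entity = .col_or(as_, "label_entity_id", rep(NA_character_, n)),
    chain  = .col_or(as_, "auth_asym_id", .col_or(as_, "label_asym_id",
                                                  rep("A", n))),
    resno  = suppressWarnings(as.integer(resno_raw)),
    model  = suppressWarnings(as.integer(
      .col_or(as_, "pdbx_PDB_model_num", rep("1", n)))),
    element = .col_or(as_, "type_symbol", rep(NA_character_, n)),
    x = as.numeric(as_$Cartn_x),
    y = as.numeric(as_$Cartn_y),
    z = as.numeric(as_$Cartn_z),
    stringsAsFactors = FALSE)
  df$altloc[is.na(df$altloc) | df$altloc %in% c("", "?")] <- "."
  df$model[is.na(df$model)] <- 1L
  if (any(!is.finite(df$x + df$y + df$z)))
    stop("format error: non-finite atom coordinates")
  ## normalize element capitalization ("FE" -> "Fe")
  df$element <- ifelse(is.na(df$element), NA,
                       paste0(toupper(substr(df$element, 1, 1)),
                              tolower(substr(df$element, 2, 10))))
  df
}
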