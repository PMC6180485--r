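#' Read a cross-link table
#'
#' Loads a CSV of residue-pair cross-links into the package's column
#' convention (`protein_a`, `residue_a`, `protein_b`, `residue_b`,
#' `e_value`, optional `count`).  Arbitrary exports (e.g. pLink-style) are
#' accommodated through `column_map`, naming which input column supplies
#' each convention column.
#'
#' @param path CSV file.
#' @param column_map Named character vector, convention name -> input column
#'   name; defaults to the identity mapping.
#' @return Tibble of cross-links.
#' @export
read_crosslinks <- function(path, column_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    missing <- setdiff(unname(column_map), names(df))
    if (length(missing)) {
      abort(sprintf("column(s) %s not found in '%s'",
                    paste(missing, collapse = ", "), path))
    }
    for (std in names(column_map)) df[[std]] <- df[[column_map[[std]]]]
  }
  need <- c("protein_a", "residue_a", "protein_b", "residue_b")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("cross-link table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df$residue_a <- as.integer(df$residue_a)
  df$residue_b <- as.integer(df$residue_b)
  if (any(df$residue_a < 1 | df$residue_b < 1, na.rm = TRUE)) {
    abort("residue numbers must be >= 1")
  }
  as_tibble(df)
}

#' Filter cross-links by E-value and collapse duplicates
#'
#' Keeps rows with `e_value` strictly below `e_max` (boundary values are
#' removed), then collapses duplicate residue pairs — compared as unordered
#' pairs, so A:10--B:20 and B:20--A:10 are the same link — summing their
#' `count` (1 per row when absent) and keeping each pair's smallest E-value.
#'
#' @param links Cross-link tibble (see [read_crosslinks()]).
#' @param e_max E-value cutoff, default `1e-5`.
#' @return Filtered, deduplicated tibble sorted by protein/residue.
#' @export
filter_links <- function(links, e_max = 1e-5) {
  if (!"e_value" %in% names(links)) abort("`links` lacks an `e_value` column")
  if (!is.numeric(e_max) || e_max <= 0) abort("`e_max` must be positive")
  if (!"count" %in% names(links)) links$count <- 1L
  kept <- filter(links, .data$e_value < e_max)
  if (nrow(kept) == 0L) return(kept)
  ka <- paste(kept$protein_a, kept$residue_a, sep = ":")
  kb <- paste(kept$protein_b, kept$residue_b, sep = ":")
  flip <- ka > kb
  key_a <- ifelse(flip, kb, ka)
  key_b <- ifelse(flip, ka, kb)
  kept$.key <- paste(key_a, key_b, sep = "--")
  kept |>
    group_by(.data$.key) |>
    summarise(protein_a = .data$protein_a[1], residue_a = .data$residue_a[1],
              protein_b = .data$protein_b[1], residue_b = .data$residue_b[1],
              e_value = min(.data$e_value), count = sum(.data$count),
              .groups = "drop") |>
    select(-".key") |>
    arrange(.data$protein_a, .data$residue_a, .data$protein_b, .data$residue_b)
}

#' Read Calpha coordinates from a structure file
#'
#' Parses a PDB (via bio3d) or mmCIF file into one Calpha record per
#' residue.  Only the first model is used; for alternate locations the
#' highest-occupancy altloc is kept; insertion codes are not supported and
#' raise an error.  Residue numbers are the author numbering of the file.
#'
#' @param path Structure file (`.pdb`, `.ent`, or `.cif`).
#' @return Tibble with `chain`, `resno`, `x`, `y`, `z`.
#' @export
read_ca_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("structure file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  atoms <- if (ext == "cif") read_cif_atoms(path) else read_pdb_atoms(path)
  ca <- atoms |>
    filter(.data$atom == "CA") |>
    arrange(.data$chain, .data$resno, dplyr::desc(.data$occupancy)) |>
    distinct(.data$chain, .data$resno, .keep_all = TRUE)
  if (nrow(ca) == 0L) abort(sprintf("no Calpha atoms found in '%s'", path))
  select(ca, "chain", "resno", "x", "y", "z")
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    abort("insertion codes are not supported")
  }
  tibble(atom = at$elety, chain = at$chain, resno = as.integer(at$resno),
         x = at$x, y = at$y, z = at$z,
         occupancy = ifelse(is.na(at$o), 1, at$o))
}

# Minimal mmCIF atom_site reader (no installed R package parses mmCIF):
# locates the _atom_site loop, reads its whitespace-delimited rows, and
# keeps first-model ATOM records.
read_cif_atoms <- function(path) {
  lines <- readr::read_lines(path)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) abort(sprintf("no _atom_site loop in '%s'", path))
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    body <- c(body, ln)
  }
  fields <- strsplit(body, "[ \t]+")
  bad <- which(lengths(fields) != length(cols))
  if (length(bad)) abort(sprintf("malformed _atom_site row %d in '%s'", bad[1], path))
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  get <- function(name, default = NULL) {
    if (name %in% cols) m[, name] else default
  }
  ins <- get("pdbx_PDB_ins_code")
  if (!is.null(ins) && any(!ins %in% c("?", ".", ""))) {
    abort("insertion codes are not supported")
  }
  model <- get("pdbx_PDB_model_num", rep("1", nrow(m)))
  keep <- get("group_PDB", rep("ATOM", nrow(m))) == "ATOM" & model == model[1]
  chain <- get("auth_asym_id", get("label_asym_id"))
  resno <- get("auth_seq_id", get("label_seq_id"))
  occ <- get("occupancy", rep("1", nrow(m)))
  tibble(atom = get("label_atom_id")[keep], chain = chain[keep],
         resno = as.integer(resno[keep]),
         x = as.numeric(m[keep, "Cartn_x"]), y = as.numeric(m[keep, "Cartn_y"]),
         z = as.numeric(m[keep, "Cartn_z"]),
         occupancy = suppressWarnings(as.numeric(occ[keep])))
}

#' Map cross-links onto a structure and test the distance restraint
#'
#' Annotates each link with the Calpha-Calpha Euclidean distance between its
#' two residues and whether it satisfies the crosslinker restraint
#' (default 30 angstrom).  Links whose residues cannot be located are
#' flagged `"unmapped"`, never dropped.
#'
#' @param links Cross-link tibble.
#' @param structure Calpha tibble from [read_ca_structure()].
#' @param chain_map Named vector, protein name -> chain ID.
#' @param cutoff Satisfaction cutoff, angstroms.
#' @return The links with `distance` and `status`
#'   (`satisfied`/`violated`/`unmapped`) columns; satisfaction counts in
#'   attribute `"summary"`.
#' @export
map_distances <- function(links, structure, chain_map, cutoff = 30) {
  need <- c("protein_a", "residue_a", "protein_b", "residue_b")
  stopifnot(all(need %in% names(links)))
  unknown <- setdiff(unique(c(links$protein_a, links$protein_b)), names(chain_map))
  if (length(unknown)) {
    abort(sprintf("no chain mapping for protein(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(unname(chain_map), unique(structure$chain))
  if (length(absent)) {
    abort(sprintf("chain(s) %s absent from the structure",
                  paste(absent, collapse = ", ")))
  }
  key <- paste(structure$chain, structure$resno)
  locate <- function(protein, resno) match(paste(chain_map[protein], resno), key)
  ia <- locate(links$protein_a, links$residue_a)
  ib <- locate(links$protein_b, links$residue_b)
  d <- sqrt((structure$x[ia] - structure$x[ib])^2 +
              (structure$y[ia] - structure$y[ib])^2 +
              (structure$z[ia] - structure$z[ib])^2)
  links$distance <- d
  links$status <- dplyr::case_when(
    is.na(d) ~ "unmapped",
    d <= cutoff ~ "satisfied",
    TRUE ~ "violated")
  attr(links, "summary") <- c(satisfied = sum(links$status == "satisfied"),
                              violated = sum(links$status == "violated"),
                              unmapped = sum(links$status == "unmapped"))
  links
}

#' Extract inter-chain residue contacts from a structure
#'
#' All residue pairs between two chain sets whose Calpha-Calpha distance is
#' at most `cutoff` (default 15 angstrom), sorted deterministically.
#'
#' @param structure Calpha tibble from [read_ca_structure()].
#' @param chains_a,chains_b Non-empty, disjoint chain ID sets.
#' @param cutoff Contact cutoff, angstroms.
#' @return Tibble of contacts: `chain_a`, `residue_a`, `chain_b`,
#'   `residue_b`, `distance`.
#' @export
extract_contacts <- function(structure, chains_a, chains_b, cutoff = 15) {
  if (!length(chains_a) || !length(chains_b)) abort("chain sets must be non-empty")
  if (length(intersect(chains_a, chains_b))) abort("chain sets must be disjoint")
  absent <- setdiff(c(chains_a, chains_b), unique(structure$chain))
  if (length(absent)) {
    abort(sprintf("chain(s) %s absent from the structure",
                  paste(absent, collapse = ", ")))
  }
  a <- filter(structure, .data$chain %in% chains_a)
  b <- filter(structure, .data$chain %in% chains_b)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
              outer(a$z, b$z, "-")^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  tibble(chain_a = a$chain[hit[, 1]], residue_a = a$resno[hit[, 1]],
         chain_b = b$chain[hit[, 2]], residue_b = b$resno[hit[, 2]],
         distance = d[hit]) |>
    arrange(.data$chain_a, .data$residue_a, .data$chain_b, .data$residue_b)
}

#' Residue-position map between two sequences by global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5)
#' between a source and a target protein sequence, returning the
#' position-to-position map.  Positions aligned to a gap map to `NA`
#' (untransferable).
#'
#' @param seq_source,seq_target Protein sequences (single strings).
#' @param min_identity Minimum alignment identity (fraction); below it the
#'   transfer is considered unreliable and an error is raised.
#' @return Tibble with `source_pos`, `target_pos` (NA when untransferable);
#'   percent identity in attribute `"identity"`.
#' @export
align_residue_map <- function(seq_source, seq_target, min_identity = 0.2) {
  if (!nzchar(seq_source) || !nzchar(seq_target)) {
    abort("sequences must be non-empty")
  }
  blosum62 <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_source), Biostrings::AAString(seq_target),
    type = "global", substitutionMatrix = blosum62,
    gapOpening = 10, gapExtension = 0.5)
  ident <- Biostrings::pid(pa) / 100
  if (ident < min_identity) {
    abort(sprintf("alignment identity %.1f%% below the %.0f%% floor; transfer unreliable",
                  100 * ident, 100 * min_identity))
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  spos <- cumsum(ap != "-")
  tpos <- cumsum(as_ != "-")
  keep <- ap != "-"
  map <- tibble(source_pos = spos[keep],
                target_pos = ifelse(as_[keep] == "-", NA_integer_, tpos[keep]))
  attr(map, "identity") <- ident
  map
}

#' Transfer residue numbering across species by sequence alignment
#'
#' Renumbers residue columns of a contact or cross-link table from a source
#' species' numbering to a target species' using [align_residue_map()].
#' Rows whose residues fall opposite an alignment gap are retained with `NA`
#' positions and `transfer_status = "untransferable"`.
#'
#' @param items Tibble of contacts or links, or a bare numeric vector of
#'   residue positions.
#' @param seq_source,seq_target Protein sequences for the renumbered
#'   protein.
#' @param columns Residue columns of `items` to renumber (ignored for a
#'   numeric vector).
#' @param min_identity Identity floor passed to [align_residue_map()].
#' @return Renumbered items with `transfer_status`, the position map in
#'   attribute `"map"` and identity in attribute `"identity"`.
#' @export
transfer_by_alignment <- function(items, seq_source, seq_target,
                                  columns = "residue_b", min_identity = 0.2) {
  map <- align_residue_map(seq_source, seq_target, min_identity)
  lut <- map$target_pos[order(map$source_pos)]
  remap <- function(pos) {
    out <- rep(NA_integer_, length(pos))
    ok <- !is.na(pos) & pos >= 1 & pos <= length(lut)
    out[ok] <- lut[pos[ok]]
    out
  }
  if (is.numeric(items)) {
    res <- remap(items)
    attr(res, "map") <- map
    attr(res, "identity") <- attr(map, "identity")
    return(res)
  }
  stopifnot(is.data.frame(items), all(columns %in% names(items)))
  for (col in columns) items[[col]] <- remap(items[[col]])
  status <- rep("transferred", nrow(items))
  for (col in columns) status[is.na(items[[col]])] <- "untransferable"
  items$transfer_status <- status
  attr(items, "map") <- map
  attr(items, "identity") <- attr(map, "identity")
  items
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Export links or contacts for visualization tools
#'
#' Writes either an xiNET-compatible CSV (`Protein1, PepPos1, Protein2,
#' PepPos2, Score`; score is `-log10(e_value)` when available, otherwise 1)
#' or Chimera pseudobond atom-spec lines (`#0:<res>.<chain>@CA`), which
#' require chain columns or a `chain_map`.  Output is byte-deterministic.
#'
#' @param x Links or contacts tibble.
#' @param path Output file.
#' @param format `"xinet_csv"` or `"chimera_pseudobond"`.
#' @param chain_map Named protein -> chain map for pseudobond output of
#'   protein-keyed links.
#' @return `path`, invisibly.
#' @export
export_links <- function(x, path, format = c("xinet_csv", "chimera_pseudobond"),
                         chain_map = NULL) {
  format <- match.arg(format)
  if (nrow(x) == 0L) abort("nothing to export: empty input")
  if (format == "xinet_csv") {
    score <- if ("e_value" %in% names(x)) -log10(x$e_value) else rep(1, nrow(x))
    out <- tibble(Protein1 = x$protein_a, PepPos1 = x$residue_a,
                  Protein2 = x$protein_b, PepPos2 = x$residue_b,
                  Score = score)
    readr::write_csv(out, path)
  } else {
    if (all(c("chain_a", "chain_b") %in% names(x))) {
      ca <- x$chain_a; cb <- x$chain_b
    } else if (!is.null(chain_map)) {
      ca <- unname(chain_map[x$protein_a]); cb <- unname(chain_map[x$protein_b])
    } else {
      abort("pseudobond export needs chain columns or a `chain_map`")
    }
    readr::write_lines(sprintf("#0:%d.%s@CA #0:%d.%s@CA",
                               x$residue_a, ca, x$residue_b, cb), path)
  }
  invisible(path)
}
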