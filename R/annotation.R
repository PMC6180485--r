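#' Read a gene annotation into a tibble of gene models
#'
#' Parses a GFF3 or BED6 file into the package's internal gene-model table:
#' one row per gene with strand-aware TSS and PAS coordinates.  Coordinates
#' are stored 0-based, half-open: a "+" gene spanning BED interval
#' `[start, end)` has `tss = start`, `pas = end`; on "-" the assignment is
#' flipped (`tss = end`, `pas = start`) so that the TSS always precedes the
#' PAS in the direction of transcription.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`; inferred from the file extension when
#'   omitted.
#' @param feature For GFF3, which feature type to keep (default `"gene"`).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`, `pas`,
#'   ordered by chromosome and leftmost coordinate.
#' @export
read_annotation <- function(path, format = NULL, feature = "gene") {
  if (!file.exists(path)) abort(sprintf("annotation file '%s' does not exist", path))
  format <- pick_file_format(path, format)
  if (format == "bed") {
    read_annotation_bed(path)
  } else {
    read_annotation_gff3(path, feature)
  }
}

read_annotation_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    abort(sprintf("malformed BED record at line %d: expected >= 6 fields, got %d",
                  idx[which(nf < 6L)[1]], nf[which(nf < 6L)[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  strand <- m[, 6]
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    abort(sprintf("gene '%s' (line %d) lacks a usable strand ('%s'); strand is required",
                  m[bad, 4][1], idx[bad][1], strand[bad][1]))
  }
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED record at line %d: non-numeric coordinates", idx[i]))
  }
  finalize_genes(tibble(
    gene_id = m[, 4], chrom = m[, 1], strand = strand,
    tss = ifelse(strand == "+", start, end),
    pas = ifelse(strand == "+", end, start)
  ))
}

read_annotation_gff3 <- function(path, feature) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("failed to parse GFF3 '%s': %s", path, conditionMessage(e)))
  )
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(S4Vectors::mcols(gr)$type) == feature]
  }
  if (length(gr) == 0L) abort(sprintf("no '%s' features found in '%s'", feature, path))
  strand <- as.character(GenomicRanges::strand(gr))
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else as.character(md$Name)
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    abort(sprintf("feature '%s' lacks a strand; stranded gene models are required",
                  ids[bad][1]))
  }
  # GFF3 is 1-based inclusive; GRanges keeps that, so 0-based half-open is
  # [start - 1, end).
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  finalize_genes(tibble(
    gene_id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    pas = ifelse(strand == "+", end0, start0)
  ))
}

finalize_genes <- function(genes) {
  genes <- genes |>
    mutate(tss = as.integer(.data$tss), pas = as.integer(.data$pas),
           left = pmin(.data$tss, .data$pas)) |>
    arrange(.data$chrom, .data$left, .data$gene_id) |>
    select(-"left")
  assert_genes(genes)
  genes
}

#' Write gene models as BED6 or GFF3
#'
#' Inverse of [read_annotation()]: converts the internal 0-based half-open
#' gene table back to the on-disk convention of each format.  Output is
#' byte-deterministic for a given input table.
#'
#' @param genes Gene-model tibble (see [read_annotation()]).
#' @param path Output file path.
#' @param score Score column value for BED output.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path, score = 0L) {
  assert_genes(genes)
  start <- pmin(genes$tss, genes$pas)
  end <- pmax(genes$tss, genes$pas)
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                             genes$chrom, start, end, genes$gene_id,
                             score, genes$strand), path)
  invisible(path)
}

#' @rdname write_bed
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(genes, path, source = "termscape") {
  assert_genes(genes)
  start <- pmin(genes$tss, genes$pas) + 1L # GFF3 is 1-based inclusive
  end <- pmax(genes$tss, genes$pas)
  readr::write_lines(c(
    "##gff-version 3",
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genes$chrom, source, start, end, genes$strand, genes$gene_id)
  ), path)
  invisible(path)
}
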