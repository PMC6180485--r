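# Plain-text track and alignment I/O.  Writers are deliberately small
# deterministic emitters so that identical inputs give byte-identical files.

#' Write per-chromosome coverage as bedGraph
#'
#' Run-length encodes each chromosome's per-base vector into standard
#' 0-based half-open bedGraph intervals; zero-valued runs are omitted.
#'
#' @param coverage Named per-chromosome list of numeric vectors, or a
#'   `calibrated_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  coverage <- track_coverage(coverage)
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(coverage)) {
    r <- rle(coverage[[chrom]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start[keep], end[keep],
                         format(r$values[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read a bedGraph into per-chromosome coverage vectors
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param chrom_sizes Named vector of chromosome sizes; intervals beyond a
#'   chromosome's size are an error.
#' @return Named list of per-base numeric vectors.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", comment = "#", progress = FALSE)
  df <- df[!grepl("^track", df$chrom), ]
  out <- lapply(chrom_sizes, numeric)
  for (chrom in unique(df$chrom)) {
    if (!chrom %in% names(chrom_sizes)) {
      abort(sprintf("bedGraph chromosome '%s' not in `chrom_sizes`", chrom))
    }
    sub <- df[df$chrom == chrom, ]
    if (any(sub$end > chrom_sizes[[chrom]])) {
      abort(sprintf("bedGraph interval beyond end of '%s'", chrom))
    }
    for (i in seq_len(nrow(sub))) {
      out[[chrom]][(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
  }
  out
}

#' Write single-end alignments as unsorted SAM
#'
#' Minimal SAM emitter for the concatenated two-species layout: `@SQ` header
#' lines for every chromosome, flag 0/16 for strand, MAPQ 42 for unique
#' reads and 0 with an `NH` tag for multi-mappers, full-length match CIGAR,
#' `*` sequence and quality.
#'
#' @param reads Alignment tibble (`chrom`, `start` 0-based, `end`, `strand`,
#'   optional `n_hits`).
#' @param chrom_sizes Named vector of chromosome sizes for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_sizes, path) {
  if (!"n_hits" %in% names(reads)) reads$n_hits <- 1L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  mapq <- ifelse(reads$n_hits > 1L, 0L, 42L)
  body <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                  seq_len(nrow(reads)), flag, reads$chrom, reads$start + 1L,
                  mapq, reads$end - reads$start, reads$n_hits)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read single-end alignments from a SAM file
#'
#' Parses the subset of SAM needed by the pipeline: reference, 1-based
#' position, strand from flag bit 0x10, read length from the CIGAR
#' match/deletion footprint, and multi-mapper evidence from the `NH` tag
#' (falling back to 1 when absent).  Unmapped records (flag 0x4 or `*`
#' reference) are dropped.
#'
#' @param path SAM file path.
#' @return Alignment tibble with `chrom`, `start` (0-based), `end`,
#'   `strand`, `n_hits`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), n_hits = integer(0)))
  }
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < 11L)
  if (length(bad)) abort(sprintf("malformed SAM record at alignment line %d", bad[1]))
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  chrom <- vapply(fields, `[[`, "", 3)
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  cigar <- vapply(fields, `[[`, "", 6)
  reflen <- vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", toks[grepl("[MDN=X]$", toks)])))
  }, integer(1), USE.NAMES = FALSE)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NH:i:", "", tag[1])) else 1L
  }, integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L & chrom != "*"
  tibble(chrom = chrom, start = pos - 1L, end = pos - 1L + reflen,
         strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
         n_hits = nh)[mapped, ]
}
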