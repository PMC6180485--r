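#' Selection criteria for non-overlapping genes
#'
#' Distances defining the non-overlapping gene filter used throughout the
#' analysis: a kept gene must have (a) its nearest same-strand downstream
#' neighbour's TSS strictly more than `min_downstream_tss_gap` nt past its
#' PAS, and (b) no opposite-strand transcription unit intersecting the
#' strand-oriented window from `opposite_overlap_upstream` nt upstream to
#' `opposite_overlap_downstream` nt downstream of the PAS.  Defaults are the
#' published 275 / 250 / 500 nt.
#'
#' @param min_downstream_tss_gap Minimum PAS-to-downstream-TSS distance, nt.
#' @param opposite_overlap_upstream Upstream extent of the PAS exclusion
#'   window, nt.
#' @param opposite_overlap_downstream Downstream extent of the PAS exclusion
#'   window, nt.
#' @return A named list of class `selection_criteria`.
#' @export
selection_criteria <- function(min_downstream_tss_gap = 275,
                               opposite_overlap_upstream = 250,
                               opposite_overlap_downstream = 500) {
  vals <- c(min_downstream_tss_gap, opposite_overlap_upstream,
            opposite_overlap_downstream)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("selection criteria must be non-negative finite distances")
  }
  structure(list(min_downstream_tss_gap = min_downstream_tss_gap,
                 opposite_overlap_upstream = opposite_overlap_upstream,
                 opposite_overlap_downstream = opposite_overlap_downstream),
            class = "selection_criteria")
}

#' Select non-overlapping genes around the PAS
#'
#' Applies the two-part non-overlap filter (see [selection_criteria()]) and
#' records why each rejected gene failed.  All distances are measured in the
#' candidate gene's direction of transcription, and intervals are half-open,
#' so boundary-touching features do not count as overlap.  Genes with no
#' same-strand downstream neighbour pass criterion (a) vacuously.
#'
#' @param genes Gene-model tibble (columns `gene_id`, `chrom`, `strand`,
#'   `tss`, `pas`; see [read_annotation()]).
#' @param criteria A [selection_criteria()] object.
#' @return The input tibble with three added columns: `selected` (logical),
#'   `downstream_tss_gap` (nt; `Inf` when no downstream same-strand TSS
#'   exists), and `reason` (`"pass"` or a semicolon-joined description of
#'   each failed criterion).
#' @export
select_genes <- function(genes, criteria = selection_criteria()) {
  assert_genes(genes)
  if (!inherits(criteria, "selection_criteria")) {
    criteria <- do.call(selection_criteria, as.list(criteria))
  }
  n <- nrow(genes)
  if (n == 0L) {
    return(mutate(genes, selected = logical(0), downstream_tss_gap = numeric(0),
                  reason = character(0)))
  }
  gap <- rep(Inf, n)
  opp <- rep(NA_character_, n)
  up <- criteria$opposite_overlap_upstream
  down <- criteria$opposite_overlap_downstream
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i] & genes$strand == genes$strand[i])
    same <- setdiff(same, i)
    if (length(same)) {
      # directed PAS -> TSS distance; only neighbours at/past the PAS count
      d <- if (genes$strand[i] == "+") genes$tss[same] - genes$pas[i]
           else genes$pas[i] - genes$tss[same]
      d <- d[d >= 0]
      if (length(d)) gap[i] <- min(d)
    }
    w <- oriented_window(genes$pas[i], genes$strand[i], -up, down)
    other <- which(genes$chrom == genes$chrom[i] & genes$strand != genes$strand[i])
    if (length(other)) {
      lo <- pmin(genes$tss[other], genes$pas[other])
      hi <- pmax(genes$tss[other], genes$pas[other])
      hit <- other[lo < w[2] & hi > w[1]]
      if (length(hit)) {
        opp[i] <- paste(sort(genes$gene_id[hit]), collapse = ",")
      }
    }
  }
  pass_gap <- gap > criteria$min_downstream_tss_gap
  pass_opp <- is.na(opp)
  reason <- rep("pass", n)
  fail <- !pass_gap | !pass_opp
  reason[fail] <- vapply(which(fail), function(i) {
    parts <- character(0)
    if (!pass_gap[i]) {
      parts <- c(parts, sprintf("downstream_tss_gap %d <= %d",
                                as.integer(gap[i]), as.integer(criteria$min_downstream_tss_gap)))
    }
    if (!pass_opp[i]) {
      parts <- c(parts, sprintf("opposite_strand_overlap %s", opp[i]))
    }
    paste(parts, collapse = "; ")
  }, character(1))
  mutate(genes, selected = pass_gap & pass_opp, downstream_tss_gap = gap,
         reason = reason)
}

#' Write a gene selection to disk
#'
#' Emits the selected genes as BED6 alongside a TSV of per-gene decisions and
#' rejection reasons.
#'
#' @param selection Output of [select_genes()].
#' @param prefix Output path prefix; writes `<prefix>_selected.bed` and
#'   `<prefix>_selection.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_selection <- function(selection, prefix) {
  stopifnot(all(c("selected", "reason") %in% names(selection)))
  bed <- paste0(prefix, "_selected.bed")
  tsv <- paste0(prefix, "_selection.tsv")
  write_bed(filter(selection, .data$selected), bed)
  readr::write_tsv(selection, tsv)
  invisible(c(bed = bed, tsv = tsv))
}
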