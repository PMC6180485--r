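#' Pol II termination (readthrough) index per gene
#'
#' For every gene, measures signal mass in two strand-oriented half-open
#' post-PAS windows — proximal `B1 = [PAS, PAS+50)` and distal
#' `B2 = [PAS+350, PAS+400)` — and divides each by the mass in the
#' `[PAS-500, PAS+500)` denominator window.  Because the index is a
#' within-sample ratio, any positive rescaling of the track (including the
#' spike-in calibration factor) cancels.  By default "reads in window" is
#' implemented as coverage mass; `method = "midpoint"` instead counts read
#' midpoints when a read tibble is supplied.
#'
#' @param track A `calibrated_track` or named per-chromosome coverage list
#'   over the signal genome (for `method = "coverage"`), or an alignment
#'   tibble (for `method = "midpoint"`).
#' @param genes Gene-model tibble, normally the [select_genes()] subset.
#' @param b1,b2,denominator Oriented half-open windows `c(from, to)` in nt
#'   relative to the PAS.
#' @param method `"coverage"` (default) or `"midpoint"`.
#' @param strain Optional strain label stored on the result.
#' @return A `termination_table` tibble: per gene `reads_b1`, `reads_b2`,
#'   `reads_denominator`, `index_b1`, `index_b2`.  Genes whose windows leave
#'   the covered genome or whose denominator is zero are excluded and listed
#'   in attributes `"dropped"` and `"zero_denominator"`.
#' @export
termination_index <- function(track, genes, b1 = c(0, 50), b2 = c(350, 400),
                              denominator = c(-500, 500),
                              method = c("coverage", "midpoint"),
                              strain = NULL) {
  method <- match.arg(method)
  assert_genes(genes)
  if (nrow(genes) == 0L) abort("empty gene set")
  if (method == "midpoint") {
    stopifnot(is.data.frame(track))
    mids <- floor((track$start + track$end) / 2)
    sizes <- tapply(pmax(track$end, 0), track$chrom, max)
    coverage <- lapply(names(sizes), function(ch) {
      tabulate(mids[track$chrom == ch] + 1L, nbins = sizes[[ch]])
    })
    names(coverage) <- names(sizes)
  } else {
    coverage <- track_coverage(track)
  }
  cs <- lapply(coverage, function(v) c(0, cumsum(v)))
  mass <- function(i, w) {
    c_chrom <- cs[[genes$chrom[i]]]
    if (is.null(c_chrom)) return(NA_real_)
    oriented_mass(c_chrom, genes$pas[i], genes$strand[i], w[1], w[2])
  }
  n <- nrow(genes)
  m_b1 <- vapply(seq_len(n), mass, numeric(1), w = b1)
  m_b2 <- vapply(seq_len(n), mass, numeric(1), w = b2)
  m_den <- vapply(seq_len(n), mass, numeric(1), w = denominator)
  oob <- is.na(m_b1) | is.na(m_b2) | is.na(m_den)
  zero <- !oob & m_den == 0
  keep <- !oob & !zero
  if (!any(keep)) abort("no genes left after window and zero-denominator exclusions")
  out <- tibble(gene_id = genes$gene_id[keep],
                reads_b1 = m_b1[keep], reads_b2 = m_b2[keep],
                reads_denominator = m_den[keep],
                index_b1 = m_b1[keep] / m_den[keep],
                index_b2 = m_b2[keep] / m_den[keep])
  if (!is.null(strain)) out$strain <- strain
  attr(out, "dropped") <- genes$gene_id[oob]
  attr(out, "zero_denominator") <- genes$gene_id[zero]
  attr(out, "windows") <- list(b1 = b1, b2 = b2, denominator = denominator)
  class(out) <- c("termination_table", class(out))
  out
}

#' Scale termination indices by the strain's median B1 index
#'
#' Divides every index by the per-strain median of `index_b1`, so the
#' scaled B1 distribution has median exactly 1 and scaled B2 values are
#' comparable across strains.  For an even number of genes the median is
#' the mean of the two central order statistics (the R default).
#'
#' @param table A `termination_table` (with a `strain` column when several
#'   strains are stacked; otherwise treated as one strain).
#' @return The table with `scaled_b1` and `scaled_b2` columns added.
#' @export
scale_by_median_b1 <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("index_b1", "index_b2") %in% names(table)))
  grp <- if ("strain" %in% names(table)) table$strain else rep("all", nrow(table))
  meds_arr <- tapply(table$index_b1, grp, median)
  meds <- setNames(as.numeric(meds_arr), dimnames(meds_arr)[[1]])
  if (any(!is.finite(meds)) || any(meds == 0)) {
    abort("median B1 index is zero or non-finite; cannot scale")
  }
  table$scaled_b1 <- table$index_b1 / unname(meds[grp])
  table$scaled_b2 <- table$index_b2 / unname(meds[grp])
  table
}

#' Compare per-gene termination indices between strains
#'
#' Two-sided Wilcoxon rank-sum test on a per-gene statistic (by default the
#' distal scaled index `scaled_b2`) between two strains, with the
#' Hodges-Lehmann shift estimate.  The exact null distribution is enumerated
#' when both groups have at most 20 untied values; otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param values_by_strain Either a data frame with `strain` and a value
#'   column, or a named list of two numeric vectors.
#' @param value Column to compare when a data frame is given.
#' @return One-row tibble: `strain_a`, `strain_b`, `n_a`, `n_b`,
#'   `statistic` (rank-sum W), `p_value`, `hl_shift` (b relative to a),
#'   `median_a`, `median_b`.
#' @export
compare_strains <- function(values_by_strain, value = "scaled_b2") {
  if (is.data.frame(values_by_strain)) {
    stopifnot("strain" %in% names(values_by_strain),
              value %in% names(values_by_strain))
    sp <- split(values_by_strain[[value]], values_by_strain$strain)
  } else {
    sp <- values_by_strain
  }
  if (length(sp) != 2L) abort("exactly two strains are required")
  if (any(lengths(sp) < 2L)) {
    abort(sprintf("strain '%s' has fewer than 2 values",
                  names(sp)[lengths(sp) < 2L][1]))
  }
  a <- sp[[1]]; b <- sp[[2]]
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    wilcox.test(b, a, alternative = "two.sided", exact = exact,
                correct = !exact, conf.int = TRUE)
  )
  tibble(strain_a = names(sp)[1], strain_b = names(sp)[2],
         n_a = length(a), n_b = length(b),
         statistic = unname(ht$statistic), p_value = ht$p.value,
         hl_shift = unname(ht$estimate),
         median_a = median(a), median_b = median(b))
}

#' Termination table across all strains of a simulation
#'
#' Runs [termination_index()] on each strain's calibrated track for one mark
#' and stacks the scaled tables.
#'
#' @param tracks Named list from [calibrate_simulation()].
#' @param genes Selected gene-model tibble.
#' @param mark Mark to extract (matched against each track's label).
#' @param ... Passed to [termination_index()].
#' @return A stacked, median-B1-scaled `termination_table` with a `strain`
#'   column.
#' @export
termination_by_strain <- function(tracks, genes, mark, ...) {
  sel <- purrr::keep(tracks, function(t) identical(t$mark, mark))
  if (!length(sel)) abort(sprintf("no calibrated track for mark '%s'", mark))
  tabs <- lapply(sel, function(t) termination_index(t, genes, strain = t$strain, ...))
  scale_by_median_b1(bind_rows(tabs))
}
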