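#' Partition alignments by species and apply read filtering
#'
#' Assigns each alignment to the spike-in genome (reference name prefixed
#' `"spikein_"`) or the signal genome, discards multi-mappers
#' (`n_hits > 1`), collapses PCR duplicates — reads with identical
#' (chromosome, 5' position, strand) — to a single read, and accumulates
#' per-base coverage per species from the retained reads.
#'
#' Two count sets are reported: `reads_*` after duplicate collapsing (the
#' filtered counts used for ChIP coverage) and `reads_*_raw` after
#' multi-mapper removal but before positional collapsing.  At high coverage
#' density, positional collapsing removes a depth- and genome-size-dependent
#' share of genuine fragments, so the mixture-ratio estimator
#' ([estimate_mixing_fraction()]) should be fed the `_raw` counts; see the
#' methods vignette.
#'
#' @param reads A tibble of alignments with columns `chrom`, `start` (0-based
#'   5' coordinate), `end`, `strand`, and optionally `n_hits` (assumed 1 when
#'   absent); typically one sample from [simulate_chip_samples()] or
#'   [read_sam()].
#' @param chrom_sizes Named vector of chromosome sizes covering both genomes;
#'   required to build coverage (reads on chromosomes absent from it are
#'   counted as unassigned and excluded).
#' @return A list of class `sample_counts`: `counts` (one-row tibble with
#'   `reads_pombe`, `reads_spikein`, `reads_pombe_raw`, `reads_spikein_raw`,
#'   `n_multimapper`, `n_duplicate`, `n_unassigned`) and `coverage` (list
#'   with per-chromosome numeric vectors under `$pombe` and `$spikein`).
#' @export
partition_and_filter <- function(reads, chrom_sizes) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (!"n_hits" %in% names(reads)) reads$n_hits <- 1L
  known <- reads$chrom %in% names(chrom_sizes)
  n_unassigned <- sum(!known)
  if (n_unassigned > 0) {
    warn(sprintf("%d reads on references matching neither genome were excluded",
                 n_unassigned))
  }
  reads <- reads[known, ]
  n_multi <- sum(reads$n_hits > 1L)
  uniq <- reads[reads$n_hits == 1L, ]
  spike <- startsWith(uniq$chrom, "spikein_")
  raw_p <- sum(!spike); raw_s <- sum(spike)
  dedup <- distinct(uniq, .data$chrom, .data$start, .data$strand, .keep_all = TRUE)
  spike_d <- startsWith(dedup$chrom, "spikein_")
  cov_for <- function(df, chroms) {
    out <- lapply(chroms, function(ch) {
      sub <- df[df$chrom == ch, ]
      coverage_from_intervals(sub$start, sub$end, chrom_sizes[[ch]])
    })
    names(out) <- chroms
    out
  }
  p_chroms <- names(chrom_sizes)[!startsWith(names(chrom_sizes), "spikein_")]
  s_chroms <- names(chrom_sizes)[startsWith(names(chrom_sizes), "spikein_")]
  structure(list(
    counts = tibble(
      reads_pombe = sum(!spike_d), reads_spikein = sum(spike_d),
      reads_pombe_raw = raw_p, reads_spikein_raw = raw_s,
      n_multimapper = n_multi, n_duplicate = nrow(uniq) - nrow(dedup),
      n_unassigned = n_unassigned),
    coverage = list(pombe = cov_for(dedup[!spike_d, ], p_chroms),
                    spikein = cov_for(dedup[spike_d, ], s_chroms))
  ), class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

counts_of <- function(x) {
  if (inherits(x, "sample_counts")) x$counts else as_tibble(x)
}

#' Spike-in scale factor with input-mixture correction
#'
#' Computes the calibration factor applied to signal-genome coverage of an IP
#' sample:
#' \deqn{\alpha = 10^6 \; \frac{\hat m}{N^{IP}_{spike}}, \qquad
#'       \hat m = \frac{N^{input}_{spike}}{N^{input}_{pombe}}}
#' where \eqn{\hat m}, the input-sample species read ratio, estimates the
#' realized cell-mixture ratio and corrects the IP spike-in depth for
#' mixture drift between samples.  The `1e6` constant keeps magnitudes
#' readable and cancels in every between-strain comparison.
#'
#' @param ip,input `sample_counts` (or one-row count tibbles) for the IP and
#'   its matched input.
#' @param use_raw Use pre-collapse unique-mapping counts (default `FALSE`:
#'   deduplicated counts, matching the coverage actually calibrated).
#' @return A single positive scale factor with the counts used attached as
#'   attribute `"provenance"`.
#' @export
spikein_scale_factor <- function(ip, input, use_raw = FALSE) {
  ipc <- counts_of(ip); inc <- counts_of(input)
  pick <- function(cnt, col) cnt[[if (use_raw) paste0(col, "_raw") else col]]
  n_ip_s <- pick(ipc, "reads_spikein")
  n_in_s <- pick(inc, "reads_spikein")
  n_in_p <- pick(inc, "reads_pombe")
  vals <- c(ip_spikein = n_ip_s, input_spikein = n_in_s, input_pombe = n_in_p)
  zero <- vals == 0
  if (any(zero)) {
    abort(sprintf("zero read count in %s; cannot form a spike-in scale factor",
                  paste(names(vals)[zero], collapse = ", ")))
  }
  m_hat <- n_in_s / n_in_p
  alpha <- 1e6 * m_hat / n_ip_s
  attr(alpha, "provenance") <- list(mixing_ratio = m_hat, ip_spikein = n_ip_s,
                                    input_spikein = n_in_s, input_pombe = n_in_p)
  alpha
}

#' Apply a scale factor to raw coverage
#'
#' @param coverage Per-chromosome list of raw signal-genome coverage vectors
#'   (e.g. `partition_and_filter(...)$coverage$pombe`).
#' @param scale_factor Positive finite factor, typically from
#'   [spikein_scale_factor()].
#' @param strain,mark Optional labels stored on the track.
#' @return A `calibrated_track`: list with `coverage` (every base multiplied
#'   by the factor), `scale_factor`, `strain`, `mark`, and `provenance`.
#' @export
calibrate_track <- function(coverage, scale_factor, strain = NULL, mark = NULL) {
  if (!is.list(coverage) || is.null(names(coverage))) {
    abort("`coverage` must be a named per-chromosome list of numeric vectors")
  }
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0) {
    abort("`scale_factor` must be a single positive finite number")
  }
  structure(list(
    coverage = lapply(coverage, function(v) v * as.numeric(scale_factor)),
    scale_factor = as.numeric(scale_factor),
    strain = strain, mark = mark,
    provenance = attr(scale_factor, "provenance")
  ), class = "calibrated_track")
}

#' @export
print.calibrated_track <- function(x, ...) {
  cat(sprintf("<calibrated_track>%s%s %d chromosome(s), scale factor %.4g\n",
              if (is.null(x$strain)) "" else paste0(" ", x$strain),
              if (is.null(x$mark)) "" else paste0(" ", x$mark),
              length(x$coverage), x$scale_factor))
  invisible(x)
}

track_coverage <- function(track) {
  if (inherits(track, "calibrated_track")) track$coverage else track
}

#' Estimate the spike-in cell-mixing fraction from an input sample
#'
#' Genome-size-normalized species read ratio of a genomic-DNA input sample:
#' `(reads_spikein / genome_size_spikein) / (reads_pombe / genome_size_pombe)`.
#' Under uniform input coverage this estimates the ratio of spike-in to
#' signal cells in the mixture.
#'
#' @param input `sample_counts` (or one-row count tibble) for the input.
#' @param genome_size_pombe,genome_size_spikein Total genome sizes, bp.
#' @param use_raw Use pre-collapse unique-mapping counts (default `TRUE`;
#'   positional duplicate collapsing biases this estimator at high depth —
#'   see [partition_and_filter()]).
#' @return Estimated cell fraction (dimensionless).
#' @export
estimate_mixing_fraction <- function(input, genome_size_pombe,
                                     genome_size_spikein, use_raw = TRUE) {
  cnt <- counts_of(input)
  assert_scalar_number(genome_size_pombe, "genome_size_pombe", positive = TRUE)
  assert_scalar_number(genome_size_spikein, "genome_size_spikein", positive = TRUE)
  ns <- cnt[[if (use_raw) "reads_spikein_raw" else "reads_spikein"]]
  np <- cnt[[if (use_raw) "reads_pombe_raw" else "reads_pombe"]]
  if (is.null(np) || np == 0) abort("zero signal-genome reads in input sample")
  (ns / genome_size_spikein) / (np / genome_size_pombe)
}

#' Calibrate every IP sample of a simulation
#'
#' Convenience wrapper running [partition_and_filter()],
#' [spikein_scale_factor()] and [calibrate_track()] over all strain x mark
#' pairs of a [simulate_chip_samples()] result.
#'
#' @param sim A `chip_simulation`.
#' @return Named list (`"<strain>_<mark>"`) of `calibrated_track` objects.
#' @export
calibrate_simulation <- function(sim) {
  stopifnot(inherits(sim, "chip_simulation"))
  sizes <- c(sim$config$chrom_sizes_pombe, sim$config$chrom_sizes_spikein)
  meta <- sim$truth$samples
  out <- list()
  for (key in unique(paste(meta$strain, meta$mark, sep = "_"))) {
    parts <- meta[paste(meta$strain, meta$mark, sep = "_") == key, ]
    ip <- partition_and_filter(sim$samples[[parts$sample_id[parts$role == "ip"]]]$reads, sizes)
    input <- partition_and_filter(sim$samples[[parts$sample_id[parts$role == "input"]]]$reads, sizes)
    alpha <- spikein_scale_factor(ip, input)
    out[[key]] <- calibrate_track(ip$coverage$pombe, alpha,
                                  strain = parts$strain[1], mark = parts$mark[1])
  }
  out
}
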