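# Internal helpers shared across modules.
#
# Coordinate conventions: all gene coordinates are stored 0-based, half-open.
# A gene on "+" occupies [tss, pas); on "-" it occupies [pas, tss) with
# transcription running right to left.  Oriented offsets relative to an anchor
# P map to genomic coordinates as [P + a, P + b) on "+" and [P - b, P - a)
# on "-", so that offset 0 is the first base downstream of the anchor on
# either strand and windows stay half-open.

# Seed handling: every stochastic entry point scopes its RNG state so that
# simulation is reproducible without clobbering the caller's stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || (positive && x <= 0)) {
    abort(sprintf("`%s` must be a single %snumber",
                  name, if (positive) "positive " else ""))
  }
  invisible(x)
}

assert_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "pas")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort(paste0("`genes` must be a data frame with columns ",
                 paste(need, collapse = ", ")))
  }
  bad <- !(genes$strand %in% c("+", "-"))
  if (any(bad)) abort("gene strand must be '+' or '-'")
  plus_bad <- genes$strand == "+" & genes$tss >= genes$pas
  minus_bad <- genes$strand == "-" & genes$tss <= genes$pas
  if (any(plus_bad | minus_bad)) {
    abort(sprintf(
      "invalid gene coordinates (tss must precede pas in transcription direction): %s",
      paste(genes$gene_id[plus_bad | minus_bad], collapse = ", ")))
  }
  invisible(genes)
}

# Genomic half-open window for an oriented offset window [a, b) around an
# anchor position; returns c(start, end) in genomic 0-based half-open coords.
oriented_window <- function(anchor, strand, a, b) {
  if (strand == "+") c(anchor + a, anchor + b) else c(anchor - b, anchor - a)
}

# Per-base values of a coverage vector over an oriented window, 5'->3' in
# transcription direction.  `cov` is the chromosome's per-base vector
# (index i holds genomic position i - 1).  Returns NULL if out of bounds.
oriented_slice <- function(cov, anchor, strand, a, b) {
  w <- oriented_window(anchor, strand, a, b)
  if (w[1] < 0 || w[2] > length(cov)) return(NULL)
  v <- cov[(w[1] + 1L):w[2]]
  if (strand == "-") rev(v) else v
}

# Mass (sum of per-base values) over an oriented window using a precomputed
# cumulative sum `cs = c(0, cumsum(cov))`; NA if out of bounds.
oriented_mass <- function(cs, anchor, strand, a, b) {
  w <- oriented_window(anchor, strand, a, b)
  if (w[1] < 0 || w[2] > length(cs) - 1L) return(NA_real_)
  cs[w[2] + 1L] - cs[w[1] + 1L]
}

# Coverage vector from read intervals on one chromosome (0-based half-open
# starts/ends, already clipped).  Difference-array accumulation.
coverage_from_intervals <- function(start, end, size) {
  if (length(start) == 0L) return(numeric(size))
  d <- tabulate(start + 1L, nbins = size + 1L) -
    tabulate(pmin(end, size) + 1L, nbins = size + 1L)
  cumsum(d)[seq_len(size)]
}

# Draw `n` integer positions in [0, length(intensity) - 1] with probability
# proportional to `intensity` (inverse-CDF; O(n log m)).
sample_positions <- function(intensity, n) {
  if (n == 0L) return(integer(0))
  cs <- cumsum(as.numeric(intensity))
  tot <- cs[length(cs)]
  if (!is.finite(tot) || tot <= 0) abort("intensity has no mass to sample from")
  findInterval(runif(n) * tot, cs) # 0-based positions
}

pick_file_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("gff3", "bed")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) "gff3"
  else if (ext == "bed") "bed"
  else abort(sprintf("cannot infer annotation format from '%s'; pass `format`", path))
}
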