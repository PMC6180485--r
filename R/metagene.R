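#' Build a TSS- or PAS-anchored metagene matrix
#'
#' Extracts calibrated signal around each gene's anchor into a genes x bins
#' matrix.  Windows are strand-oriented: negative positions are upstream and
#' positive positions downstream in the direction of transcription, with the
#' signal of "-" genes reversed accordingly.  Each bin's value is the mean
#' per-base signal inside it.  Genes whose extended window leaves the
#' chromosome are dropped and reported via the `"dropped"` attribute.
#'
#' @param track A `calibrated_track` or named per-chromosome coverage list.
#' @param genes Gene-model tibble (normally the selected subset from
#'   [select_genes()]).
#' @param anchor `"pas"` or `"tss"`.
#' @param upstream,downstream Window extent on each side of the anchor, nt
#'   (defaults: PAS window \[-500, +1000\], TSS window \[-250, +1000\]).
#' @param bin_size Bin width, nt; must divide the window length.
#' @return A `metagene_matrix`: list with `matrix` (rownames = gene ids),
#'   `bins` (tibble of bin start/end/mid offsets), `anchor`, `bin_size`, and
#'   the track labels.
#' @export
build_metagene_matrix <- function(track, genes, anchor = c("pas", "tss"),
                                  upstream = NULL, downstream = NULL,
                                  bin_size = 10) {
  anchor <- match.arg(anchor)
  assert_genes(genes)
  if (nrow(genes) == 0L) abort("empty gene list")
  upstream <- upstream %||% if (anchor == "pas") 500 else 250
  downstream <- downstream %||% 1000
  width <- upstream + downstream
  if (width < bin_size) abort("window must cover at least one bin")
  if (width %% bin_size != 0) {
    abort(sprintf("bin_size %d does not divide the %d nt window", bin_size, width))
  }
  coverage <- track_coverage(track)
  nb <- as.integer(width / bin_size)
  rows <- vector("list", nrow(genes))
  kept <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cov <- coverage[[genes$chrom[i]]]
    if (is.null(cov)) next
    P <- if (anchor == "pas") genes$pas[i] else genes$tss[i]
    v <- oriented_slice(cov, P, genes$strand[i], -upstream, downstream)
    if (is.null(v)) next
    rows[[i]] <- colMeans(matrix(v, nrow = bin_size))
    kept[i] <- TRUE
  }
  if (!any(kept)) abort("no gene window fits inside the covered chromosomes")
  mat <- do.call(rbind, rows[kept])
  rownames(mat) <- genes$gene_id[kept]
  bins <- tibble(start = seq(-upstream, downstream - bin_size, by = bin_size),
                 end = seq(-upstream + bin_size, downstream, by = bin_size))
  bins$mid <- (bins$start + bins$end) / 2
  structure(list(matrix = mat, bins = bins, anchor = anchor,
                 bin_size = as.integer(bin_size),
                 strain = if (inherits(track, "calibrated_track")) track$strain else NULL,
                 mark = if (inherits(track, "calibrated_track")) track$mark else NULL,
                 dropped = genes$gene_id[!kept]),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("<metagene_matrix> %s-anchored, %d genes x %d bins (%d nt bins)\n",
              toupper(x$anchor), nrow(x$matrix), ncol(x$matrix), x$bin_size))
  invisible(x)
}

#' @export
as_tibble.metagene_matrix <- function(x, ...) {
  tibble(gene_id = rep(rownames(x$matrix), times = ncol(x$matrix)),
         position = rep(x$bins$mid, each = nrow(x$matrix)),
         signal = as.vector(x$matrix))
}

#' Average a metagene matrix into a meta-profile
#'
#' Column-wise mean or median across genes, with an optional gene-resampling
#' bootstrap band.  Replicate matrices are averaged at the profile level
#' (profiles first, then their mean), not by pooling reads.
#'
#' @param matrix A `metagene_matrix`, or a list of replicate
#'   `metagene_matrix` objects sharing the same binning.
#' @param estimator `"mean"` or `"median"`.
#' @param boot Number of bootstrap resamples for a 95% band (0 = none).
#' @param seed Seed for the bootstrap.
#' @return Tibble with `position`, `signal`, and (when `boot > 0`) `lo`,
#'   `hi`; carries the anchor/strain/mark as attributes.
#' @export
meta_profile <- function(matrix, estimator = c("mean", "median"), boot = 0,
                         seed = 1L) {
  estimator <- match.arg(estimator)
  if (inherits(matrix, "metagene_matrix")) matrix <- list(matrix)
  stopifnot(length(matrix) >= 1,
            all(vapply(matrix, inherits, logical(1), "metagene_matrix")))
  bins <- matrix[[1]]$bins
  est <- function(m) apply(m, 2, estimator)
  profs <- vapply(matrix, function(x) {
    if (nrow(x$matrix) == 0L) abort("metagene matrix has no gene rows")
    if (!identical(x$bins, bins)) abort("replicate matrices must share binning")
    est(x$matrix)
  }, numeric(nrow(bins)))
  out <- tibble(position = bins$mid, signal = rowMeans(profs))
  if (boot > 0) {
    bands <- local_seed(seed, {
      reps <- replicate(boot, {
        rowMeans(vapply(matrix, function(x) {
          idx <- sample.int(nrow(x$matrix), replace = TRUE)
          est(x$matrix[idx, , drop = FALSE])
        }, numeric(nrow(bins))))
      })
      apply(reps, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    })
    out$lo <- bands[1, ]
    out$hi <- bands[2, ]
  }
  attr(out, "anchor") <- matrix[[1]]$anchor
  attr(out, "strain") <- matrix[[1]]$strain
  attr(out, "mark") <- matrix[[1]]$mark
  out
}

#' Equalize profiles upstream of the anchor
#'
#' Adjusts each strain's meta-profile so its mean over an upstream window
#' matches the reference strain's, making downstream divergence directly
#' comparable across strains.  The default adjustment is an additive offset;
#' `method = "multiplicative"` rescales instead.
#'
#' @param profiles Named list (strain -> profile tibble from
#'   [meta_profile()]) sharing one binning.
#' @param reference Name of the reference strain.
#' @param upstream_window Offsets `c(from, to)` with `to <= 0` defining the
#'   upstream equalization window.
#' @param method `"additive"` or `"multiplicative"`.
#' @return Tibble of adjusted profiles in long form (`strain`, `position`,
#'   `signal`) with per-strain shifts in attribute `"shifts"`.
#' @export
equalize_upstream <- function(profiles, reference,
                              upstream_window = c(-500, 0),
                              method = c("additive", "multiplicative")) {
  method <- match.arg(method)
  stopifnot(is.list(profiles), reference %in% names(profiles))
  if (upstream_window[1] >= upstream_window[2] || upstream_window[2] > 0) {
    abort("`upstream_window` must be a non-empty interval ending at or before 0")
  }
  pos <- profiles[[reference]]$position
  sel <- pos >= upstream_window[1] & pos < upstream_window[2]
  if (!any(sel)) abort("`upstream_window` contains no bins")
  ref_level <- mean(profiles[[reference]]$signal[sel])
  shifts <- numeric(0)
  out <- purrr::imap(profiles, function(p, strain) {
    if (!identical(p$position, pos)) abort("profiles must share binning")
    lev <- mean(p$signal[sel])
    if (method == "additive") {
      shift <- ref_level - lev
      sig <- p$signal + shift
    } else {
      if (lev == 0) abort(sprintf("strain '%s' has zero upstream level", strain))
      shift <- ref_level / lev
      sig <- p$signal * shift
    }
    shifts[[strain]] <<- shift
    tibble(strain = strain, position = p$position, signal = sig)
  })
  res <- bind_rows(out)
  attr(res, "shifts") <- shifts
  attr(res, "method") <- method
  res
}

#' Write a metagene result (TSV plus figure)
#'
#' Writes the tabular form — the reproducible surface — next to a rendered
#' figure: a long-form TSV and heatmap for a matrix, or a profile TSV and
#' line plot for a profile.  Heatmap rows are ordered by gene length (via
#' row sums' stable order on id) only through the stored gene order, which
#' is fixed, so output is byte-deterministic.
#'
#' @param x A `metagene_matrix` or a profile tibble from [meta_profile()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.pdf`.
#' @return Named vector of paths, invisibly.
#' @export
render_metagene <- function(x, prefix) {
  tsv <- paste0(prefix, ".tsv")
  pdf <- paste0(prefix, ".pdf")
  if (inherits(x, "metagene_matrix")) {
    readr::write_tsv(as_tibble(x), tsv)
    p <- ggplot2::autoplot(x)
  } else {
    readr::write_tsv(x, tsv)
    p <- plot_meta_profile(x)
  }
  ggplot2::ggsave(pdf, p, width = 6, height = 4)
  invisible(c(tsv = tsv, figure = pdf))
}
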