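#' Configuration for the two-species ChIP-seq simulator
#'
#' Bundles every tunable of the synthetic-data generator: a fission-yeast-like
#' signal genome, a budding-yeast-like spike-in genome (chromosomes prefixed
#' `"spikein_"`), gene packing, per-mark CTD phospho-profile shapes, the
#' post-PAS readthrough decay length per strain, spike-in mixing, IP
#' efficiency, and the count-noise model.  The defaults describe a desk-scale
#' experiment: 300 genes on 2 x 250 kb chromosomes, one 100 kb spike-in
#' chromosome, 2e5 single-end 50 nt reads per sample, a 15% spike-in cell
#' fraction, and two strains — a wild type with fast post-PAS release
#' (decay 50 nt) and a termination-defective mutant (decay 400 nt).
#'
#' @param seed Integer seed; identical configurations reproduce all outputs
#'   bit-for-bit.
#' @param n_genes Number of genes to place.
#' @param chrom_sizes_pombe,chrom_sizes_spikein Named integer vectors of
#'   chromosome sizes (bp).  Spike-in chromosome names must carry the
#'   `"spikein_"` prefix.
#' @param spikein_cell_fraction Spike-in cells as a fraction of signal-genome
#'   cells, in (0, 1).  Default 0.15.
#' @param mixing_jitter_sd Standard deviation (log scale) of per-strain
#'   lognormal jitter on the realized mixing fraction.  Default 0: mixture
#'   drift is an experiment-specific nuisance, switched on explicitly in
#'   robustness checks.
#' @param ip_efficiency Immunoprecipitation efficiency: a single positive
#'   scalar or a vector named by strain.  Scales specific chromatin of both
#'   species (same antibody), so spike-in calibrated comparisons are designed
#'   to be invariant to it.
#' @param strains Named numeric vector mapping strain name to its post-PAS
#'   readthrough decay length (nt): mean occupancy `d` nt past the PAS decays
#'   as `exp(-d / decay)`.
#' @param occupancy_multiplier Optional named per-strain multiplier on true
#'   gene-body occupancy (default 1 for every strain) — used to plant global
#'   occupancy changes that only spike-in calibration can recover.
#' @param mark_profiles Named list of per-mark shape parameter lists; see
#'   [default_mark_profiles()].
#' @param reads_per_sample Fragments sequenced per sample (before planted PCR
#'   duplication).
#' @param noise `"negative_binomial"` (gamma-distributed per-bin rate
#'   multipliers, the realistic overdispersed regime) or `"poisson"`.
#' @param nb_dispersion Negative-binomial dispersion (variance of the per-bin
#'   rate multiplier); default 0.1.
#' @param read_length Read length, nt (single-end point intervals; no
#'   fragment extension).
#' @param post_pas_nt How far past the PAS true occupancy is modelled, nt.
#' @param background_density Uniform nonspecific IP background (occupancy
#'   units per base), not scaled by `ip_efficiency`.
#' @param spikein_ip_density Specific IP signal density per spike-in base per
#'   spike-in cell, relative to a pombe occupancy unit.
#' @param violation_fraction Fraction of inter-gene gaps deliberately drawn
#'   too short so the downstream-gap / opposite-overlap selection filter has
#'   genuine failures to find.
#' @param multimapper_fraction,duplicate_fraction Fractions of reads emitted
#'   as multi-mappers (`n_hits = 2`) and as planted PCR duplicate copies.
#'
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 300L,
                              chrom_sizes_pombe = c(chrI = 250000L, chrII = 250000L),
                              chrom_sizes_spikein = c(spikein_chrI = 100000L),
                              spikein_cell_fraction = 0.15,
                              mixing_jitter_sd = 0,
                              ip_efficiency = 1,
                              strains = c(wt = 50, dis2d = 400),
                              occupancy_multiplier = NULL,
                              mark_profiles = default_mark_profiles(),
                              reads_per_sample = 2e5,
                              noise = c("negative_binomial", "poisson"),
                              nb_dispersion = 0.1,
                              read_length = 50L,
                              post_pas_nt = 1000L,
                              background_density = 0.02,
                              spikein_ip_density = 1,
                              violation_fraction = 0.15,
                              multimapper_fraction = 0.02,
                              duplicate_fraction = 0.05) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_genes, "n_genes", positive = TRUE)
  if (!is.numeric(chrom_sizes_pombe) || is.null(names(chrom_sizes_pombe)) ||
      any(chrom_sizes_pombe <= 0)) {
    abort("`chrom_sizes_pombe` must be a named vector of positive sizes")
  }
  if (!is.numeric(chrom_sizes_spikein) || is.null(names(chrom_sizes_spikein)) ||
      any(chrom_sizes_spikein <= 0)) {
    abort("`chrom_sizes_spikein` must be a named vector of positive sizes")
  }
  if (!all(startsWith(names(chrom_sizes_spikein), "spikein_"))) {
    abort("spike-in chromosome names must start with 'spikein_'")
  }
  if (!is.numeric(spikein_cell_fraction) || spikein_cell_fraction <= 0 ||
      spikein_cell_fraction >= 1) {
    abort("`spikein_cell_fraction` must lie in (0, 1)")
  }
  if (mixing_jitter_sd < 0) abort("`mixing_jitter_sd` must be >= 0")
  if (any(ip_efficiency <= 0)) abort("`ip_efficiency` must be positive")
  if (is.null(names(strains)) || any(strains <= 0)) {
    abort("`strains` must be a named vector of positive readthrough decay lengths (nt)")
  }
  if (is.null(occupancy_multiplier)) {
    occupancy_multiplier <- setNames(rep(1, length(strains)), names(strains))
  }
  if (any(occupancy_multiplier <= 0)) abort("`occupancy_multiplier` must be positive")
  noise <- match.arg(noise)
  if (reads_per_sample < 0) abort("`reads_per_sample` must be >= 0")
  assert_scalar_number(read_length, "read_length", positive = TRUE)
  assert_scalar_number(post_pas_nt, "post_pas_nt", positive = TRUE)
  if (violation_fraction < 0 || violation_fraction >= 1) {
    abort("`violation_fraction` must lie in [0, 1)")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    chrom_sizes_pombe = chrom_sizes_pombe,
    chrom_sizes_spikein = chrom_sizes_spikein,
    spikein_cell_fraction = spikein_cell_fraction,
    mixing_jitter_sd = mixing_jitter_sd,
    ip_efficiency = ip_efficiency,
    strains = strains,
    occupancy_multiplier = occupancy_multiplier,
    mark_profiles = mark_profiles,
    reads_per_sample = as.integer(reads_per_sample),
    noise = noise, nb_dispersion = nb_dispersion,
    read_length = as.integer(read_length),
    post_pas_nt = as.integer(post_pas_nt),
    background_density = background_density,
    spikein_ip_density = spikein_ip_density,
    violation_fraction = violation_fraction,
    multimapper_fraction = multimapper_fraction,
    duplicate_fraction = duplicate_fraction
  ), class = "sim_config")
}

#' Default CTD phospho-mark shape library
#'
#' Qualitative occupancy shapes of the simulated marks along a gene and past
#' its PAS: total Pol II (`polii`) and Ser5P are uniform over the body; Ser2P
#' and Tyr1P rise logistically toward the 3' end and stay high into the
#' termination zone; Thr4P is low over the body and peaks downstream of the
#' PAS (Gaussian bump, default centre +300 nt).  Every downstream value is
#' additionally damped by the strain's readthrough decay `exp(-d / decay)`.
#'
#' @return Named list of shape-parameter lists, one per mark.
#' @export
default_mark_profiles <- function() {
  list(
    polii = list(shape = "uniform"),
    ser5p = list(shape = "uniform"),
    ser2p = list(shape = "logistic", baseline = 0.15, center = 0.65, scale = 0.10),
    tyr1p = list(shape = "logistic", baseline = 0.15, center = 0.70, scale = 0.10),
    thr4p = list(shape = "post_pas_peak", baseline = 0.15,
                 peak_offset_nt = 300, peak_sd_nt = 150, peak_height = 1)
  )
}

# Relative body shape at fractional positions rel in [0, 1).
mark_body_shape <- function(profile, rel) {
  switch(profile$shape,
    uniform = rep(1, length(rel)),
    logistic = profile$baseline + (1 - profile$baseline) /
      (1 + exp(-(rel - profile$center) / profile$scale)),
    post_pas_peak = rep(profile$baseline, length(rel)),
    abort(sprintf("unknown mark shape '%s'", profile$shape))
  )
}

# Relative downstream shape at d nt past the PAS, before readthrough decay.
mark_downstream_shape <- function(profile, d) {
  switch(profile$shape,
    uniform = rep(1, length(d)),
    logistic = rep(profile$baseline + (1 - profile$baseline) /
                     (1 + exp(-(1 - profile$center) / profile$scale)), length(d)),
    post_pas_peak = profile$baseline + profile$peak_height *
      exp(-(d - profile$peak_offset_nt)^2 / (2 * profile$peak_sd_nt^2)),
    abort(sprintf("unknown mark shape '%s'", profile$shape))
  )
}

#' True downstream occupancy at a distance past the PAS
#'
#' The generator's noiseless model of relative occupancy `d` nt downstream of
#' the PAS for a given strain and mark: the mark's downstream shape damped by
#' the strain's readthrough decay, `shape(d) * exp(-d / decay)`.  Useful as
#' ground truth when checking monotonicity of readthrough effects.
#'
#' @param config A [simulation_config()].
#' @param strain Strain name (must be in `config$strains`).
#' @param mark Mark name (must be in `config$mark_profiles`).
#' @param d Distances past the PAS, nt (vector).
#' @return Numeric vector of relative occupancies (gene level 1).
#' @export
true_downstream_occupancy <- function(config, strain, mark, d) {
  stopifnot(inherits(config, "sim_config"))
  if (!strain %in% names(config$strains)) {
    abort(sprintf("unknown strain '%s'; configured: %s", strain,
                  paste(names(config$strains), collapse = ", ")))
  }
  profile <- config$mark_profiles[[mark]]
  if (is.null(profile)) {
    abort(sprintf("unknown mark '%s'; configured: %s", mark,
                  paste(names(config$mark_profiles), collapse = ", ")))
  }
  mark_downstream_shape(profile, d) * exp(-d / config$strains[[strain]])
}

#' Simulate a gene annotation with planted selection failures
#'
#' Places `config$n_genes` genes left to right on the signal-genome
#' chromosomes with lognormal body lengths and exponential inter-gene gaps on
#' random strands.  A configurable fraction of gaps
#' (`config$violation_fraction`) is drawn deliberately short (30-250 nt) so
#' that both parts of the non-overlap selection filter — the downstream-TSS
#' gap and the opposite-strand PAS window — have genuine failures to detect.
#' Generation is a pure function of the config seed.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, writes `genes.gff3` and
#'   `genes.bed`.
#' @return Gene-model tibble (see [read_annotation()]) with the chromosome
#'   sizes attached as attribute `"chrom_sizes"`.
#' @export
simulate_annotation <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$chrom_sizes_pombe
  # genes per chromosome, proportional to size
  n_per <- floor(config$n_genes * sizes / sum(sizes))
  rem <- config$n_genes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  edge <- 700L # clearance at both chromosome ends for +/-500 nt windows

  genes <- local_seed(config$seed, {
    out <- vector("list", length(sizes))
    gi <- 0L
    for (ci in seq_along(sizes)) {
      nc <- n_per[ci]
      if (nc == 0L) next
      lens <- pmin(pmax(round(rlnorm(nc, log(600), 0.35)), 300L), 2500L)
      short <- runif(nc) < config$violation_fraction
      gaps <- ifelse(short, round(runif(nc, 30, 250)), round(550 + stats::rexp(nc, 1 / 400)))
      strand <- sample(c("+", "-"), nc, replace = TRUE)
      pos <- edge
      start <- integer(nc)
      for (j in seq_len(nc)) {
        start[j] <- pos + gaps[j]
        pos <- start[j] + lens[j]
      }
      if (pos > sizes[ci] - edge) {
        abort(sprintf(
          "infeasible packing: %d genes need %d bp on '%s' (%d bp available after %d bp edge clearance); reduce n_genes or enlarge the chromosome",
          nc, pos + edge, names(sizes)[ci], sizes[ci], edge))
      }
      end <- start + lens
      out[[ci]] <- tibble(
        gene_id = sprintf("g%04d", gi + seq_len(nc)),
        chrom = names(sizes)[ci], strand = strand,
        tss = ifelse(strand == "+", start, end),
        pas = ifelse(strand == "+", end, start)
      )
      gi <- gi + nc
    }
    bind_rows(out)
  })
  genes <- finalize_genes(genes)
  attr(genes, "chrom_sizes") <- sizes
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gff3(genes, file.path(dir, "genes.gff3"))
    write_bed(genes, file.path(dir, "genes.bed"))
  }
  genes
}

# Per-chromosome true signal intensity (occupancy units per base) for one
# strain x mark over the pombe genome; additive across overlapping genes.
gene_signal_vector <- function(genes, chrom_sizes, levels, decay, profile,
                               post_pas_nt) {
  sig <- lapply(chrom_sizes, numeric)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    size <- chrom_sizes[[chrom]]
    lev <- levels[[genes$gene_id[i]]]
    strand <- genes$strand[i]
    tss <- genes$tss[i]; pas <- genes$pas[i]
    len <- abs(pas - tss)
    body <- lev * mark_body_shape(profile, (seq_len(len) - 0.5) / len)
    down <- lev * mark_downstream_shape(profile, 0:(post_pas_nt - 1)) *
      exp(-(0:(post_pas_nt - 1)) / decay)
    if (strand == "+") {
      gpos <- c(tss:(pas - 1L), pas + 0:(post_pas_nt - 1L))
    } else {
      gpos <- c((tss - 1L):pas, pas - 1L - 0:(post_pas_nt - 1L))
    }
    val <- c(body, down)
    ok <- gpos >= 0L & gpos < size
    idx <- gpos[ok] + 1L
    sig[[chrom]][idx] <- sig[[chrom]][idx] + val[ok]
  }
  sig
}

# Apply the configured count-noise model to an intensity list (per-chrom),
# multiplying 50 nt bins by iid gamma rates for the negative-binomial regime.
apply_count_noise <- function(sig, config) {
  if (config$noise == "poisson") return(sig)
  shape <- 1 / config$nb_dispersion
  lapply(sig, function(v) {
    nb <- ceiling(length(v) / 50)
    mult <- rep(rgamma(nb, shape = shape, rate = shape), each = 50)[seq_along(v)]
    v * mult
  })
}

# Draw read 5' start positions from a per-chromosome intensity list.
draw_reads <- function(sig, n, read_length) {
  sizes <- lengths(sig)
  usable <- lapply(sig, function(v) v[seq_len(max(length(v) - read_length + 1L, 1L))])
  conc <- unlist(usable, use.names = FALSE)
  pos <- sample_positions(conc, n)
  offs <- cumsum(c(0, lengths(usable)))
  ci <- pmin(findInterval(pos, offs), length(sig))
  start <- pos - offs[ci]
  tibble(chrom = names(sig)[ci], start = as.integer(start),
         end = as.integer(start + read_length),
         strand = sample(c("+", "-"), n, replace = TRUE))
}

#' Simulate spike-in calibrated ChIP-seq samples
#'
#' For every requested strain x mark, draws one IP and one input sample of
#' single-end reads over the concatenated two-species genome, with known
#' ground truth.  Per-gene IP intensity is gene level x mark body shape, and
#' past the PAS it is damped by `exp(-d / readthrough_decay)`; a uniform
#' nonspecific background is added.  Spike-in reads are uniform over the
#' spike-in genome with mass proportional to the strain's realized mixing
#' fraction (configured fraction x optional lognormal jitter) and, for IP
#' samples, the IP efficiency that also scales the specific pombe signal.
#' Input samples mix the two genomes in proportion to genome size x cell
#' abundance.  Reads are then thinned into multi-mappers and augmented with
#' planted PCR duplicate copies per the config.
#'
#' @param config A [simulation_config()].
#' @param genes Annotation from [simulate_annotation()] (or any gene-model
#'   tibble with a `"chrom_sizes"` attribute covering `config`'s genome).
#' @param marks Marks to simulate; default all configured marks.
#' @param strains Strains to simulate; default all configured strains.
#' @return An object of class `chip_simulation`: list with `samples` (named
#'   list of per-sample lists holding `sample_id`, `strain`, `mark`, `role`
#'   and a `reads` tibble) and `truth` (gene levels, per-strain realized
#'   mixing and decay, per-sample read tallies, and the default-filter gene
#'   selection).
#' @export
simulate_chip_samples <- function(config, genes, marks = NULL, strains = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_genes(genes)
  if (config$reads_per_sample == 0L) abort("`reads_per_sample` must be positive")
  marks <- marks %||% names(config$mark_profiles)
  unknown <- setdiff(marks, names(config$mark_profiles))
  if (length(unknown)) {
    abort(sprintf("unknown mark(s) %s; configured marks: %s",
                  paste(unknown, collapse = ", "),
                  paste(names(config$mark_profiles), collapse = ", ")))
  }
  strains <- strains %||% names(config$strains)
  unknown <- setdiff(strains, names(config$strains))
  if (length(unknown)) {
    abort(sprintf("unknown strain(s) %s; configured strains: %s",
                  paste(unknown, collapse = ", "),
                  paste(names(config$strains), collapse = ", ")))
  }
  sizes_p <- config$chrom_sizes_pombe
  sizes_s <- config$chrom_sizes_spikein
  Gp <- sum(sizes_p); Gs <- sum(sizes_s)
  eff <- config$ip_efficiency
  get_eff <- function(strain) {
    if (!is.null(names(eff)) && strain %in% names(eff)) eff[[strain]] else unname(eff[1])
  }

  local_seed(config$seed + 1L, {
    levels <- setNames(rlnorm(nrow(genes), 0, 0.5), genes$gene_id)
    mixing <- setNames(config$spikein_cell_fraction *
                         exp(rnorm(length(strains), 0, config$mixing_jitter_sd) -
                               config$mixing_jitter_sd^2 / 2),
                       strains)
    samples <- list()
    tallies <- list()
    for (strain in strains) {
      decay <- config$strains[[strain]]
      m <- mixing[[strain]]
      E <- get_eff(strain)
      mult <- config$occupancy_multiplier[[strain]] %||% 1
      for (mark in marks) {
        profile <- config$mark_profiles[[mark]]
        sig <- gene_signal_vector(genes, sizes_p, levels * mult, decay,
                                  profile, config$post_pas_nt)
        for (role in c("ip", "input")) {
          if (role == "ip") {
            pombe_int <- lapply(sig, function(v) E * v + config$background_density)
            spike_den <- E * m * config$spikein_ip_density
          } else {
            pombe_int <- lapply(sizes_p, function(s) rep(1, s))
            spike_den <- m
          }
          spike_int <- lapply(sizes_s, function(s) rep(spike_den, s))
          pombe_int <- apply_count_noise(pombe_int, config)
          spike_int <- apply_count_noise(spike_int, config)
          mass_p <- sum(vapply(pombe_int, sum, numeric(1)))
          mass_s <- sum(vapply(spike_int, sum, numeric(1)))
          n <- config$reads_per_sample
          n_s <- rbinom(1L, n, mass_s / (mass_p + mass_s))
          reads <- bind_rows(
            draw_reads(pombe_int, n - n_s, config$read_length),
            draw_reads(spike_int, n_s, config$read_length)
          )
          reads$n_hits <- ifelse(runif(n) < config$multimapper_fraction, 2L, 1L)
          reads$is_pcr_dup <- FALSE
          n_dup <- round(config$duplicate_fraction * n)
          if (n_dup > 0) {
            dup <- reads[sample.int(n, n_dup, replace = TRUE), ]
            dup$is_pcr_dup <- TRUE
            reads <- bind_rows(reads, dup)
          }
          reads <- reads[sample.int(nrow(reads)), ]
          sample_id <- paste(strain, mark, role, sep = "_")
          samples[[sample_id]] <- list(sample_id = sample_id, strain = strain,
                                       mark = mark, role = role, reads = reads)
          tallies[[sample_id]] <- tibble(sample_id = sample_id, strain = strain,
                                         mark = mark, role = role,
                                         n_pombe = n - n_s, n_spikein = n_s,
                                         n_pcr_dup = n_dup)
        }
      }
    }
    sel <- select_genes(genes)
    truth <- list(
      levels = tibble(gene_id = genes$gene_id, level = unname(levels[genes$gene_id])),
      strains = tibble(strain = strains,
                       readthrough_decay_nt = unname(config$strains[strains]),
                       true_mixing = unname(mixing[strains]),
                       ip_efficiency = vapply(strains, get_eff, numeric(1)),
                       occupancy_multiplier =
                         unname(config$occupancy_multiplier[strains])),
      samples = bind_rows(tallies),
      selected = sel$gene_id[sel$selected],
      genome = list(pombe = sizes_p, spikein = sizes_s, Gp = Gp, Gs = Gs),
      seed = config$seed
    )
    structure(list(samples = samples, truth = truth, config = config),
              class = "chip_simulation")
  })
}

#' @export
print.chip_simulation <- function(x, ...) {
  cat(sprintf("<chip_simulation> %d samples (%s), seed %d\n",
              length(x$samples),
              paste(unique(x$truth$samples$strain), collapse = "/"),
              x$truth$seed))
  invisible(x)
}

#' Write a simulation's ground truth as JSON
#'
#' @param sim A `chip_simulation` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "chip_simulation"))
  jsonlite::write_json(list(
    levels = sim$truth$levels, strains = sim$truth$strains,
    samples = sim$truth$samples, selected = sim$truth$selected,
    genome = sim$truth$genome, seed = sim$truth$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
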