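test_that("species partitioning, deduplication and multimapper removal match a hand tally", {
  set.seed(31)
  sizes <- c(chrI = 10000L, spikein_chrI = 4000L)
  base <- tibble::tibble(
    chrom = sample(names(sizes), 850, replace = TRUE, prob = c(0.8, 0.2)),
    start = sample.int(3000L, 850, replace = TRUE),
    strand = sample(c("+", "-"), 850, replace = TRUE),
    n_hits = 1L)
  base$end <- base$start + 50L
  dup <- base[sample.int(850, 100), ]          # 100 planted duplicate copies
  multi <- dplyr::mutate(base[sample.int(850, 50), ],
                         start = start + 7L, end = end + 7L, n_hits = 2L)
  reads <- dplyr::bind_rows(base, dup, multi)[sample.int(1000), ]

  res <- partition_and_filter(reads, sizes)

  # independent set-based tally
  uniq <- reads[reads$n_hits == 1L, ]
  key <- paste(uniq$chrom, uniq$start, uniq$strand)
  kept <- uniq[!duplicated(key), ]
  expect_equal(res$counts$n_multimapper, 50L)
  expect_equal(res$counts$reads_pombe, sum(!startsWith(kept$chrom, "spikein_")))
  expect_equal(res$counts$reads_spikein, sum(startsWith(kept$chrom, "spikein_")))
  expect_equal(res$counts$reads_pombe_raw, sum(!startsWith(uniq$chrom, "spikein_")))
  expect_equal(res$counts$n_duplicate, nrow(uniq) - nrow(kept))
  # coverage mass equals retained reads x read length
  expect_equal(sum(res$coverage$pombe$chrI) + sum(res$coverage$spikein$spikein_chrI),
               nrow(kept) * 50)
})

test_that("reads on unknown references are excluded and reported", {
  sizes <- c(chrI = 1000L)
  reads <- tibble::tibble(chrom = c("chrI", "chrUn"), start = c(10L, 10L),
                          end = c(60L, 60L), strand = "+")
  expect_warning(res <- partition_and_filter(reads, sizes), "neither genome")
  expect_equal(res$counts$n_unassigned, 1L)
  expect_equal(res$counts$reads_pombe, 1L)
})

test_that("the spike-in scale factor follows the mixture-corrected formula", {
  ip <- tibble::tibble(reads_pombe = 5e5, reads_spikein = 2e5,
                       reads_pombe_raw = 5e5, reads_spikein_raw = 2e5)
  input <- tibble::tibble(reads_pombe = 1e6, reads_spikein = 1.5e5,
                          reads_pombe_raw = 1e6, reads_spikein_raw = 1.5e5)
  alpha <- spikein_scale_factor(ip, input)
  expect_equal(as.numeric(alpha), 1e6 * 0.15 / 2e5) # = 0.75
  expect_equal(as.numeric(alpha), 0.75)

  # determinism and input-depth invariance
  expect_equal(as.numeric(spikein_scale_factor(ip, input)), as.numeric(alpha))
  doubled <- dplyr::mutate(input, reads_pombe = reads_pombe * 2,
                           reads_spikein = reads_spikein * 2)
  expect_equal(as.numeric(spikein_scale_factor(ip, doubled)), as.numeric(alpha))

  none <- dplyr::mutate(input, reads_spikein = 0)
  expect_error(spikein_scale_factor(ip, none), "input_spikein")
})

test_that("track calibration is an exact scalar multiply with an exact inverse", {
  cov <- one_cov(c(10, 20, 0, 5))
  expect_equal(calibrate_track(cov, 1.0)$coverage$chrI, c(10, 20, 0, 5))
  scaled <- calibrate_track(one_cov(c(10, 20)), 0.75)
  expect_equal(scaled$coverage$chrI, c(7.5, 15))
  big <- calibrate_track(cov, 3.17)
  expect_equal(big$coverage$chrI / 3.17, cov$chrI, tolerance = 1e-12)
  expect_error(calibrate_track(cov, Inf), "finite")
  expect_error(calibrate_track(cov, -1), "positive")
})

test_that("the mixing-fraction estimator normalizes by genome size", {
  cnt <- tibble::tibble(reads_pombe = 1000, reads_spikein = 150,
                        reads_pombe_raw = 1000, reads_spikein_raw = 150)
  expect_equal(estimate_mixing_fraction(cnt, 1e6, 1e6), 0.15)
  half <- dplyr::mutate(cnt, reads_spikein = 75, reads_spikein_raw = 75)
  expect_equal(estimate_mixing_fraction(half, 1e6, 5e5), 0.15)
  zero <- dplyr::mutate(cnt, reads_pombe_raw = 0)
  expect_error(estimate_mixing_fraction(zero, 1e6, 1e6), "zero")
})

test_that("simulated input samples recover the configured mixing fraction", {
  cfg <- tiny_config(seed = 13, reads_per_sample = 50000)
  genes <- simulate_annotation(cfg)
  sim <- simulate_chip_samples(cfg, genes, strains = "wt")
  sizes <- c(cfg$chrom_sizes_pombe, cfg$chrom_sizes_spikein)
  input <- partition_and_filter(sim$samples$wt_polii_input$reads, sizes)
  est <- estimate_mixing_fraction(input, sum(cfg$chrom_sizes_pombe),
                                  sum(cfg$chrom_sizes_spikein))
  s <- input$counts$reads_spikein_raw
  p <- input$counts$reads_pombe_raw
  se <- est * sqrt(1 / s + 1 / p)
  expect_lt(abs(est - 0.15), 3 * se)
})
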