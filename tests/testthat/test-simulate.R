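test_that("identical configurations reproduce outputs bit-for-bit", {
  cfg <- tiny_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- simulate_annotation(cfg, dir = d1)
  g2 <- simulate_annotation(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
  s1 <- simulate_chip_samples(cfg, g1)
  s2 <- simulate_chip_samples(cfg, g2)
  expect_identical(s1$samples$wt_polii_ip$reads, s2$samples$wt_polii_ip$reads)
  expect_identical(s1$truth$strains, s2$truth$strains)
})

test_that("a lone gene passes every selection filter", {
  cfg <- simulation_config(seed = 1, n_genes = 1,
                           chrom_sizes_pombe = c(chrI = 20000L),
                           chrom_sizes_spikein = c(spikein_chrI = 5000L))
  genes <- simulate_annotation(cfg)
  expect_equal(nrow(genes), 1L)
  expect_true(select_genes(genes)$selected)
})

test_that("planted short gaps produce both kinds of selection failure", {
  cfg <- simulation_config(seed = 2, n_genes = 80,
                           chrom_sizes_pombe = c(chrI = 90000L, chrII = 90000L),
                           chrom_sizes_spikein = c(spikein_chrI = 10000L),
                           violation_fraction = 0.5)
  res <- select_genes(simulate_annotation(cfg))
  expect_true(any(grepl("downstream_tss_gap", res$reason)))
  expect_true(any(grepl("opposite_strand_overlap", res$reason)))
  expect_true(any(res$selected))
})

test_that("infeasible gene packing fails with an explicit constraint message", {
  cfg <- simulation_config(seed = 1, n_genes = 100,
                           chrom_sizes_pombe = c(chrI = 20000L),
                           chrom_sizes_spikein = c(spikein_chrI = 5000L))
  expect_error(simulate_annotation(cfg), "infeasible packing")
})

test_that("poisson input reads are uniform within counting error", {
  cfg <- tiny_config(seed = 11, noise = "poisson",
                     reads_per_sample = 100000, duplicate_fraction = 0,
                     multimapper_fraction = 0)
  genes <- simulate_annotation(cfg)
  sim <- simulate_chip_samples(cfg, genes, strains = "wt")
  reads <- sim$samples$wt_polii_input$reads
  starts <- reads$start[reads$chrom == "chrI"]
  n <- length(starts)
  usable <- 50000 - cfg$read_length + 1
  bin <- 5000
  counts <- table(cut(starts, breaks = seq(0, 50000, by = bin), right = FALSE))
  expected <- n * pmin(bin, usable - (seq_len(10) - 1) * bin) / usable
  z <- (as.numeric(counts) - expected) / sqrt(expected)
  expect_true(all(abs(z) < 4))
  expect_equal(mean(as.numeric(counts)[1:9] / expected[1:9]), 1, tolerance = 0.01)
})

test_that("true occupancy past the PAS is monotone in the readthrough decay", {
  cfg <- simulation_config(seed = 1, strains = c(a = 50, b = 100, c = 150, d = 400))
  d <- 350:400
  means <- vapply(c("a", "b", "c", "d"), function(s) {
    mean(true_downstream_occupancy(cfg, s, "polii", d))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # doubling the decay strictly raises occupancy at PAS+400
  expect_gt(true_downstream_occupancy(cfg, "b", "polii", 400),
            true_downstream_occupancy(cfg, "a", "polii", 400))
})

test_that("simulated distal coverage increases with the decay parameter", {
  cfg <- tiny_config(seed = 21, strains = c(slow = 400, fast = 50))
  genes <- simulate_annotation(cfg)
  sel <- dplyr::filter(select_genes(genes), selected)
  sim <- simulate_chip_samples(cfg, genes)
  sizes <- c(cfg$chrom_sizes_pombe, cfg$chrom_sizes_spikein)
  mass_distal <- function(sample) {
    cov <- partition_and_filter(sample$reads, sizes)$coverage$pombe
    cs <- lapply(cov, function(v) c(0, cumsum(v)))
    mean(vapply(seq_len(nrow(sel)), function(i) {
      termscape:::oriented_mass(cs[[sel$chrom[i]]], sel$pas[i], sel$strand[i],
                                350, 400)
    }, numeric(1)))
  }
  expect_gt(mass_distal(sim$samples$slow_polii_ip),
            2 * mass_distal(sim$samples$fast_polii_ip))
})

test_that("configuration and sampling errors are explicit", {
  cfg <- tiny_config(seed = 1)
  genes <- simulate_annotation(cfg)
  expect_error(simulate_chip_samples(cfg, genes, marks = "h3k4me3"),
               "unknown mark.*polii")
  cfg0 <- tiny_config(seed = 1)
  cfg0$reads_per_sample <- 0L
  expect_error(simulate_chip_samples(cfg0, genes), "reads_per_sample")
  expect_error(simulation_config(spikein_cell_fraction = 1.2), "0, 1")
  expect_error(simulation_config(strains = c(wt = -5)), "positive")
})

test_that("structure fixtures plant links on the right side of the cutoff", {
  fix <- simulate_structure_fixture(seed = 4, n_residues = 40, n_links = 12,
                                    max_planted_distance = 30)
  expect_true(all(fix$truth$distance[fix$truth$planted] <= 30))
  expect_true(all(fix$truth$distance[!fix$truth$planted] > 30))
  expect_true(all(fix$truth$e_value[fix$truth$planted] < 1e-5))
  expect_true(all(fix$truth$e_value[!fix$truth$planted] > 1e-5))

  empty <- simulate_structure_fixture(seed = 4, n_residues = 5, n_links = 0,
                                      n_decoys = 0)
  csv <- readLines(empty$links)
  expect_length(csv, 1L) # header only
  expect_error(simulate_structure_fixture(seed = 1, n_residues = 1, n_links = 0),
               ">= 2")
  expect_error(simulate_structure_fixture(seed = 1, n_residues = 3, n_links = 10),
               "possible")
})

test_that("titration fixtures honour the isotherm limits", {
  flat <- simulate_titration(Kd = 500, concentrations = c(0, 10, 100),
                             noise_sd = 0)
  expect_equal(flat$anisotropy[1], 0.05) # A_free at P = 0
  sat <- simulate_titration(Kd = 1, concentrations = 1e9, noise_sd = 0)
  expect_equal(sat$anisotropy, 0.20, tolerance = 1e-6) # A_bound at saturation
  expect_error(simulate_titration(Kd = 500, noise_sd = -1), "noise_sd")
})
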