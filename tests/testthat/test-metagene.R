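two_genes <- function() {
  make_genes(~id, ~chrom, ~strand, ~tss, ~pas,
             "plus", "chrI", "+", 2000L, 3000L,
             "minus", "chrI", "-", 8000L, 7000L)
}

test_that("a constant track fills the matrix with that constant and conserves mass", {
  genes <- two_genes()
  track <- one_cov(rep(2.5, 10000))
  mat <- build_metagene_matrix(track, genes, anchor = "pas",
                               upstream = 500, downstream = 1000, bin_size = 10)
  expect_equal(dim(mat$matrix), c(2L, 150L))
  expect_true(all(mat$matrix == 2.5))
  # mass conservation: sum(bins) * bin_size = per-base sum over the window
  expect_equal(sum(mat$matrix[1, ]) * 10, 2.5 * 1500)
})

test_that("a single-base spike lands in the anchor bin on either strand", {
  genes <- two_genes()
  cov <- rep(0, 10000)
  cov[3000 + 1] <- 7   # first base downstream of the + gene PAS (position 3000)
  cov[7000 - 1 + 1] <- 7 # first base downstream of the - gene PAS
  mat <- build_metagene_matrix(one_cov(cov), genes, anchor = "pas",
                               upstream = 500, downstream = 1000, bin_size = 10)
  hit <- which(mat$matrix["plus", ] != 0)
  expect_equal(mat$bins$start[hit], 0)
  expect_equal(unname(mat$matrix["plus", hit]), 7 / 10)
  expect_equal(which(mat$matrix["minus", ] != 0), hit)
})

test_that("metagene matrices are invariant under genome mirror reflection", {
  cfg <- tiny_config(seed = 17)
  genes <- simulate_annotation(cfg)
  sel <- dplyr::filter(select_genes(genes), selected)
  sim <- simulate_chip_samples(cfg, genes, strains = "wt")
  sizes <- c(cfg$chrom_sizes_pombe, cfg$chrom_sizes_spikein)
  cov <- partition_and_filter(sim$samples$wt_polii_ip$reads, sizes)$coverage$pombe
  mat <- build_metagene_matrix(cov, sel, anchor = "pas")
  M <- cfg$chrom_sizes_pombe[["chrI"]]
  mirrored_cov <- one_cov(rev(cov$chrI))
  mirrored <- sel
  mirrored$strand <- ifelse(sel$strand == "+", "-", "+")
  mirrored$tss <- M - sel$tss
  mirrored$pas <- M - sel$pas
  mat2 <- build_metagene_matrix(mirrored_cov, mirrored, anchor = "pas")
  expect_equal(mat2$matrix[rownames(mat$matrix), ], mat$matrix)
})

test_that("profiles average genes, then replicates, and bootstrap degenerates", {
  genes <- two_genes()
  m1 <- build_metagene_matrix(one_cov(rep(1, 10000)), genes[1, ], anchor = "pas")
  expect_equal(meta_profile(m1)$signal, unname(m1$matrix[1, ]))
  m3 <- build_metagene_matrix(one_cov(rep(3, 10000)), genes[1, ], anchor = "pas")
  avg <- meta_profile(list(m1, m3))
  expect_true(all(avg$signal == 2))
  boot <- meta_profile(m1, boot = 50)
  expect_true(all(boot$lo == boot$signal & boot$hi == boot$signal))
})

test_that("upstream equalization shifts profiles onto the reference", {
  genes <- two_genes()
  base <- meta_profile(build_metagene_matrix(one_cov(rep(2, 10000)), genes,
                                             anchor = "pas"))
  shifted <- dplyr::mutate(base, signal = signal + 5)
  adj <- equalize_upstream(list(ref = base, other = shifted), "ref")
  expect_equal(attr(adj, "shifts")[["other"]], -5)
  expect_equal(attr(adj, "shifts")[["ref"]], 0)
  wide <- tidyr::pivot_wider(adj, names_from = "strain", values_from = "signal")
  expect_equal(wide$other, wide$ref)
  expect_error(equalize_upstream(list(ref = base), "ref",
                                 upstream_window = c(0, 0)), "window")
})

test_that("readthrough strains diverge only downstream of the PAS after equalization", {
  cfg <- tiny_config(seed = 23, strains = c(fast = 50, slow = 400),
                     reads_per_sample = 60000)
  genes <- simulate_annotation(cfg)
  sel <- dplyr::filter(select_genes(genes), selected)
  sim <- simulate_chip_samples(cfg, genes)
  tracks <- calibrate_simulation(sim)
  profs <- lapply(tracks, function(t) meta_profile(build_metagene_matrix(t, sel)))
  names(profs) <- vapply(tracks, `[[`, "", "strain")
  adj <- equalize_upstream(profs, "fast", upstream_window = c(-500, -100))
  wide <- tidyr::pivot_wider(adj, names_from = "strain", values_from = "signal")
  up <- wide$position < -100
  down <- wide$position > 100 & wide$position < 500
  rel_up <- mean(abs(wide$slow[up] - wide$fast[up])) / mean(wide$fast[up])
  rel_down <- mean(wide$slow[down] - wide$fast[down]) / mean(wide$fast[up])
  expect_lt(rel_up, 0.1)
  expect_gt(rel_down, 0.3)
})

test_that("window validation and rendering behave as documented", {
  genes <- two_genes()
  track <- one_cov(rep(1, 10000))
  expect_error(build_metagene_matrix(track, genes, bin_size = 7),
               "does not divide")
  expect_error(build_metagene_matrix(track, genes[0, ]), "empty")
  mat <- build_metagene_matrix(track, genes)
  prof <- meta_profile(mat)
  prefix <- file.path(withr::local_tempdir(), "prof")
  paths <- render_metagene(prof, prefix)
  back <- readr::read_tsv(paths[["tsv"]], show_col_types = FALSE)
  expect_equal(back$signal, prof$signal)
  expect_equal(back$position, prof$position)
})
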