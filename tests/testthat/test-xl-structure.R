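toy_structure <- function() {
  tibble::tibble(
    chain = c("A", "A", "A", "B", "B", "B"),
    resno = c(1L, 2L, 3L, 1L, 2L, 3L),
    x = c(0, 3.8, 7.6, 0, 3, 20),
    y = c(0, 0, 0, 4, 14.5, 0),
    z = 0)
}

test_that("E-value filtering is strict and collapses unordered duplicate pairs", {
  links <- tibble::tibble(
    protein_a = c("p1", "p1", "p2", "p1", "p1", "p2", "p1", "p1", "p1", "p2"),
    residue_a = c(10L, 10L, 5L, 20L, 10L, 5L, 30L, 40L, 50L, 60L),
    protein_b = c("p2", "p2", "p1", "p2", "p2", "p1", "p2", "p2", "p2", "p1"),
    residue_b = c(99L, 99L, 10L, 80L, 99L, 10L, 70L, 60L, 50L, 40L),
    e_value = c(1e-6, 1e-7, 1e-8, 1e-9, 1e-4, 1e-10, 1e-5, 1e-6, 1e-7, 1e-8))
  out <- filter_links(links)
  # row 5 fails (1e-4) and row 7 sits exactly on the boundary (strict <)
  expect_equal(sum(out$count), 8L)
  expect_equal(nrow(out), 5L) # 3 duplicated pairs collapse (one swapped-order)
  p1_10 <- out[out$residue_a == 10L | out$residue_b == 10L, ]
  expect_equal(sort(p1_10$count), c(2L, 2L))
  expect_true(all(out$e_value < 1e-5))

  expect_equal(nrow(filter_links(dplyr::mutate(links, e_value = 1e-5))), 0L)
  expect_error(filter_links(dplyr::select(links, -e_value)), "e_value")
})

test_that("crosslink distances are Euclidean with unmapped links preserved", {
  st <- toy_structure()
  links <- tibble::tibble(protein_a = "pA", residue_a = c(1L, 1L, 9L),
                          protein_b = "pB", residue_b = c(1L, 1L, 2L),
                          e_value = 1e-8)
  links$residue_a[2] <- 1L; links$residue_b[2] <- 1L
  res <- map_distances(links, st, c(pA = "A", pB = "B"), cutoff = 30)
  expect_equal(res$distance[1], 4)   # (0,0,0) -> (0,4,0)
  expect_equal(res$status[3], "unmapped")
  expect_equal(unname(attr(res, "summary")["unmapped"]), 1L)

  # hand case: (0,0,0) to (3,4,0) is exactly 5 A
  st2 <- tibble::tibble(chain = c("A", "B"), resno = 1L,
                        x = c(0, 3), y = c(0, 4), z = 0)
  one <- tibble::tibble(protein_a = "pA", residue_a = 1L,
                        protein_b = "pB", residue_b = 1L, e_value = 1e-8)
  expect_equal(map_distances(one, st2, c(pA = "A", pB = "B"))$distance, 5)
  # a residue crosslinked to itself sits at 0 A and is satisfied
  self <- tibble::tibble(protein_a = "pA", residue_a = 1L,
                         protein_b = "pA", residue_b = 1L, e_value = 1e-8)
  selfres <- map_distances(self, st2, c(pA = "A"))
  expect_equal(selfres$distance, 0)
  expect_equal(selfres$status, "satisfied")

  expect_error(map_distances(one, st2, c(pA = "A", pB = "Z")), "Z")
})

test_that("planted fixture links are all satisfied at the planting cutoff", {
  fix <- simulate_structure_fixture(seed = 8, n_residues = 50, n_links = 15,
                                    max_planted_distance = 30)
  st <- read_ca_structure(fix$pdb)
  links <- filter_links(read_crosslinks(fix$links))
  res <- map_distances(links, st, fix$chain_map, cutoff = 30)
  expect_equal(nrow(res), 15L)          # decoys removed by the E-value filter
  expect_true(all(res$status == "satisfied"))
  # coordinates survive the PDB round trip to write/read precision
  back <- dplyr::arrange(st, chain, resno)
  orig <- dplyr::arrange(fix$coords, chain, resno)
  expect_equal(back$x, orig$x, tolerance = 1e-3)
})

test_that("contact extraction is thresholded exactly and matches the all-pairs oracle", {
  st <- toy_structure() # A1-B2 distance = sqrt(9 + 14.5^2) = 14.9..., A3-B3 = 12.4
  d_a1b2 <- sqrt(3^2 + 14.5^2)
  expect_lt(d_a1b2, 15)
  contacts <- extract_contacts(st, "A", "B", cutoff = 15)
  oracle <- brute_force_contacts(st, "A", "B", 15)
  expect_equal(nrow(contacts), nrow(oracle))
  expect_equal(contacts$distance, oracle$distance)
  # 14.9 in, 15.1 out
  st15 <- tibble::tibble(chain = c("A", "B"), resno = 1L, x = c(0, 14.9), y = 0, z = 0)
  expect_equal(nrow(extract_contacts(st15, "A", "B", 15)), 1L)
  st15$x[2] <- 15.1
  expect_equal(nrow(extract_contacts(st15, "A", "B", 15)), 0L)
  # cutoff 0 keeps only coincident atoms
  co <- tibble::tibble(chain = c("A", "B", "B"), resno = c(1L, 1L, 2L),
                       x = c(1, 1, 2), y = 0, z = 0)
  expect_equal(extract_contacts(co, "A", "B", 0)$residue_b, 1L)
  expect_error(extract_contacts(st, character(0), "B"), "non-empty")

  # larger randomized oracle check on the fixture geometry
  fix <- simulate_structure_fixture(seed = 5, n_residues = 120, n_links = 0,
                                    n_decoys = 0)
  got <- extract_contacts(fix$coords, "A", "B", cutoff = 15)
  want <- brute_force_contacts(fix$coords, "A", "B", 15)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$residue_a, want$residue_a)
  expect_equal(got$distance, want$distance)
})

test_that("the minimal mmCIF reader agrees with the PDB route", {
  fix <- simulate_structure_fixture(seed = 2, n_residues = 8, n_links = 0,
                                    n_decoys = 0)
  st <- read_ca_structure(fix$pdb)
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.label_atom_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    sprintf("ATOM %d CA %s %d %.3f %.3f %.3f 1.00",
            seq_len(nrow(st)), st$chain, st$resno, st$x, st$y, st$z),
    "#"), cif)
  st2 <- read_ca_structure(cif)
  expect_equal(st2, st)
})

test_that("alignment transfer is the identity for identical sequences and shifts by insertions", {
  s <- "MKLVDSTRRQW"
  map <- align_residue_map(s, s)
  expect_equal(map$target_pos, map$source_pos)
  expect_equal(attr(map, "identity"), 1)

  # one extra N-terminal residue in the target shifts every position by +1
  map2 <- align_residue_map(s, paste0("G", s))
  expect_equal(map2$target_pos, map2$source_pos + 1L)

  # a deletion in the target leaves the deleted position untransferable
  del <- paste0(substr(s, 1, 4), substr(s, 6, nchar(s)))
  map3 <- align_residue_map(s, del)
  expect_true(is.na(map3$target_pos[5]))
  expect_equal(map3$target_pos[6:11], 5:10)

  contacts <- tibble::tibble(chain_a = "D", residue_a = 1L,
                             chain_b = "A", residue_b = c(2L, 5L))
  moved <- transfer_by_alignment(contacts, s, del, columns = "residue_b")
  expect_equal(moved$residue_b, c(2L, NA))
  expect_equal(moved$transfer_status, c("transferred", "untransferable"))

  expect_error(align_residue_map("MKLV", "WWWW"), "identity")
  expect_error(align_residue_map("", "MKLV"), "non-empty")
})

test_that("exports are deterministic and round-trip through the reader", {
  links <- tibble::tibble(protein_a = "pA", residue_a = c(3L, 8L),
                          protein_b = "pB", residue_b = c(14L, 2L),
                          e_value = c(1e-8, 1e-9))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_links(links[1, ], csv, "xinet_csv")
  expect_length(readLines(csv), 2L) # header + one row
  export_links(links, csv, "xinet_csv")
  back <- read_crosslinks(csv, column_map = c(
    protein_a = "Protein1", residue_a = "PepPos1",
    protein_b = "Protein2", residue_b = "PepPos2"))
  expect_equal(back$residue_a, links$residue_a)
  expect_equal(back$protein_b, links$protein_b)

  fix <- simulate_structure_fixture(seed = 9, n_residues = 30, n_links = 7,
                                    n_decoys = 0)
  pb <- withr::local_tempfile(fileext = ".pb")
  export_links(fix$truth, pb, "chimera_pseudobond", chain_map = fix$chain_map)
  lines <- readLines(pb)
  expect_length(lines, 7L)
  expect_equal(lines[1], sprintf("#0:%d.A@CA #0:%d.B@CA",
                                 fix$truth$residue_a[1], fix$truth$residue_b[1]))
  expect_error(export_links(links[0, ], csv, "xinet_csv"), "empty")
})
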