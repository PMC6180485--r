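# Toy structure and titration fixtures with planted ground truth, for
# exercising the crosslink-validation and binding-fit stages offline.

#' Simulate a two-chain Calpha structure with planted cross-links
#'
#' Builds a minimal PDB of two `n_residues`-long chains (A and B) of Calpha
#' atoms whose inter-chain distances span from a few angstroms to far beyond
#' `max_planted_distance`, then samples `n_links` "true" cross-links among
#' residue pairs whose actual Calpha-Calpha distance is at most
#' `max_planted_distance` (assigned E-values below 1e-5) and `n_decoys`
#' decoy links among pairs exceeding it (E-values above 1e-5).  Distances in
#' the returned truth table are the exact distances in the emitted
#' coordinates.
#'
#' @param seed Integer seed.
#' @param n_residues Residues per chain (>= 2).
#' @param n_links Number of planted true links (may be 0).
#' @param max_planted_distance Distance ceiling for true links, angstroms
#'   (default 30, the lysine-lysine crosslinker restraint).
#' @param n_decoys Number of decoy links (default half of `n_links`).
#' @param dir Output directory (created if needed).
#' @return List with `pdb` and `links` (file paths), `truth` (tibble of all
#'   emitted links with exact distance and `planted` flag), `coords` (tibble
#'   of chain/residue/xyz), and `chain_map` (protein name -> chain ID).
#' @export
simulate_structure_fixture <- function(seed, n_residues, n_links,
                                       max_planted_distance = 30,
                                       n_decoys = ceiling(n_links / 2),
                                       dir = tempfile("xlfix")) {
  if (n_residues < 2) abort("`n_residues` must be >= 2")
  if (n_links > n_residues^2) {
    abort(sprintf("n_links (%d) exceeds the %d possible inter-chain pairs",
                  n_links, n_residues^2))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  coords <- local_seed(seed, {
    i <- seq_len(n_residues)
    jit <- function(n) rnorm(n, 0, 0.4)
    bind_rows(
      tibble(chain = "A", resno = i, x = 3.8 * (i - 1) + jit(n_residues),
             y = jit(n_residues), z = jit(n_residues)),
      # chain B starts close to A and drifts away, so inter-chain distances
      # cover both sides of any sensible cutoff
      tibble(chain = "B", resno = i, x = 3.8 * (i - 1) + jit(n_residues),
             y = 6 + (i - 1) * (120 / n_residues) + jit(n_residues),
             z = jit(n_residues))
    )
  })
  a <- filter(coords, .data$chain == "A")
  b <- filter(coords, .data$chain == "B")
  dmat <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
                 outer(a$z, b$z, "-")^2)
  near <- which(dmat <= max_planted_distance, arr.ind = TRUE)
  far <- which(dmat > max_planted_distance, arr.ind = TRUE)
  if (n_links > nrow(near)) {
    abort(sprintf("only %d residue pairs lie within %.1f A; cannot plant %d links",
                  nrow(near), max_planted_distance, n_links))
  }
  if (n_decoys > nrow(far)) n_decoys <- nrow(far)
  truth <- local_seed(seed + 1L, {
    pick <- function(pairs, k, planted) {
      if (k == 0L || nrow(pairs) == 0L) {
        return(tibble(protein_a = character(0), residue_a = integer(0),
                      protein_b = character(0), residue_b = integer(0),
                      e_value = numeric(0), distance = numeric(0),
                      planted = logical(0)))
      }
      sel <- pairs[sample.int(nrow(pairs), k), , drop = FALSE]
      ev <- if (planted) 10^-runif(k, 6, 9) else 10^-runif(k, 1, 4.5)
      tibble(protein_a = "protA", residue_a = as.integer(sel[, 1]),
             protein_b = "protB", residue_b = as.integer(sel[, 2]),
             e_value = ev, distance = dmat[sel], planted = planted)
    }
    bind_rows(pick(near, n_links, TRUE), pick(far, n_decoys, FALSE))
  })
  pdb_path <- file.path(dir, "fixture.pdb")
  links_path <- file.path(dir, "links.csv")
  write_ca_pdb(coords, pdb_path)
  readr::write_csv(select(truth, -"planted", -"distance"), links_path)
  list(pdb = pdb_path, links = links_path, truth = truth, coords = coords,
       chain_map = c(protA = "A", protB = "B"))
}

# Minimal PDB emitter: one CA atom per residue, fixed-width ATOM records.
write_ca_pdb <- function(coords, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), coords$chain, coords$resno,
    coords$x, coords$y, coords$z)
  readr::write_lines(c(lines, "END"), path)
  invisible(path)
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Generates anisotropy readings for a 1:1 binding reaction at fixed labelled
#' ligand concentration `L` from the ligand-depletion isotherm (see
#' [fraction_bound()]) with optional Gaussian noise:
#' `A(P) = A_free + (A_bound - A_free) * f(P, L, Kd) + N(0, noise_sd)`.
#'
#' @param Kd Dissociation constant, nM (> 0).
#' @param A_free,A_bound Anisotropy of free and fully bound ligand.
#' @param L Labelled ligand concentration, nM (default 75, the two-repeat CTD
#'   peptide concentration used in the assay being modelled).
#' @param concentrations Protein concentrations titrated, nM (>= 0).
#' @param noise_sd Gaussian noise SD on anisotropy (>= 0).
#' @param seed Integer seed.
#' @param replicate Replicate label attached to the series.
#' @return Tibble with columns `protein_nM`, `anisotropy`, `replicate`.
#' @export
simulate_titration <- function(Kd, A_free = 0.05, A_bound = 0.20, L = 75,
                               concentrations = 75 * 2^seq(-4, 6),
                               noise_sd = 0, seed = 1L, replicate = 1L) {
  assert_scalar_number(Kd, "Kd", positive = TRUE)
  assert_scalar_number(L, "L", positive = TRUE)
  if (any(concentrations < 0)) abort("`concentrations` must be non-negative")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  f <- fraction_bound(concentrations, L, Kd)
  local_seed(seed, {
    tibble(protein_nM = concentrations,
           anisotropy = A_free + (A_bound - A_free) * f +
             rnorm(length(concentrations), 0, noise_sd),
           replicate = replicate)
  })
}
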