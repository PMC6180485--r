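# Independent oracles and small shared fixtures.  Each oracle is a direct,
# unoptimized restatement of the definition it checks, kept free of any
# package internals.

# O(n^2) all-pairs gene-selection oracle: literal translation of the two
# filter criteria, one pair at a time.
brute_force_select <- function(genes, gap = 275, up = 250, down = 500) {
  n <- nrow(genes)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok_a <- TRUE
    ok_b <- TRUE
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      if (genes$strand[j] == genes$strand[i]) {
        d <- if (genes$strand[i] == "+") genes$tss[j] - genes$pas[i]
             else genes$pas[i] - genes$tss[j]
        if (d >= 0 && d <= gap) ok_a <- FALSE
      } else {
        w <- if (genes$strand[i] == "+") c(genes$pas[i] - up, genes$pas[i] + down)
             else c(genes$pas[i] - down, genes$pas[i] + up)
        lo <- min(genes$tss[j], genes$pas[j])
        hi <- max(genes$tss[j], genes$pas[j])
        if (lo < w[2] && hi > w[1]) ok_b <- FALSE
      }
    }
    keep[i] <- ok_a && ok_b
  }
  keep
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
enumerate_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_along(a)])
  splits <- utils::combn(length(pooled), n1)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  p_lo <- mean(stats <= obs)
  p_hi <- mean(stats >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force all-pairs Calpha distance table between two chain sets.
brute_force_contacts <- function(coords, chains_a, chains_b, cutoff) {
  out <- list()
  k <- 0L
  a <- coords[coords$chain %in% chains_a, ]
  b <- coords[coords$chain %in% chains_b, ]
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        k <- k + 1L
        out[[k]] <- data.frame(chain_a = a$chain[i], residue_a = a$resno[i],
                               chain_b = b$chain[j], residue_b = b$resno[j],
                               distance = d)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(chain_a = character(0), residue_a = integer(0),
                      chain_b = character(0), residue_b = integer(0),
                      distance = numeric(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chain_a, df$residue_a, df$chain_b, df$residue_b), ]
}

# Equilibrium bound-ligand concentration by root finding on the mass-action
# equation (P - x)(L - x) = Kd * x, an independent route to fraction bound.
root_fraction_bound <- function(P, L, Kd) {
  if (P == 0) return(0)
  f <- function(x) (P - x) * (L - x) - Kd * x
  x <- stats::uniroot(f, c(0, min(P, L)), tol = 1e-13)$root
  x / L
}

# Small fast simulation settings shared across tests; any default can be
# overridden through `...`.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 30,
         chrom_sizes_pombe = c(chrI = 50000L),
         chrom_sizes_spikein = c(spikein_chrI = 15000L),
         reads_per_sample = 20000,
         mark_profiles = default_mark_profiles()["polii"]),
    list(...))
  do.call(simulation_config, args)
}

# Build a gene-model tibble by hand.
make_genes <- function(...) {
  df <- tibble::tribble(...)
  names(df) <- c("gene_id", "chrom", "strand", "tss", "pas")
  df
}

# One-chromosome coverage list with given values.
one_cov <- function(values, chrom = "chrI") {
  setNames(list(values), chrom)
}
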