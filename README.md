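# termscape

Quantitative analysis of RNA polymerase II transcription **termination** from
**spike-in calibrated ChIP-seq**, with companion tools for crosslinking
mass-spectrometry restraints and fluorescence-anisotropy binding curves.

## The problem

When Pol II transcribes past a gene's polyadenylation site (PAS) it must be
released from the template; phosphatase mutants (e.g. loss of the PP1
phosphatase Dis2 in fission yeast) delay that release, so polymerase — and
3'-end CTD phospho-marks such as Thr4P — persist hundreds of nucleotides past
the PAS. Detecting this *readthrough* quantitatively requires:

1. **Calibration.** A fixed proportion of foreign cells (*S. cerevisiae*,
   15% of the *S. pombe* cells) is spiked in before crosslinking. After
   aligning to a concatenated two-species genome, discarding multi-mappers
   and PCR duplicates, the signal coverage of an IP sample is scaled by

   `alpha = 1e6 * m_hat / N_spike^IP`, with `m_hat = N_spike^input / N_pombe^input`,

   where the input-sample species ratio `m_hat` corrects for drift in the
   cell-mixture ratio between samples.

2. **Gene selection.** Windows around the PAS are only interpretable for
   genes without neighbours in them: a gene is kept iff the nearest
   same-strand downstream TSS is **> 275 nt** past its PAS and no
   opposite-strand transcription unit intersects **PAS − 250 nt … PAS + 500
   nt** (strand-oriented, half-open).

3. **The termination index.** For each gene, signal mass in the proximal
   window **B1 = [PAS, PAS+50)** and the distal window
   **B2 = [PAS+350, PAS+400)** is divided by the mass in **[PAS−500,
   PAS+500)**. Within each strain the indices are rescaled so that the
   median of B1 is exactly 1; elevated scaled B2 means delayed release.
   Strains are compared by a two-sided Wilcoxon rank-sum test on per-gene
   scaled B2.

Everything runs on synthetic data with known ground truth: the package ships
a generator for two-species read mixtures (configurable spike-in fraction,
mixing jitter, IP efficiency, Poisson or negative-binomial counts), gene
annotations with planted selection failures, per-strain post-PAS occupancy
decay `exp(-d / decay)`, CTD phospho-mark shape profiles, toy structures
with planted crosslinks, and noisy titrations. TSS/PAS-anchored metagene
matrices, profile plots, upstream-equalized strain overlays, Calpha-distance
validation of crosslinks (30 A restraint), 15 A inter-chain contact
extraction with alignment-based cross-species residue transfer, and a
ligand-depletion 1:1 binding-isotherm fit (`Kd` at 75 nM labelled peptide)
round out the toolkit.

## Worked example

```r
library(termscape)
library(dplyr)

config <- simulation_config(seed = 42, n_genes = 120,
                            chrom_sizes_pombe = c(chrI = 120000L, chrII = 120000L),
                            chrom_sizes_spikein = c(spikein_chrI = 40000L),
                            reads_per_sample = 1e5)
genes    <- simulate_annotation(config)           # wt (decay 50 nt) vs dis2d (400 nt)
selected <- filter(select_genes(genes), selected) # 103 of 120 genes kept
sim      <- simulate_chip_samples(config, genes, marks = "polii")
tracks   <- calibrate_simulation(sim)             # spike-in scale factors per strain

term <- termination_by_strain(tracks, selected, mark = "polii")
term |> group_by(strain) |>
  summarise(median_scaled_b1 = median(scaled_b1),
            median_scaled_b2 = median(scaled_b2))
#>   strain median_scaled_b1 median_scaled_b2
#> 1 dis2d                 1           0.614
#> 2 wt                    1           0.0373
compare_strains(term)
#>   strain_a strain_b   n_a   n_b statistic  p_value hl_shift median_a median_b
#> 1 dis2d    wt         103   103        11 3.51e-35   -0.566    0.614   0.0373
```

The medians of scaled B1 are 1 by construction; the termination-defective
strain's median scaled B2 (0.614) sits ~16-fold above the wild type's
(0.037), and the rank-sum test rejects equality at p = 3.5e-35 — the
defective strain retains far more polymerase 350-400 nt past the PAS.

Binding curves work the same way:

```r
fit <- fit_titration(simulate_titration(Kd = 500, noise_sd = 0.002, seed = 1))
fit
#> <binding_fit> Kd = 502.8 nM (SE 27), A_free = 0.04996, A_bound = 0.2019
tidy(fit)    # broom-style parameter table; autoplot(fit) draws the curve
```

`run_pipeline(list(seed = 1), "outdir")` chains every stage (simulate,
select, calibrate, metagene, termination, comparison) into one reproducible
run with plain-text outputs and a provenance-stamped `summary.json`;
`inst/scripts/termscape-run.R` wraps it for the shell.

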