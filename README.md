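# cryosig

Comparative-genomics signatures of cold adaptation in closely related
prokaryotes.

Psychrophilic and psychrotolerant microbes leave detectable fingerprints in
their genomes: lower G+C content of genomic DNA, RNA genes and all three
codon positions (GC1/GC2/GC3), a shifted amino-acid composition (more Lys
and Asn, less Arg and Pro), and proteomes with higher predicted
conformational flexibility — usually without a matching change in
isoelectric point. `cryosig` packages the full analysis that turns a set of
annotated genome assemblies plus ortholog tables into statistical statements
about such a cold-adapted group: for microbial comparative genomicists who
have a candidate clade (here called the *PD group*, after the polar and
deep-earth haloarchaea that motivated the pipeline) and a reference group,
and want the contrasts quantified reproducibly.

## What it computes

* **Genome QC and deduplication** — assemblies are dropped when they have
  more than 300 contigs, N50 below 20 kb, completeness below 95% or
  contamination above 5%; survivors are single-linkage clustered at
  AAI ≥ 99.5% and one representative is kept per cluster
  (completeness ↓ contamination ↑ N50 ↓ id as tiebreaks).
* **Compositional profiles** — genome size, CDS count, coding density
  (union of CDS intervals), G+C of genome / CDS / hypothetical CDS /
  tRNA / rRNA / pooled RNA, pooled codon-position GC1/GC2/GC3, and the 20
  amino-acid proportions from translated CDS (genetic code 11).
* **Protein properties** — per-protein sliding-window flexibility
  (window 9, unweighted; Vihinen B-factor scale by default) and
  isoelectric point (Henderson–Hasselbalch charge model, bisection root),
  averaged per genome.
* **Pangenome structure** — rarefaction of pan/core gene counts over
  genome permutations (medians of 1,000 permutations by default), Heaps'
  law fits `n(N) = κ·N^(−α)` of the new-gene discovery and core-decay
  curves (α < 1 ⇒ open pangenome), discovery prediction for the next
  genome, and the cloud (< 15%), shell (15–95%), soft-core (95–<100%)
  and strict-core (100%) occupancy partition.
* **Group statistics** — per-trait two-sided Wilcoxon rank-sum tests
  (exact when n ≤ 12 without ties) with Benjamini–Hochberg adjustment and
  figure-style stars (`*` < 0.05, `**` < 0.01, `***` < 0.005), plus
  Bray–Curtis distances, a two-group PERMANOVA (exact label enumeration on
  small designs, seeded permutations otherwise) and NMDS for functional
  gene-count tables.
* **Synthetic study sets** — a generator that writes FASTA/GFF3 genomes
  with programmed GC3, amino-acid and tRNA-GC group offsets,
  presence/absence matrices with known Heaps exponent, and overdispersed
  count tables with controlled group effects — every programmed parameter
  is recorded in a truth table.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Fit pangenome openness on a simulated 30-genome set with a known exponent,
then compare two genome groups with programmed cold-adaptation signatures:

```r
library(cryosig)

pa  <- simulate_presence_absence(pangenome_sim_spec(30, core_size = 800,
                                                    kappa = 400, alpha = 0.6,
                                                    seed = 7))
rar <- rarefy(pa$matrix, n_permutations = 500, seed = 8)
fit_heaps(rar, "pan_new_genes")
#> <heaps_fit> pan_new_genes: kappa = 453.948, alpha = 0.6323 +/- 0.0173 (open, alpha < 1)
predict_discovery(fit_heaps(rar, "pan_new_genes"), 31)
#> [1] 51.8       # expected new genes from a 31st genome
```

The fitted α ≈ 0.63 recovers the programmed 0.6 (the `± 0.0173` is the
across-permutation spread); α < 1 classifies the pangenome as open, and a
31st genome is expected to contribute ~52 new gene clusters.

```r
sim    <- simulate_genomes(genome_sim_spec(n_pd = 5, n_ref = 5,
                                           genes_per_genome = 300, seed = 9))
prof   <- composition_profiles(sim$genomes)
pp     <- protein_profiles(sim$genomes)
traits <- dplyr::left_join(prof, pp[, c("genome_id", "mean_flexibility",
                                        "mean_pi")], by = "genome_id")
compare_traits(traits) |>
  dplyr::filter(trait %in% c("gc3", "aa_K", "mean_flexibility", "mean_pi"))
#>   trait            median_focal median_other   p_raw  p_adj direction  stars
#> 1 gc3                   77.4         79.3    0.00794 0.0385 down_in_PD *
#> 2 aa_K                   0.0390       0.0281 0.00794 0.0385 up_in_PD   *
#> 3 mean_flexibility       1.00         1.00   0.00794 0.0385 up_in_PD   *
#> 4 mean_pi                4.66         4.72   0.222   0.420  ns         NS
```

The generator programmed GC3 3 points lower and Lys 1 point higher in the
PD group: both are flagged in the right direction after BH adjustment, the
induced flexibility gain is detected, and the isoelectric point — which was
not shifted — stays non-significant.

A thin command-line front end over the same functions ships as
`inst/exec/cryosig` (`simulate`, `qc`, `composition`, `protprops`,
`pangenome`, `compare`, `run-all`), and `run_pipeline()`/`run_config()`
orchestrate all stages into one seeded, byte-reproducible run directory.

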