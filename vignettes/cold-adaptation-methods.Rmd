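---
title: "Methods: detecting genomic signatures of cold adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting genomic signatures of cold adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cryosig` implements a comparative-genomics workflow for contrasting a
candidate cold-adapted genome group (the "PD" label throughout) against a
reference group of close relatives. This vignette explains the models and
procedures, the tunable parameters and their defaults, what the synthetic
study generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## Inputs and scope

The pipeline consumes finished artifacts: assembled genomes (FASTA) with
PROKKA-style GFF3 annotations, per-genome assembly metrics (QUAST/CheckM
style), a pairwise average amino-acid identity (AAI) matrix, an
ortholog-cluster presence/absence matrix, and functional gene-count tables.
Producing those artifacts (assembly, annotation, ortholog clustering, AAI
computation, functional annotation) is out of scope; the package treats
them as input contracts and validates them on the way in.

## Quality control and deduplication

A genome is removed when *any* of the following holds: more than 300
contigs, N50 below 20,000 bp, completeness below 95%, contamination above
5%. All inequalities are strict, so a genome sitting exactly on every
threshold passes, and every violated rule is reported (not just the first).
Genomes with pairwise AAI at or above 99.5% are treated as redundant;
because redundancy chains (A~B and B~C imply one strain even if
AAI(A,C) < 99.5), clusters are single-linkage connected components of the
redundancy graph. The retained representative is chosen deterministically:
highest completeness, then lowest contamination, then highest N50, then the
lexicographically smallest genome id. All thresholds are arguments.

## Compositional traits

G+C content is `100·(G+C)/(A+C+G+T)` with IUPAC ambiguity codes excluded
from numerator and denominator (a deterministic rule, preferred over
fractional weighting for reproducibility); a sequence with no unambiguous
base yields `NA` rather than 0. Codon-position GC1/GC2/GC3 pool codons over
all retained coding sequences of a genome — one value per genome, because
the group comparisons operate on genome-level distributions — and a per-CDS
mode exists for finer work. On ambiguity-free CDS the identity
`gc_cds = (GC1 + GC2 + GC3)/3` holds exactly and is asserted in the tests.

Coding density is the genome fraction covered by the *union* of CDS
intervals, so overlapping or duplicated CDS count once. "Hypothetical"
sequences are CDS whose product annotation matches the case-insensitive
pattern `hypothetical protein` (configurable regex), and their G+C is
computed on the nucleotide CDS. RNA G+C pools tRNA and rRNA genes; each
class is also reported alone, with `NA` when a genome lacks annotated
members of a class.

Translation uses genetic code table 11 (the bacterial/archaeal standard;
configurable). The code table is applied uniformly — alternative initiator
codons are not promoted to Met — so translations are exactly reproducible
by a codon-dictionary lookup. CDS whose length is not a multiple of 3 are
dropped with a warning (a strict mode errors instead), and CDS translating
with an internal stop are flagged pseudogenes; both are excluded from
composition and protein statistics, with exclusion counts logged, since
finished annotations make these rare.

## Protein flexibility and isoelectric point

Flexibility is a sliding-window average: windows of 9 residues (odd,
unweighted), window score = mean of per-residue scale values, protein
score = mean over window positions; unknown residues (`X`) take the scale
mean, and proteins shorter than the window are excluded from the genome
mean with a logged count. The genome aggregate is an unweighted mean over
proteins (a length-weighted variant is a one-line change), matching
genome-scale distribution comparisons.

Two scales ship. The default is the Vihinen–Torkkila–Riikonen normalized
B-factor scale, on which the canonical psychrophile substitutions — more
Lys, fewer Arg and Pro — *increase* the score, consistent with the
interpretation of flexibility as a cold-adaptation proxy. The
Bhaskaran–Ponnuswamy average-flexibility index is available as an
alternative, but note its ordering differs (it scores Arg and Pro as more
flexible than Lys), so the same compositional shift moves it the other
way; analyses about cold adaptation should state the scale they use. Only
relative group differences under a fixed scale are scientifically
interpretable here; absolute values depend on the scale and window.

The isoelectric point models net charge as Henderson–Hasselbalch terms for
the N- and C-terminus and the side chains of K, R, H (positive) and D, E,
C, Y (negative). Charge is strictly decreasing in pH, so the root is found
by bisection on [0, 14], run to a pH tolerance of 1e-3. A charge-magnitude
stopping rule was considered and rejected: weakly charged peptides sit on a
wide plateau where |charge| is tiny far from the true root, which would
make results disagree with a dense grid scan. Three pKa sets are shipped
(IPC protein — the default, IPC peptide, EMBOSS); all reported contrasts
pin one set, and the group-difference conclusions do not hinge on the set.

## Pangenome rarefaction and Heaps' law

For each of `n_permutations` (default 1,000) random genome orders, the pan
curve is the cumulative union of gene clusters, the core curve the
cumulative intersection, and the discovery curve the per-step pan
increment; element-wise medians across permutations summarize them. An
exhaustive mode enumerates all `G!` orders for small G and is used to
validate the permutation machinery.

Openness is fitted on the discovery curve as `n(N) = κ·N^(−α)` over
N = 2..G by Levenberg–Marquardt least squares (log–log regression provides
starting values; the low-level optimizer is used because the zero-residual
noise-free case must converge cleanly, and it is validated to recover exact
power laws to 1e-6). α < 1 classifies the pangenome as open. The quoted
`alpha_se` is the across-permutation variability (α refit on each
permutation's own curve, then the standard deviation); the asymptotic
fit SE is reported alongside as `alpha_se_fit`. Core decline is fitted with
the same power-law form; an exponential alternative would be a reasonable
extension, as the true functional form of core decay is model-dependent.
`predict_discovery` evaluates the fitted form: expected new genes
`κ·N^(−α)` for the discovery curve, and `κ·[(N−1)^(−α) − N^(−α)]` core
genes lost for the decay curve.

Occupancy partitioning uses cloud < 15%, shell 15–95%, soft core
95–<100%, strict core = 100%. Published descriptions of these bins
sometimes stop the soft core at 99%, leaving 99–<100% unassigned; the
package's default closes that gap (soft core = [95%, 100%)) and also emits
the literal binning with the gap bin reported, so either convention can be
reproduced.

## Group statistics

"Wilcoxon test" means the two-sample rank-sum (Mann–Whitney) test,
two-sided, since the groups are independent genomes. The null distribution
is enumerated exactly when the combined n is at most 12 and ties are
absent; otherwise the normal approximation with tie and continuity
corrections is used. An exhaustive sweep of all achievable 6+6 statistics
shows the approximation is within 0.016 of enumeration everywhere and
within 0.01 wherever p < 0.2, so decisions at the usual thresholds are
unaffected.

p-values are adjusted with Benjamini–Hochberg within one trait family per
call — all traits passed to `compare_traits()` together form one family
(e.g. the 20 amino acids plus the GC and protein traits of a profile
table). Raw and adjusted values are always both reported so any other
family convention can be reconstructed. Stars follow the figure
convention `*` < 0.05, `**` < 0.01, `***` < 0.005, applied to the adjusted
value by default. Direction is the sign of the focal-minus-reference median
difference, reported only for significant traits.

PERMANOVA is the two-group Anderson pseudo-F computed from total and
within-group sums of squared distances. When `choose(n, n1)` distinct
label assignments number at most 10,000 they are all enumerated and
`p = #{F ≥ F_obs}/#assignments` (note that with equal group sizes each
assignment's complement gives the same F, so the smallest achievable p on a
3|3 design is 2/20); otherwise seeded random permutations give
`p = (1 + #{F_perm ≥ F_obs})/(1 + n_permutations)` (default 999). The
pseudo-F agrees with `vegan::adonis2` to numerical precision; the
in-package implementation exists for the enumeration mode and seed
discipline. NMDS is Kruskal stress-1 via `vegan::metaMDS` (monotone
regression, best of 20 seeded random starts); stress is descriptive output,
not a test statistic. All-zero distance matrices are rejected as
degenerate rather than producing a 0/0 pseudo-F.

## The synthetic study generator

The generator exists so every claim the pipeline makes can be checked
against programmed truth. Its defaults encode the study design that
motivated the package: 10 cold-adapted vs 60 reference genomes; a
reference GC3 target of 80% with a −3 point PD offset (high-GC
haloarchaea have strongly GC-rich third positions); per-genome GC3 targets
jittered with SD 1.0 point (within-clade spread, chosen so that a clade
of close relatives is tight but not degenerate); an acidic haloarchaeal
amino-acid frequency vector with a PD shift of Lys +1, Asn +0.5, Arg −1,
Pro −0.5 percentage points (the classic cold signature, summing to zero);
tRNA G+C 62% with a −2 point PD offset and rRNA G+C 58% in both groups, so
the tRNA contrast is real and the rRNA contrast is null by construction;
1,000 CDS per genome at 250 ± 80 codons. The CDS count is deliberately
reduced-scale (real haloarchaeal genomes carry ~3,000): compositional
estimates concentrate with the total residue count, which remains in the
hundreds of thousands per genome, while simulation stays fast enough to
regenerate everything at test time.

Proteins are drawn residue-wise from the (jittered) group frequencies and
back-translated with expectation-matched GC3 control: every residue except
Met and Trp has both strong-ending (G/C) and weak-ending (A/T) synonymous
codons, so a single closed-form strong-codon probability
`s = (t − f_MW)/(1 − f_MW)` hits the genome's GC3 target `t` in
expectation (clamped with a recorded flag when infeasible). This is O(total
residues), with no rejection sampling. Stop codons are written as TAA,
which dilutes realized GC3 by a factor L/(L+1) per gene — about 0.3
points at the default lengths — identically in both groups, so programmed
*offsets* are preserved. Genes are placed on 5 contigs with Poisson-spaced
intergenic spacers (mean 120 bp at 60% G+C), on random strands
(minus-strand genes are written reverse-complemented), and 30% of CDS are
labelled "hypothetical protein". A truth table records every realized
per-genome parameter so tests recompute expectations without re-reading
generator code.

The presence/absence generator's power-law model is exchangeable by
construction: each accessory gene is present in each genome independently
with its own occupancy probability, drawn from a truncated density
∝ `p^(α−2)` on [1e-5, 1], with the latent pool size calibrated (Beta-tail
asymptotics) so the expected discovery curve is `κ·N^(−α)` for *any*
genome order. A sequential construction in which later genomes inherit a
coin-flip of previously seen genes was evaluated and rejected: it is not
exchangeable, and its permuted discovery curve decays with a fitted
exponent far above the nominal one, which would defeat the recovery
studies. The `constant_unique` model (core plus fixed private genes,
true α = 0) and `identical` model cover the degenerate ends. Count tables
are negative-binomial (size 5) around lognormal family means, with a
`1 + effect_size` multiplier on 30% of families in the focal group;
`effect_size = 0` is the exchangeable null used for permutation-uniformity
checks.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: phylogenetic autocorrelation between
genomes (draws are independent given group), selection-driven codon-usage
bias beyond the GC3 target, indels/operon structure/gene order, annotation
error, and any correlation between compositional traits and gene content.
A real clade-versus-reference contrast should consider phylogenetic
non-independence before interpreting p-values causally.

## Calibration and problem sizes

The suite checks, at fixed seeds: type-I error of the per-trait test within
[0.03, 0.07] at nominal 0.05 over 1,000 null replicates (10 vs 60 design);
power ≥ 80% for a −1.5 point GC3 shift at SD 1.0 over 200 replicates;
uniformity of PERMANOVA p under the exchangeable null across 500 replicates
(KS test); Heaps recovery |α̂ − 0.6| ≤ 0.1 at G = 50, κ = 500 with 200
rarefaction permutations; and exact-oracle agreement for N50, codon GC,
translation, flexibility, pI, exact Wilcoxon, 3|3 PERMANOVA and 8-genome
exhaustive rarefaction. The end-to-end study in the tests uses a 2 × 10
genome set at the default genome scale; `scripts/acceptance.R` runs the
full 10 vs 60 design at 500 CDS per genome and a 70-genome pangenome with a
1,215-gene core and κ = 1300, α = 0.564 — sizes chosen to mirror the
motivating study's scale while regenerating everything from code at run
time.

## Known limitations

Single-linkage AAI clustering can chain distinct strains through
intermediates; the cluster report makes this auditable. The Heaps α for
core decay is a descriptive fit, not a mechanistic model. ProtScale-style
absolute flexibility values depend on scale and window, so only
within-analysis contrasts are meaningful. PERMANOVA here is two-group
one-factor only. The pipeline assumes one annotation provenance across
genomes; mixing annotators changes CDS counts and hypothetical-protein
labelling in ways the QC stage does not detect.
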