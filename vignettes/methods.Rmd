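---
title: "Models and methods: molecular genealogy from replicate aDNA genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: molecular genealogy from replicate aDNA genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeokin)
```

# Scope

`palaeokin` reconstructs genealogical relationships among ancient
individuals from classical degraded-DNA marker panels: mtDNA control-region
haplotypes with diagnostic coding SNPs, Y-chromosomal biallelic markers and
Y-STR haplotypes, and autosomal STR profiles typed in replicate. Its
bundled worked dataset is the published genotype material from seven
medieval burials at Tavan Tolgoi; every number the package's documentation
quotes for that material is recomputed from the bundled replicate tables by
the test suite and by `scripts/acceptance.R`, never hard-coded.

# Replicate consensus

Low-template samples are typed repeatedly (here: three extraction
replicates per sample across two laboratories). `call_consensus()` votes at
genotype level: a replicate supports its entire allelotype at a locus, not
each allele separately. The genotype held by a strict majority of the
*successful* calls, and by at least `min_count` of them, is the consensus.

* `min_fraction = 0.5` (strict majority). The sequencing arm of the source
  protocol demanded agreement in at least 5 of 6 experiments; the STR
  tables carry only three replicates per sample, so the threshold is
  configurable and defaults to the strict majority, which reproduces every
  printed consensus row.
* `min_count = 2` guards against a "majority of one" when only a single
  replicate amplified.
* Any non-unanimity among successful calls flags the cell discordant, even
  when a majority exists (e.g. the CSF1PO cell of MN0104, consensus 11/12
  over a dissenting 12/12). Across the 6-sample x 8-locus autosomal table
  this yields 5 discordant cells of 48.
* A tie yields an explicit candidate set (the D21S11 cell of MN0126:
  30/30 vs 30/33.2, one surviving vote each). Downstream kinship expands
  candidates combinatorially into scenarios and reports each; candidate
  genotypes are never averaged.
* A wholly failed replicate casts no vote and does not count toward
  discordance.

Genotype-level voting was chosen over allele-level voting because it is the
convention the printed consensus rows follow, and it keeps the ambiguity
structure honest: allele-level voting would have silently resolved the
D21S11 tie toward 30/30.

# Kinship model

Pairwise relationships are compared through the standard forensic
likelihood-ratio framework over Cotterman IBD-sharing coefficients
$(k_0, k_1, k_2)$: unrelated $(1,0,0)$, parent-offspring $(0,1,0)$, full
siblings $(\tfrac14,\tfrac12,\tfrac14)$. Per locus,

$$LR = k_0 + k_1 T_1 + k_2 T_2, \qquad
T_1 = \frac{P(g_2 \mid g_1, \text{1 IBD})}{P(g_2)}, \quad
T_2 = \frac{[g_1 = g_2]}{P(g_2)},$$

with $P(g_2)$ the Hardy-Weinberg genotype probability and the one-IBD term
computed by the transmission argument (a uniformly chosen allele of $g_1$
is passed IBD, the partner allele is drawn from the population). Loci are
assumed independent (product rule, no co-ancestry correction), and a single
reported allele is treated as an apparent homozygote.

Design choices:

* **No-mutation model.** A locus with zero shared alleles is a Mendelian
  exclusion; it zeroes the parent-offspring likelihood exactly. This is
  what makes the package's central conclusion about the two male family
  members frequency-independent: they mismatch completely at D21S11 (under
  either candidate) and at FGA, so the parent-offspring posterior is 0
  under any strictly positive frequency table. A mutation-tolerant variant
  is deliberately out of scope.
* **Arithmetic.** LRs are computed in double precision. Exact rational
  arithmetic was considered and rejected: with decimal frequencies the
  denominators of an 8-locus product overflow fixed-precision integers,
  and no arbitrary-precision dependency is warranted, because the only
  decision that must be exact -- zero vs non-zero -- is structural: the
  $k_1$/$k_2$ terms of an excluded locus are exactly 0.0 in IEEE
  arithmetic, so the product is an exact zero.
* **Posterior convention.** Posteriors are Bayes' rule under a uniform
  prior over the evaluated hypothesis set unless the caller supplies one;
  every report states the prior. The source study's "nearly 100%" and
  "64.2%" figures rest on an unpublished Korean allele-frequency table and
  an unstated prior; they are treated as non-reproducible. In their place
  the test suite checks properties: locus LRs agree with a Monte-Carlo
  pedigree oracle (one million simulated pairs per hypothesis on a
  three-allele locus, every genotype configuration, within three standard
  errors), and on 500 simulated pairs per relationship over the 8-locus
  panel true parent-offspring pairs never show an exclusion while
  unrelated pairs show one at the enumerated rate.
* **Frequency table.** The bundled table
  (`allele_freqs_synthetic.tsv`) is explicitly synthetic: uniform-ish
  masses over plausible allele ranges covering every fixture allele.
  Alleles absent from a user table can be given a configurable floor
  frequency, which is logged whenever substituted.

# mtDNA haplotypes and haplogroups

Haplotypes are rCRS-difference sets in forensic notation; `16093C` is a
substitution, `249del` a deletion, `309+C`/`310+3C` insertions named by
anchor position with an optional copy count. A reader for the alternative
"point" dialect (`309.1C`) is provided, but the plus dialect is canonical.

`call_variants()` aligns a sample region sequence against the reference
segment by exact global dynamic programming with unit mismatch and gap
costs (regions are at most ~450 bp, so the quadratic DP is instant and
optimal; the row recurrence is solved with a vectorised running-minimum
scan). Indels inside homopolymer runs are then re-anchored at the 3' end
of the run -- the standard forensic mtDNA convention -- which makes calls
deterministic regardless of where the aligner placed the gap. Ambiguous
(non-ACGT) sample bases are excluded from the variant set and reported
with a warning. The inverse operation `apply_variants()` exists chiefly so
that round-trip invariance can be tested: for canonical, non-overlapping
variant sets, call(apply(V)) = V.

Haplogroup assignment walks a loadable rule tree and returns the deepest
node all of whose path-accumulated diagnostic SNPs are observed. The
bundled tree encodes exactly the diagnostic coding SNPs typed in the
source material: M (10398G) with children CZ (4715G) and M9 (3394C); D
(5178A) with child D4 (3010A); R (10398C + 12705C). Two structural
decisions deserve note:

* D and R sit directly under the reference root rather than inside the
  full phylogenetic nesting, because the D4 samples were typed only at
  3010/5178 (no 10398 call is printed); under the "all path SNPs observed"
  rule a phylogenetically nested D would be unreachable from the printed
  data. The tree mirrors what was typed, not the whole mtDNA phylogeny,
  and is a plain text file users can replace with a fuller motif table.
* Labels N, Z and G belong to the study's panel vocabulary but no defining
  SNP for them is printed; a rule node without a defining SNP would match
  vacuously, so they are omitted from the bundled tree. Within CZ, no
  printed SNP separates C from Z, so classification stops at CZ.

`haplotype_distance()` is the symmetric difference of variant sets over
shared region spans; the contamination screen flags a researcher reference
at distance ≤ `max_distance` (default 0, i.e. only an exact match over
shared regions is treated as contamination evidence).

# Y-chromosome lineage

`classify_y_haplogroup()` returns the deepest haplogroup whose defining
marker is observed derived and whose root-path carries no observed
ancestral call. Missing intermediate markers do not block descent -- the
partially typed male still reaches R1b from M207 + M343 -- but the call is
flagged `inferred`. Derived calls on incompatible branches raise an error
rather than a silent choice.

Y-STR haplotypes are compared only at loci typed in both profiles;
categories are identical / partial / mismatch on allele multisets. A
single reported value at the duplicated DYS385 locus is treated as one
observed allele with the partner possibly dropped out, scoring *partial*
against a two-allele partner that contains it. This dropout-aware rule is
what reproduces the printed "identical in 7 of 8 plus one shared DYS385
allele" count; treating the single value as a homozygote would have
scored that locus a mismatch. DYS389II is compared as printed, without
subtracting DYS389I.

# Authenticity

`detect_damage()` works at clone-consensus level: per treatment arm, the
substitutions carried by a strict majority of clones form the arm's
consensus; a position where the inactive-UDG consensus differs from the
direct haplotype by C→T or G→A becomes a damage call, marked reverted when
the active-UDG consensus agrees with direct. Strand is not tracked -- both
transition directions are accepted as deamination-consistent. Any other
discrepancy between arms is reported as an anomaly, not damage. The
clone-level fractions behind each call are attached for transparency.

The clone sequences behind the source study's single damage example (a
reverted C→T at 16,250) are not printed; the packaged test reconstructs
that case synthetically to the study's description, and the simulator
provides planted-truth validation.

# The synthetic-data generator

`simulate_pedigree()` draws founder autosomal genotypes under
Hardy-Weinberg from a frequency table, copies Y haplotypes father→son and
mtDNA lineages mother→child, and transmits one uniformly chosen allele per
parent per autosomal locus. `simulate_replicates()` corrupts a true
profile with whole-replicate failure, per-locus dropout, allelic dropout
(heterozygote → apparent homozygote) and ±1-repeat misreads, emitting the
same table layout the consensus reader consumes. `simulate_deamination()`
converts each eligible C (G) of each inactive-arm clone to T (A) with a
given rate and records the planted positions. All generators require a
seed and are bit-reproducible given it.

What the simulator does *not* emulate -- and what passing tests therefore
do not establish about real data: stutter artefacts and peak-height
information, microvariant creation (misreads move whole repeats only),
inter-generational mutation, position-dependent damage profiles along the
molecule, and population substructure in the frequency table. The
generator exists to validate the inferential machinery under the model's
own assumptions, not to mimic electrophoretic reality.

# Validation problem sizes

The package's checks run at sizes chosen to give tight Monte-Carlo
standard errors while staying desk-scale: one million simulated pairs per
hypothesis for the locus-LR oracle; 500 simulated pairs per relationship
for recovery; 10,000 randomized variant strings and 10,000 randomized
replicate tables for the round-trip and consensus invariants; 100
random-variant-set alignment round-trips over both control regions. All
comparisons against simulation use three-standard-error bounds.

# Known limitations

* Kinship is pairwise (plus the trio Mendelian check); no joint
  multi-person likelihoods.
* The bundled haplogroup trees are diagnostic minima, not full phylogenies
  (no PhyloTree/ISOGG calling).
* No θ-correction, inbreeding, or mutation modelling in the LRs.
* Heteroplasmy is not modelled; ambiguous bases are excluded with a
  warning.
* The reference segment shipped for sequence-level demonstrations is an
  explicitly synthetic stand-in, not the rCRS itself; all study
  computations run from printed variant and genotype tables, which need no
  reference sequence.
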