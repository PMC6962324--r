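---
title: "Methods: strain-level phage diversity and transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level phage diversity and transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagestrain)
```

## The problem

crAss-like bacteriophages are among the most prevalent viruses of the human
gut; the prototypical member (p-crAssphage) has a ~97 kb circular dsDNA
genome with 88 predicted genes. Shotgun metagenomes let us ask three
questions about them without isolation or culture: is the phage present in a
sample, how diverse is the within-host strain population, and do specific
strains move between hosts (mother to infant at birth, donor to recipient in
fecal microbiota transplantation)? `phagestrain` implements that analysis
chain on top of tabular inputs — classified read counts, per-position
pileups, gene annotations, and assembled genome sequences — and pairs it
with a simulator that generates all of those with known ground truth.

## Detection from classified read counts

A sample is called positive when at least 1,000 reads are classified to the
taxon, which for 100 bp reads on a ~100 kb genome corresponds to roughly 1x
coverage; virome-enriched sequencing, where PCR amplification inflates
low-level signal, uses a 10,000-read (10x) threshold instead. Samples with
fewer than 10,000 total reads are excluded before any call is made, and
relative abundance uses post-preprocessing totals as the denominator (at
the ~8.7 M read depths typical of these cohorts the 1,000-read threshold is
a relative abundance around 0.011%). Percentages are reported at two
significant figures. Subject-level prevalence counts a subject positive if
any non-excluded sample is positive — the weakest defensible rule, adopted
deliberately because per-sample carriage fluctuates near the detection
limit.

## Variant sites from pileups

Against the reference, every position with total depth below 10x is
`uncovered`. An allele must be supported by at least 5 reads to be called
at all. One qualifying allele makes the site fixed (reference or
alternate); exactly two make it *multiallelic*, the package's proxy for
within-sample strain diversity, with the minor allele fraction computed
from the two called alleles' counts only (sequencing-error bases at other
nucleotides are excluded by construction). Sites with three or more
qualifying alleles are kept as multiallelic on the top two alleles by
count and flagged; ties between candidate alleles break by base order
A<C<G<T so output is deterministic. A covered site where no allele reaches
5 reads has no callable allele and is reported `uncovered`, but its
position is retained separately so that comparisons never mistake it for a
fixed-reference site. There is no analogue of an assembler's QUAL filter
for raw pileups; the depth and support thresholds stand in for it, which
is a documented limitation rather than a hidden one.

## F_multi and the detectability denominator

Raw multiallelic-site counts are not comparable between samples whose
coverage differs by orders of magnitude: a minor allele at fraction 0.1 is
invisible below 50x if alleles need 5 supporting reads. `F_multi(x)` is
the proportion of multiallelic sites with minor AF > x among the genome
positions *covered well enough to detect* a minor allele at fraction x.
The package makes "well enough" concrete as

```
depth >= ceiling(min_allele_reads / x)
```

i.e. the depth at which the expected number of minor-allele reads reaches
the support threshold. This is the central interpretive decision in the
package and is isolated behind `detectable_sites()` so an alternative rule
(e.g. a binomial detection-probability criterion) can be swapped in
without touching anything else. The AF grid is fixed at
{0.40, 0.30, 0.20, 0.10}; `sites_per_kb()` re-expresses the same ratio as
sites/kb and percent of genome. The denominator counts *all* sufficiently
covered positions, not only positions passing any further per-site filter
— with pileup-level calling those coincide, and the all-positions reading
keeps the denominator independent of the numerator's thresholds.

Group comparisons use the two-sided Wilcoxon rank-sum test, exact for
small tie-free groups and normal-approximated with tie correction
otherwise, with no multiple-testing correction — each AF threshold is
reported as its own comparison. Longitudinal summaries report per-timepoint
values and flag timepoints whose detectability denominator differs from
the subject median by more than a factor of 2, where F_multi values are
not directly comparable; a least-squares slope summarises direction only.
A mixed-model treatment of repeated sampling is deliberately out of scope.
When a subject has several samples, diversity analyses use the one with
the highest coverage (`select_best_sample()`).

## Mother-to-infant allele sharing

At maternal multiallelic sites where the infant is fixed and covered at
10x, the infant's allele is classed as the maternal major, the maternal
minor, or neither (an allele the mother does not carry, e.g. a
post-acquisition mutation). The accompanying rank-sum test compares
maternal AFs of infant-detected vs non-detected alleles; a major-allele
excess is the signature of the dominant maternal strain founding the
infant population. The analysis is only attempted when the mother has at
least 10 multiallelic sites, below which the test is uninformative.

## Effect prediction and the mutation null model

Each substitution is classified `synonymous`, `nonsynonymous`, `nonsense`
(alternate codon is a stop, reference codon is not) or `noncoding` using
the standard genetic code; for these four categories the standard code and
the bacterial/plastid code agree, so no code switch is exposed. Stop-loss
and start-codon changes that alter the amino acid count as nonsynonymous —
no extra categories are introduced. A substitution inside overlapping
genes takes the most severe category (nonsense > nonsynonymous >
synonymous) so each site contributes exactly one category and the
multinomial test stays well-defined.

The null model enumerates all 3L single-base changes of the genome with
equal probability — no mutational spectrum — and classifies each one.
Observed category counts are tested per category with a binomial
likelihood-ratio statistic

```
G = 2 [ O ln(O / n p0) + (n - O) ln((n - O) / n(1 - p0)) ]
```

against chi-square with 1 df (0·ln 0 = 0), and overall with the
multinomial G-test on k − 1 df. Two observed distributions (e.g. mothers
vs infants) are compared category-wise with the two-sample binomial LRT.
At n = 200 draws from the null the per-category type-I error at
alpha = 0.05 sits within [0.03, 0.07] (checked in the test suite), which
is as close to nominal as the discrete counts allow.

Gene-level ranking normalises nonsynonymous multiallelic-site counts by
gene length (sites/kb); ties break by gene start coordinate. Window
profiles use 1,500 bp windows stepped by 200 bp: coverage fraction (a
sample covers a window when at least half its positions are at 10x — the
window-aggregation rule is otherwise underdetermined), GC, GC skew
(G − C)/(G + C), pooled multiallelic count at AF > 0.1, and
log2((N + 1)/(S + 1)) with a +1 pseudocount on both terms so windows with
zero synonymous sites stay finite. The final partial window is truncated
at the genome end, never wrapped, so with step = size the window counts
sum exactly to the total.

## Pairwise genome comparison

Assembled genomes are compared with an anchor-chain-extend aligner that
reports the same two quantities a whole-genome aligner would: the
length-weighted average identity over 1-1 aligned segments and the total
aligned length. Anchors are maximal exact matches built from 20-mers
unique in both sequences (unique 20-mers are effectively specific at the
100 kb scale, and dropping repeated ones removes repeat-induced spurious
anchors). The highest-weight colinear chain is selected by weighted
longest-increasing-subsequence; gaps up to 2,000 bp between anchors are
closed by global alignment (match +1, mismatch −1, gap open −4, gap
extend −1; equal-length gaps reduce to direct base comparison), and larger
gaps split the alignment so unrelated insertions are not forced into the
identity average. Both orientations are tried; the one with more aligned
sequence wins. Average identity is length-weighted across segments —
total matches over total aligned columns — so short perfect segments
cannot mask long divergent ones.

SNP identity between two samples is
`100 × (1 − differing fixed SNPs / sites covered ≥10x in both)`;
multiallelic and uncallable positions are excluded from the numerator but
remain in the co-coverage denominator. Identity matrices are clustered
with Ward's method (`ward.D2`) on Euclidean distances between matrix rows;
cells with no usable alignment are flagged and imputed with the column
minimum for clustering only.

Transmission is called from the comparison: `putative_transmission` above
99.7% identity with at least 20 kb aligned; `related` between 98% and the
cut (the unnamed 99.2–99.7% span is folded into `related`, and the
numeric identity is always reported alongside the label); `unrelated`
below 98%; `insufficient_data` under 20 kb aligned — a deliberately
conservative rule, since a 12 kb near-identical fragment is compatible
with amplification artefacts.

## The simulator and what it does (not) emulate

The generator's defaults describe the study design the analysis assumes:

* **Reference**: 97,000 bp, GC 0.35, 88 non-overlapping codon-length genes
  covering 90% of the genome, none spanning the circular origin (effect
  prediction is simpler, and nothing in the analysis depends on
  origin-spanning genes).
* **Between-host structure**: each host's population descends from a
  founder lineage 0.02 substitutions/site from the reference, so
  unrelated hosts' consensus genomes share roughly 96% identity — the
  regime in which the transmission classifier must separate signal from
  background.
* **Within-host structure**: 3 strains per carrier at 5e-4 substitutions/
  site around the founder with symmetric-Dirichlet abundances; this puts
  multiallelic densities at the fraction-of-a-percent scale the statistics
  are designed for. Both the many-close-strains and few-divergent-strains
  regimes are reachable through (`n_strains`, `divergence`).
* **Substitution spectrum**: transitions drawn with probability
  κ/(κ + 1), κ = 3, so the generative Ts/Tv ratio equals κ and pooled
  Ts/Tv recovery has a non-trivial target.
* **Coverage**: negative-binomial per site (mean 100, dispersion 5) rather
  than Poisson, to reproduce highly variable coverage; sequencing error
  0.002 per base, uniform across the three other bases.
* **Transmission**: a bottleneck samples `bottleneck_k = 1` strain without
  replacement proportional to abundance (if k reaches the strain count the
  whole population transfers). After acquisition, each timepoint's
  mutation bout splits off a sub-strain carrying new variants at 1e-4
  substitutions/site and 30% of its parent's abundance — so infants accrue
  multiallelic sites over time while maternal populations stay static —
  the same mutation-bout mechanism can model maternal drift, but the
  default keeps mothers static, matching the observation that maternal
  diversity is stable over months.
* **Read counts**: log-normal totals around 8.7 M reads; classified reads
  are coverage × L / 100. Non-carriers get exactly zero classified reads,
  so the false-positive rate of detection on simulated cohorts is zero by
  construction — the simulator does not model classifier confusion between
  related taxa.

Not emulated: read-level FASTQ artefacts (mapping bias, duplicates),
indels and structural variants, recombination between strains, and
host-bacterium dynamics. Passing tests on this simulator therefore show
that the statistics recover the parameters of *this* generative model —
sampling noise, coverage variation, sequencing error, bottlenecks — not
that they are robust to misassembly or mapping artefacts in real data.

## Numerical and scale choices

Internal coordinates are 0-based half-open everywhere; conversion happens
only at the GFF3/VCF boundary (both 1-based on disk). All randomness flows
from a single integer seed per entry point, and reruns are byte-identical.
The test suite and examples run the same code paths at reduced problem
sizes (genomes of 1–50 kb, cohorts of 2–20 families, 10–40 replicates per
Monte-Carlo check), sizes chosen so the binomial/Dirichlet moment checks
retain enough precision to detect real defects; the full 97 kb defaults
are exercised by the transmission-recovery runs. Degenerate inputs are
defined rather than erroneous wherever a convention exists: zero
transversions give an undefined-flagged Ts/Tv rather than infinity, an
empty detectability mask gives an undefined-flagged F_multi, and an
alignment with no anchors reports zero aligned length.

## Known limitations

Strain haplotypes are never phased — multiallelic sites are a diversity
proxy, and two samples with equal F_multi can have different strain
structures. The aligner has no inversion or rearrangement handling and
drops repeated anchors, so tandem duplications reduce aligned length. The
equal-probability null ignores mutational spectrum; a transition-biased
null would shift the synonymous expectation upward. The detectability
rule uses an expected-count argument, which is slightly liberal near the
threshold compared to a full binomial power calculation.
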