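# phagestrain

Strain-level analysis of prevalent gut bacteriophages (crAss-like phages)
from shotgun metagenomes, for microbiome researchers studying phage
acquisition, within-host diversity, and transmission between hosts
(mother–infant pairs, FMT donor–recipient pairs).

Metagenomic assembly collapses a phage population to its dominant allele at
every position. `phagestrain` works underneath that consensus:

* **Detection** — presence/absence per sample from classified read counts,
  using a ≥1,000-read threshold (≈1x coverage for 100 bp reads on a
  ~100 kb genome; 10,000 reads for virome-enriched sequencing), with
  relative-abundance and fold-coverage conversions.
* **Variant sites** — fixed SNPs and *multiallelic sites* (two alleles,
  each with ≥5 supporting reads, at positions covered ≥10x) called from
  per-position pileups; transition/transversion ratios.
* **Strain diversity** — the coverage-normalised statistic

  `F_multi(x) = (# multiallelic sites with minor AF > x) / (# positions with depth ≥ ceil(5/x))`

  which makes samples with wildly different coverage comparable, plus
  sites/kb densities, Wilcoxon group comparisons, longitudinal
  trajectories, and mother→infant allele-sharing at maternal multiallelic
  sites.
* **Effect annotation** — codon-level synonymous / nonsynonymous /
  nonsense / noncoding classification, an equal-probability mutation null
  model over all 3L substitutions, per-category and multinomial
  likelihood-ratio (G) tests, length-normalised per-gene nonsynonymous
  ranking, and sliding-window genome profiles (coverage, GC, GC skew,
  multiallelic counts, log2 N/S).
* **Genome comparison** — an anchor-chain aligner (unique 20-mer anchors,
  weighted colinear chaining, banded gap closing) reporting average
  identity and total 1–1 aligned length; SNP identity between variant
  sets; Ward (ward.D2) clustering of identity matrices; transmission
  classification at the >99.7% identity / ≥20 kb aligned rule.
* **Synthetic cohorts** — a first-class simulator of multi-strain phage
  populations, negative-binomial coverage pileups with sequencing error,
  bottlenecked mother→infant transmission and FMT engraftment, with
  ground-truth labels for every sample.

Everything is data-frame-first: functions take and return tibbles, results
have `tidy()` / `glance()` methods, and plotting helpers return ggplots.

## Worked example

Simulate a two-strain population on a 20 kb genome, sequence it to ~120x,
call variants, and measure diversity:

```r
library(phagestrain)

g   <- generate_genome(20000, gc = 0.35, seed = 1)
pop <- simulate_population(g, n_strains = 2, divergence = 2e-3,
                           abundance_concentration = 1, seed = 2)
pop$abundance
#> [1] 0.5023055 0.4976945

pu <- simulate_pileup(pop, coverage_mean = 120, error_rate = 0.002, seed = 3)
vs <- call_variants(pu, g)
glance(vs)
#> # A tibble: 1 × 6
#>   sample_id n_fixed n_multiallelic frac_covered mean_depth     L
#>   <chr>       <int>          <int>        <dbl>      <dbl> <int>
#> 1 sample_1        0             89        1.000       120. 20000

f_multi(vs)
#> # A tibble: 4 × 6
#>   sample_id     x numerator denominator   value undefined
#>   <chr>     <dbl>     <int>       <int>   <dbl> <lgl>
#> 1 sample_1    0.4        85       19991 0.00425 FALSE
#> 2 sample_1    0.3        89       19983 0.00445 FALSE
#> 3 sample_1    0.2        88       19884 0.00443 FALSE
#> 4 sample_1    0.1        84       18660 0.00450 FALSE
```

Both strains are at ~50% abundance and differ at ~90 positions, so ~0.45%
of detectable positions are multiallelic at every AF threshold — the
strains' divergent sites sit near minor AF 0.5, and the denominator
shrinks at x = 0.1 because detecting a 10% minor allele needs ≥50x depth.

Transmit the population through a single-strain bottleneck and test
whether the consensus ("assembled") genomes betray the event:

```r
pop2 <- simulate_population(g, n_strains = 2, divergence = 2e-3,
                            abundance_concentration = 0.3, seed = 5)
kid  <- simulate_transmission(pop2, bottleneck_k = 1, seed = 4)
cmp  <- align_pair(consensus_sequence(pop2), consensus_sequence(kid))
classify_transmission(cmp, length_cut = 15000)
#> # A tibble: 1 × 5
#>   identity aligned_length n_segments orientation label
#>      <dbl>          <int>      <int> <chr>       <chr>
#> 1      100          20000          1 forward     putative_transmission
```

The dominant strain founded the recipient population, so the two consensus
genomes align end-to-end at 100% identity — a putative transmission under
the >99.7% / ≥20 kb rule (the length cut is scaled to this 20 kb toy
genome). `run_pipeline()` chains all stages on a simulated cohort and
writes one TSV per stage plus a JSON manifest; see the methods vignette
(`vignettes/phage-strain-methods.Rmd`) for the models, parameter defaults
and design decisions.

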