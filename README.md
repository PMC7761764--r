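# rrnalink

Classification of bacterial genomes by rRNA operon linkage.

In most bacteria the 16S, 23S and 5S rRNA genes sit in one co-transcribed
operon, separated by a short internal transcribed spacer (ITS). In a
sizeable minority — dominated by obligate symbionts with reduced,
AT-rich genomes — the 16S and 23S genes have drifted apart or become
*unlinked*. `rrnalink` implements the genome-scale analysis of this
phenomenon for anyone working with complete bacterial assemblies:
microbial genomicists surveying RefSeq-style cohorts, and researchers
studying symbiont genome reduction.

## What it computes

Given a genome (FASTA) and its annotation (GFF3 with rRNA features), the
package:

1. **Screens** the annotation by in silico PCR: 16S amplicons from
   27F (`AGRGTTYGATYHTGGCTCAG`) / 1492R (`TACCTTGTTAYGACTT`) with product
   length in (1000, 4000) bp, 23S amplicons from 11a
   (`GGAACTGAAACATCTAAGTA`) / 2241r (`ACCRCCCCAGTHAAACT`) in (1000, 6800)
   bp. Each primer tolerates up to 2 mismatches; discordant genomes are
   retried at 4, and genomes still discordant in the per-type copy
   numbers (n16S, n23S) are excluded.
2. **Pairs** the surviving features into operon units. With features
   ordered by start coordinate, a sense 16S followed by a sense 23S (or
   an antisense 23S followed by an antisense 16S) forms a unit; on a
   circular chromosome the last and first features may pair across the
   origin. The ITS of a unit is the gap between the gene bodies,

       ITS = start(downstream) − end(upstream) − 1                (no wrap)
       ITS = (L − end(upstream)) + (start(downstream) − 1)        (wrapped)

   for a chromosome of length L. A unit with ITS ≤ 1500 bp is *linked*,
   over 1500 bp *unlinked*; leftover lone 16S or 23S genes are *singles*
   and count as unlinked evidence.
3. **Calls** each genome `linked` (only linked units), `unlinked` (no
   linked unit), `mixed` (both kinds of evidence), or `undetermined`.
4. **Compares** genome classes: a per-genome feature table (genome size,
   AT contents, 16S copy number, mean rRNA gene lengths, symbiont
   label), PCA, Kruskal–Wallis with Dunn's post hoc test, Welch *t*,
   ANOVA + Tukey HSD, paired *t* on functional category counts, and
   phylogenetic GLS with Brownian covariance (V_ij = shared
   root-to-ancestor path length) for tree-corrected contrasts.

A synthetic genome generator (`simulate_genome()`, `simulate_cohort()`)
produces FASTA/GFF3 cohorts with a ground-truth manifest covering every
configuration — linked, unlinked, antisense, origin-spanning, singles,
planted primer-site mutations, partial and erroneous annotations — so
the entire pipeline is testable without downloads.

## Worked example

The canonical trap for naive ITS arithmetic is an operon spanning the
origin of a circular chromosome: a plus-strand 16S ending at 3,503,539
and a plus-strand 23S starting at 437 on a 3,504,252 bp chromosome are
more than 3 Mb apart in linear coordinates, yet form one linked operon:

```r
library(rrnalink)
units <- pair_operons(
  data.frame(chrom_id = "chr1", rna_type = c("23S", "16S"), strand = "+",
             start = c(437L, 3501990L), end = c(3336L, 3503539L),
             partial = FALSE, source = "annotation"),
  c(chr1 = "circular"), c(chr1 = 3504252L))
units[, c("kind", "its_length", "wrapped", "linkage")]
#>   kind its_length wrapped linkage
#> 1 pair       1149    TRUE  linked
```

Going around the origin the spacer is (3,504,252 − 3,503,539) +
(437 − 1) = 1149 bp ≤ 1500, so the unit is linked.

End to end on a synthetic cohort:

```r
dir <- file.path(tempdir(), "cohort")
simulate_cohort(c(linked = 3, mixed = 3, unlinked = 3), seed = 7, dir = dir)
res <- run_pipeline(dir, file.path(tempdir(), "reports"))
res$calls[, c("genome_id", "status", "n_linked", "n_unlinked", "n_singles")]
#>          genome_id   status n_linked n_unlinked n_singles
#> 1   SYN_linked_001   linked        2          0         0
#> 2   SYN_linked_002   linked        2          0         0
#> 3   SYN_linked_003   linked        2          0         0
#> 4    SYN_mixed_001    mixed        1          1         0
#> 5    SYN_mixed_002    mixed        1          0         1
#> 6    SYN_mixed_003    mixed        1          1         0
#> 7 SYN_unlinked_001 unlinked        0          1         0
#> 8 SYN_unlinked_002 unlinked        0          0         2
#> 9 SYN_unlinked_003 unlinked        0          1         0
```

All nine genomes pass screening at 2 mismatches and every call matches
the generator's manifest. The feature table shows the planted symbiont
contrast — unlinked genomes smaller and more AT-rich:

```r
aggregate(cbind(genome_size, genome_at) ~ status, res$features,
          function(x) round(mean(x), 3))
#>     status genome_size genome_at
#> 1   linked    41784.67     0.527
#> 2    mixed    42001.33     0.501
#> 3 unlinked    17162.00     0.645
```

`run_pipeline()` writes `screening.tsv`, `units.tsv`,
`genome_calls.tsv`, `features.tsv`, `stats/feature_tests.tsv` and a run
log echoing every effective parameter.

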