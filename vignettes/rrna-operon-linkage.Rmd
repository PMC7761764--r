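---
title: "Classifying bacterial rRNA operon linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bacterial rRNA operon linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnalink)
```

## The question and the method

Bacterial 16S and 23S rRNA genes are usually co-transcribed from one
operon with a short internal transcribed spacer (ITS) between them.
Genomes in which the two genes are far apart, on opposite strands, or on
different replicons carry *unlinked* rRNA operons — a configuration
concentrated in host-associated bacteria with reduced genomes.
`rrnalink` classifies complete genomes by this criterion and provides
the statistics used to contrast the resulting classes.

The procedure has four stages.

**Annotation collection.** rRNA features of type `rRNA` whose product
attribute names 16S or 23S are read from GFF3 with 1-based inclusive
coordinates; 5S genes are ignored throughout. Features flagged
`partial=true`, or whose Note marks the prediction as too short, are
removed before any downstream step: an incomplete gene model cannot be
trusted for pairing, and its presence is itself a sign of assembly
trouble. Chromosome topology comes from `region` lines
(`Is_circular=true`); replicons without topology information default to
circular — the overwhelmingly common case for complete bacterial
chromosomes — and the default is logged and overridable.

**Screening by in silico PCR.** Annotated copy numbers are
cross-validated against amplicons predicted from the sequence with the
universal primer pairs 27F/1492R (16S; product strictly between 1000
and 4000 bp) and 11a/2241r (23S; 1000–6800 bp). Primer matching is
IUPAC-aware set membership with an *absolute* mismatch budget per
primer; a genome base outside A/C/G/T always counts as a mismatch.
Amplicons on the same chromosome with ≥ 50% reciprocal overlap are
merged into loci, collapsing duplicate hits from nearby degenerate
sites. Screening compares (n16S, n23S) component-wise — equal totals
with swapped per-type counts are still discordant — first at 2
mismatches, then at 4; genomes that never agree are excluded from all
later stages but kept in the screening report. The search runs on the
linearized sequence, so a genome whose only rRNA crosses the origin
would fail concordance; this mirrors the behaviour of linear-text
primer-search tools and is a documented limitation.

**Operon pairing.** Within each replicon, features are ordered by
(start, end, type) — the two tiebreakers make ordering deterministic —
and scanned once left to right. A sense 16S pairs with the
*immediately* following feature when that feature is a sense 23S; an
antisense 23S pairs with an immediately following antisense 16S. Any
intervening rRNA of the wrong type or strand breaks the pair: allowing
skips would create ambiguous many-to-many pairings, while the single
ordered pass keeps every feature in exactly one unit. On circular
replicons, if the last and first features are both unpaired and would
form a valid pair across the origin, they are paired with the wrapped
spacer

$$\mathrm{ITS} = (L - \mathrm{end}_{up}) + (\mathrm{start}_{down} - 1).$$

This wrap rule is what rescues genuine operons that happen to straddle
the assembly origin: a 16S ending 713 bp before the end of a
3,504,252 bp chromosome and a 23S starting at position 437 yield
ITS = 713 + 436 = 1149 bp, a linked operon, despite a 3 Mb linear
separation. Pairing never crosses replicons.

**Classification.** A pair with ITS ≤ 1500 bp is linked; strictly over
1500 bp, unlinked (so exactly 1500 is linked). Unpaired singles count as
unlinked evidence: a lone 16S or 23S implies its partner sits on the
other strand, another replicon, or far away — the canonical unlinked
situation — so counting singles as linked or neutral would misclassify
exactly the genomes the analysis is about. The policy is echoed in all
outputs (`singles_policy=unlinked`). A genome is then `linked` when all
its units are linked pairs, `unlinked` when it has no linked pair,
`mixed` otherwise, and `undetermined` when it has no 16S/23S at all.
With this accounting, genomes across the classes plus undetermined plus
excluded always sum to the input count.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `its_threshold` | 1500 bp | linked/unlinked ITS boundary (strictly-over rule) |
| `mismatch_budgets` | 2, then 4 | absolute per-primer mismatch escalation in screening |
| 16S product window | (1000, 4000) bp | exclusive bounds on 27F/1492R products |
| 23S product window | (1000, 6800) bp | exclusive bounds on 11a/2241r products |
| locus merge | 50% reciprocal overlap | dedup rule for amplicons of one target |
| topology default | circular | used when the GFF records no topology |

All of these live in `pipeline_config()` and are echoed in the run log.
The mismatch budget is applied to each primer independently; whether it
should instead be summed over the pair is ambiguous in the field's
usage, and the per-primer reading is the stricter and simpler one.

## The synthetic data generator

`simulate_genome()` realizes a scenario — chromosomes with lengths and
topologies, operon layouts (`linked_pair`, `unlinked_pair`,
`antisense_pair`, `wraparound_pair`, `single_16S`, `single_23S`),
planted primer-site substitutions, partial-annotation flags and
annotation errors — as FASTA plus GFF3 plus a manifest of expected
features, units, genome call and screening verdict. Design choices that
matter:

* **Templates carry exact primer sites.** The 16S template (1550 bp)
  starts with a realization of 27F and ends with the reverse complement
  of a 1492R realization; the 23S template (2900 bp) analogously. Both
  lengths sit inside their product windows by construction, so every
  planted gene amplifies exactly once at zero mismatches.
* **Planted mismatches are exact.** A substitution is always drawn from
  outside the degenerate code's allowed set, so a site planted with
  *k* substitutions scores exactly *k* mismatches: 1–2 pass at budget
  2, 3–4 only at budget 4, more are never found.
* **Background scrubbing.** Short reverse primers (16–17 bp) match
  random background within 4 mismatches often enough to create spurious
  in-window products and flip screening verdicts. After assembly the
  generator therefore re-randomizes any background window within 5
  mismatches of a primer (a margin above the largest screening budget),
  leaving planted sites untouched. Screening outcomes are thereby
  determined by the scenario, not by background luck.
* **Partial flags break concordance by design.** A partial-flagged
  feature is dropped at collection while its gene body remains
  amplifiable, so such genomes are expected to be excluded — the
  conservative behaviour one wants for suspect annotations.
* **Interior sequence is uniform pseudo-random** at a configurable AT
  fraction. No rRNA secondary structure, tRNAs in the spacer, promoter
  context or real intergenic composition is modelled.

`simulate_cohort()` stacks scenario variants so a cohort covers all six
layout types, and draws class-conditional genome properties: background
AT fractions of 0.514 / 0.501 / 0.649 for linked / mixed / unlinked
(matching the direction and rough magnitude of the real symbiont
contrast) and padding that makes unlinked genomes several-fold smaller
than linked ones. Unlinked genomes are labelled symbionts in
`labels.tsv`. Genome sizes are tens of kilobases rather than megabases:
operon geometry, screening and classification are length-scale
invariant, so the reduced scale changes nothing about what the tests
exercise while keeping cohort generation fast. What passing on
synthetic cohorts does *not* show: robustness to real annotation noise,
repeat-driven misassembly, or primer-site divergence beyond the planted
substitution model.

## Statistical procedures

Group comparisons of genomic features use the Kruskal–Wallis rank sum
test (tie-corrected) followed by Dunn's pairwise z-tests. No standard
post hoc adjustment is canonical here; Holm's method is used because it
is uniformly valid without independence assumptions, and the method
name is written into every output. Two-group contrasts use Welch's
*t* with Satterthwaite degrees of freedom; multi-group mean contrasts
use one-way ANOVA with Tukey's HSD. Functional category counts are
compared by paired *t*-tests on per-phylum mean counts, pairing linked
and unlinked means within a phylum so that deep taxonomic composition
cancels.

The phylogenetic regression is GLS with the Brownian-motion covariance
$V_{ij}$ = shared root-to-MRCA path length (computed from the tree with
`ape::vcv`), fitting intercept plus one predictor (e.g. linkage coded
0/1):

$$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y,$$

with residual variance on $n-2$ degrees of freedom and a two-sided
*t*-test on the slope. On a star tree this reduces exactly to OLS, and
rescaling all branch lengths leaves the slope and *t* unchanged; both
properties are tested. No Pagel's λ or OU extensions are fitted — the
plain Brownian model is the stated scope.

## Numerical and degenerate-input choices

* Overlapping annotated genes on a linear replicon give a negative gap;
  ITS is clamped to 0 with a warning. On circular replicons a
  downstream start at or before the upstream end is read as wraparound,
  per the spacer definition above. Annotated features that themselves
  span the origin (end < start in the GFF) are rejected with an error
  rather than guessed at.
* `anova_tukey` on all-equal values reports F = 0, p = 1 instead of
  erroring; `paired_t_by_category` returns t = 0, p = 1 for identical
  pairs and NA (with a warning) for constant nonzero differences.
* PCA standardizes columns and drops constant ones with a warning;
  loadings are orthonormal and explained variance non-increasing.
* A singular Brownian covariance (duplicated zero-length tips) is an
  error naming the cause, as is any tree/data taxa mismatch.
* All pipeline outputs are TSV with fixed column order, so reruns on
  identical input are byte-identical.

## Problem sizes used in the test suite

The suite validates the classifier's invariants (feature conservation,
rotation of the circular origin, strand reversal) on randomly generated
feature sets; primer matching against a brute-force IUPAC scan on 100
random chromosomes of 0.3–1.2 kb; cohort round trips on 30 genomes (10
per class, all six layout types); and PGLS slope recovery over 200
Brownian simulations on a 20-tip tree, requiring the planted slope
inside ±3 SE in at least 95% of replicates. These sizes were chosen as
the smallest at which each property is non-trivially exercised.

## Known limitations

* No origin-spanning amplicons in screening, and no origin-spanning
  annotated features (see above).
* The screening step validates copy numbers, not sequence identity; a
  mis-typed annotation (16S labelled 23S) at matching counts would pass.
* 5S rRNA is ignored entirely; operon units are 16S–23S only.
* The generator does not simulate reads, assemblies, or realistic rRNA
  sequence families; concordance failures are modelled only through the
  explicit scenario switches.
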