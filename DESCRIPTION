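Package: rrnalink
Title: Linkage Classification of Bacterial rRNA Operons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial genomes by the linkage status of their rRNA
    operons. Reads genome sequences (FASTA) and annotations (GFF3), pairs
    16S and 23S rRNA genes into operon units with strand- and
    circularity-aware internal transcribed spacer (ITS) computation,
    cross-validates annotated rRNA copy numbers against in silico PCR with
    degenerate universal primers, and labels each genome linked, mixed or
    unlinked. Includes the comparative statistics used to contrast genome
    classes (PCA, Kruskal-Wallis with Dunn post hoc, Welch t, ANOVA with
    Tukey HSD, paired t on functional category counts, and phylogenetic
    generalized least squares under Brownian motion), plus a synthetic
    genome generator that produces FASTA/GFF3 cohorts with ground-truth
    manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
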