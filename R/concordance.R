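# Cross-validation of annotated rRNA copy numbers against in silico PCR.
#
# A genome passes when annotation and PCR agree on the (16S, 23S) count
# pair, compared component-wise (equal totals with swapped per-type
# counts are still discordant). Screening first allows 2 mismatches per
# primer; discordant genomes are retried at 4; genomes still discordant
# are excluded from all downstream analysis.

#' Per-type rRNA counts of a genome's features
#'
#' @param features rRNA feature data.frame (one genome, partial features
#'   already removed).
#' @return Named integer vector `c(n16S = ..., n23S = ...)`.
#' @export
profile_counts <- function(features) {
  c(n16S = sum(features$rna_type == "16S"),
    n23S = sum(features$rna_type == "23S"))
}

#' Screen one genome: annotation counts vs in silico PCR counts
#'
#' Runs amplicon prediction and locus counting at each mismatch budget in
#' turn (default 2 then 4) and stops at the first budget whose per-type
#' locus counts equal the annotation counts component-wise. A genome that
#' matches no budget is excluded.
#'
#' @param chromosomes Named list of chromosome records.
#' @param annotation_counts Named vector `c(n16S=, n23S=)`, e.g. from
#'   [profile_counts()].
#' @param pairs Primer pairs, default [default_primer_pairs()].
#' @param budgets Strictly increasing integer mismatch budgets.
#' @param genome_id Genome identifier echoed in the result.
#' @return One-row data.frame: `genome_id`, `n16S_annot`, `n23S_annot`,
#'   per-budget PCR counts (`n16S_mm2`, ..., NA for budgets not reached),
#'   and `verdict` ("pass_mm2", "pass_mm4", ..., or "excluded").
#' @export
screen_genome <- function(chromosomes, annotation_counts,
                          pairs = default_primer_pairs(),
                          budgets = c(2L, 4L), genome_id = "genome") {
  stopifnot(length(budgets) >= 1L, !is.unsorted(budgets, strictly = TRUE))
  ann <- c(n16S = unname(annotation_counts[["n16S"]]),
           n23S = unname(annotation_counts[["n23S"]]))
  row <- data.frame(genome_id = genome_id,
                    n16S_annot = ann[["n16S"]], n23S_annot = ann[["n23S"]],
                    stringsAsFactors = FALSE)
  verdict <- "excluded"
  for (b in budgets) {
    counts <- c(n16S = 0L, n23S = 0L)
    for (tgt in c("16S", "23S")) {
      amps <- lapply(chromosomes, predict_amplicons, pair = pairs[[tgt]],
                     max_mm = b)
      amps <- do.call(rbind, amps)
      counts[[paste0("n", tgt)]] <- count_rrna_loci(amps)
    }
    row[[paste0("n16S_mm", b)]] <- counts[["n16S"]]
    row[[paste0("n23S_mm", b)]] <- counts[["n23S"]]
    if (counts[["n16S"]] == ann[["n16S"]] &&
        counts[["n23S"]] == ann[["n23S"]]) {
      verdict <- paste0("pass_mm", b)
      break
    }
  }
  for (b in budgets) {  # budgets never reached -> NA columns
    for (col in paste0(c("n16S_mm", "n23S_mm"), b)) {
      if (is.null(row[[col]])) row[[col]] <- NA_integer_
    }
  }
  row$verdict <- verdict
  row
}

#' Screen a cohort of genomes
#'
#' @param cohort Named list of genomes, each a list with elements
#'   `chromosomes` and `features` (as returned by [load_genome()]).
#' @param pairs,budgets Passed to [screen_genome()].
#' @return data.frame with one row per genome (the screening report).
#' @export
screen_cohort <- function(cohort, pairs = default_primer_pairs(),
                          budgets = c(2L, 4L)) {
  rows <- lapply(names(cohort), function(gid) {
    g <- cohort[[gid]]
    screen_genome(g$chromosomes, profile_counts(g$features),
                  pairs = pairs, budgets = budgets, genome_id = gid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
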