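# Per-genome genomic feature table: size, AT contents, rRNA copy numbers
# and mean gene lengths, joined with symbiont labels.

#' AT content of a nucleotide sequence
#'
#' (A + T) / total length, case-insensitive. Ambiguity codes contribute to
#' the denominator only: they are evidence of sequence, not of A/T.
#'
#' @param sequence Non-empty nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
at_content <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("at_content requires a non-empty character scalar")
  }
  b <- charToRaw(toupper(sequence))
  sum(b == charToRaw("A") | b == charToRaw("T")) / length(b)
}

# Extract a feature's sequence from its chromosome (reverse-complemented
# for antisense features). Features are stored unwrapped, so a plain
# substring suffices.
.feature_seq <- function(chrom, start, end, strand) {
  s <- substr(chrom$sequence, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Build the per-genome genomic feature table
#'
#' One row per screened genome: total genome size (sum over all replicons
#' in the assembly), whole-genome AT content, mean AT content of the 16S
#' genes (extracted from the genome, antisense features
#' reverse-complemented), 16S copy number, mean 16S/23S gene lengths
#' (end - start + 1), linkage status and symbiont label.
#'
#' @param cohort Named list of genomes (elements `chromosomes`,
#'   `features`).
#' @param calls data.frame of genome calls (from [classify_genome()] rows)
#'   with columns `genome_id` and `status`.
#' @param symbiont_labels Optional data.frame with columns `genome_id` and
#'   `symbiont` ("yes"/"no"); genomes absent from it get "unknown".
#' @return data.frame with columns `genome_id`, `genome_size`,
#'   `genome_at`, `mean_16S_at`, `n16S`, `mean_16S_len`, `mean_23S_len`,
#'   `status`, `symbiont`.
#' @export
build_feature_table <- function(cohort, calls, symbiont_labels = NULL) {
  ids <- names(cohort)
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(ids, function(gid) {
    g <- cohort[[gid]]
    chroms <- g$chromosomes
    feats <- g$features
    genome_size <- sum(vapply(chroms, `[[`, numeric(1), "length"))
    whole <- paste(vapply(chroms, `[[`, character(1), "sequence"),
                   collapse = "")
    f16 <- feats[feats$rna_type == "16S", , drop = FALSE]
    f23 <- feats[feats$rna_type == "23S", , drop = FALSE]
    at16 <- if (nrow(f16)) {
      mean(vapply(seq_len(nrow(f16)), function(i) {
        at_content(.feature_seq(chroms[[f16$chrom_id[i]]], f16$start[i],
                                f16$end[i], f16$strand[i]))
      }, numeric(1)))
    } else NA_real_
    status <- calls$status[match(gid, calls$genome_id)]
    symb <- "unknown"
    if (!is.null(symbiont_labels)) {
      m <- match(gid, symbiont_labels$genome_id)
      if (!is.na(m)) symb <- as.character(symbiont_labels$symbiont[m])
    }
    data.frame(genome_id = gid, genome_size = genome_size,
               genome_at = at_content(whole), mean_16S_at = at16,
               n16S = nrow(f16),
               mean_16S_len = if (nrow(f16)) {
                 mean(f16$end - f16$start + 1)
               } else NA_real_,
               mean_23S_len = if (nrow(f23)) {
                 mean(f23$end - f23$start + 1)
               } else NA_real_,
               status = if (is.na(status)) "undetermined" else status,
               symbiont = symb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
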