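# IUPAC nucleotide ambiguity codes and the concrete bases each one admits.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# 256 x 256 lookup: .IUPAC_ALLOW[primer_byte + 1, genome_byte + 1] is TRUE
# when the genome base belongs to the primer code's set. Genome characters
# outside {A,C,G,T} never match (they count as mismatches by definition).
.IUPAC_ALLOW <- local({
  m <- matrix(FALSE, 256L, 256L)
  for (code in names(.IUPAC_SETS)) {
    p <- utf8ToInt(code) + 1L
    for (b in .IUPAC_SETS[[code]]) m[p, utf8ToInt(b) + 1L] <- TRUE
  }
  m
})

.valid_iupac <- function(chars) all(chars %in% names(.IUPAC_SETS))

#' Count mismatches between a degenerate primer and a genome window
#'
#' A position matches when the genome base belongs to the set of bases the
#' primer's IUPAC code admits (e.g. `R` admits A or G). Genome characters
#' outside A/C/G/T (such as N) always count as mismatches: an ambiguous
#' genome base is not experimental evidence of a primer binding site.
#'
#' @param primer_window Primer sequence (IUPAC codes allowed), 5'-3'.
#' @param genome_window Genome sequence of the same length, upper case.
#' @return Integer mismatch count.
#' @examples
#' iupac_mismatches("R", "A")      # 0: R = A or G
#' iupac_mismatches("ACGT", "ACGN") # 1: N in the genome is a mismatch
#' @export
iupac_mismatches <- function(primer_window, genome_window) {
  pb <- charToRaw(toupper(primer_window))
  gb <- charToRaw(toupper(genome_window))
  if (length(pb) != length(gb)) {
    stop("primer and genome windows differ in length (",
         length(pb), " vs ", length(gb), ")")
  }
  pc <- strsplit(toupper(primer_window), "", fixed = TRUE)[[1]]
  if (!.valid_iupac(pc)) {
    stop("primer contains non-IUPAC characters: ",
         paste(unique(pc[!pc %in% names(.IUPAC_SETS)]), collapse = ", "))
  }
  sum(!.IUPAC_ALLOW[cbind(as.integer(pb) + 1L, as.integer(gb) + 1L)])
}

#' Reverse complement of a (possibly degenerate) nucleotide sequence
#'
#' Degenerate codes map onto their complementary sets (R<->Y, K<->M, B<->V,
#' D<->H; S, W and N are self-complementary).
#'
#' @param x Character scalar nucleotide sequence.
#' @return Reverse-complemented sequence, upper case.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Random DNA of length n at a given AT fraction; uses the current RNG stream.
random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}
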