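# In silico PCR: locate degenerate primer binding sites allowing a fixed
# number of absolute mismatches per primer, pair sites into products, and
# filter products by length windows. The search is on the linearized
# stored sequence; products spanning the origin of a circular chromosome
# are not predicted (documented limitation, mirroring linear-text primer
# search tools).

#' Construct a primer pair with its product-length window
#'
#' Length bounds are strict: a product survives only when
#' `min_product_len < length < max_product_len`.
#'
#' @param target "16S" or "23S".
#' @param forward,reverse Primer sequences, 5'-3', IUPAC codes allowed.
#' @param min_product_len,max_product_len Exclusive product-length bounds (bp).
#' @param forward_name,reverse_name Optional primer names.
#' @return List of class `primer_pair`.
#' @export
primer_pair <- function(target, forward, reverse,
                        min_product_len, max_product_len,
                        forward_name = "fwd", reverse_name = "rev") {
  stopifnot(target %in% c("16S", "23S"),
            min_product_len < max_product_len)
  for (p in c(forward, reverse)) {
    pc <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
    if (length(pc) == 0L || !.valid_iupac(pc)) {
      stop("invalid primer sequence: ", p)
    }
  }
  structure(list(target = target,
                 forward = toupper(forward), reverse = toupper(reverse),
                 forward_name = forward_name, reverse_name = reverse_name,
                 min_product_len = min_product_len,
                 max_product_len = max_product_len),
            class = "primer_pair")
}

#' Default universal rRNA primer pairs
#'
#' 16S: 27F `AGRGTTYGATYHTGGCTCAG` / 1492R `TACCTTGTTAYGACTT`, product
#' window 1000-4000 bp (exclusive). 23S: 11a `GGAACTGAAACATCTAAGTA` /
#' 2241r `ACCRCCCCAGTHAAACT`, window 1000-6800 bp (exclusive).
#'
#' @return Named list of two `primer_pair` objects (`"16S"`, `"23S"`).
#' @export
default_primer_pairs <- function() {
  list(
    "16S" = primer_pair("16S", "AGRGTTYGATYHTGGCTCAG", "TACCTTGTTAYGACTT",
                        1000L, 4000L, "27F", "1492R"),
    "23S" = primer_pair("23S", "GGAACTGAAACATCTAAGTA", "ACCRCCCCAGTHAAACT",
                        1000L, 6800L, "11a", "2241r")
  )
}

.seq_of <- function(chrom) {
  if (is.character(chrom)) toupper(chrom) else toupper(chrom$sequence)
}

# Mismatch counts of a primer against every window of a byte vector.
# Returns an integer vector of length L - k + 1 (empty when k > L).
.window_mismatches <- function(seq_bytes, primer_chars) {
  L <- length(seq_bytes)
  k <- length(primer_chars)
  if (k > L) return(integer(0))
  n <- L - k + 1L
  mm <- integer(n)
  idx <- as.integer(seq_bytes) + 1L
  for (j in seq_len(k)) {
    allowed <- .IUPAC_ALLOW[utf8ToInt(primer_chars[j]) + 1L, ]
    mm <- mm + as.integer(!allowed[idx[j:(j + n - 1L)]])
  }
  mm
}

#' Find binding sites of a degenerate primer on a chromosome
#'
#' Scans both the stored strand (orientation "forward") and the primer's
#' reverse complement (orientation "reverse"), reporting every window with
#' at most `max_mm` mismatches. Positions are 1-based at the window's left
#' end on the stored sequence.
#'
#' @param chrom Chromosome record or plain character sequence.
#' @param primer Primer sequence (IUPAC codes allowed).
#' @param max_mm Maximum number of mismatches (absolute count, >= 0).
#' @return data.frame with columns `position`, `orientation`
#'   ("forward"/"reverse") and `mismatches`.
#' @export
find_primer_sites <- function(chrom, primer, max_mm) {
  stopifnot(max_mm >= 0)
  s <- .seq_of(chrom)
  bytes <- charToRaw(s)
  out <- list()
  for (ori in c("forward", "reverse")) {
    pseq <- if (ori == "forward") toupper(primer) else revcomp(primer)
    pc <- strsplit(pseq, "", fixed = TRUE)[[1]]
    if (!.valid_iupac(pc)) stop("invalid primer sequence: ", primer)
    mm <- .window_mismatches(bytes, pc)
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      out[[ori]] <- data.frame(position = hit, orientation = ori,
                               mismatches = mm[hit],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), orientation = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_amplicons <- function() {
  data.frame(chrom_id = character(), target = character(),
             start = integer(), end = integer(), strand = character(),
             length = integer(), fwd_mm = integer(), rev_mm = integer(),
             stringsAsFactors = FALSE)
}

#' Predict PCR products of a primer pair on one chromosome
#'
#' A plus-strand product runs from a forward-orientation forward-primer
#' site to a downstream reverse-orientation reverse-primer site; a
#' minus-strand product symmetrically from a forward-orientation
#' reverse-primer site to a downstream reverse-orientation forward-primer
#' site. Product length includes both primer sites and must fall strictly
#' inside the pair's window. The search is linear: no product spans the
#' origin of a circular chromosome.
#'
#' @param chrom Chromosome record (or character sequence; `chrom_id` then
#'   reported as "seq").
#' @param pair A [primer_pair()].
#' @param max_mm Mismatch budget applied to each primer independently.
#' @return data.frame of amplicons (`chrom_id`, `target`, `start`, `end`,
#'   `strand`, `length`, `fwd_mm`, `rev_mm`).
#' @export
predict_amplicons <- function(chrom, pair, max_mm) {
  stopifnot(inherits(pair, "primer_pair"))
  id <- if (is.character(chrom)) "seq" else chrom$id
  f_sites <- find_primer_sites(chrom, pair$forward, max_mm)
  r_sites <- find_primer_sites(chrom, pair$reverse, max_mm)
  lf <- nchar(pair$forward)
  lr <- nchar(pair$reverse)

  emit <- function(left, left_len, left_mm, right, right_len, right_mm,
                   strand, left_is_fwd) {
    rows <- list()
    for (i in seq_len(nrow(left))) {
      p1 <- left$position[i]
      ends <- right$position + right_len - 1L
      len <- ends - p1 + 1L
      ok <- right$position >= p1 + left_len &
        len > pair$min_product_len & len < pair$max_product_len
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_id = id, target = pair$target,
        start = p1, end = ends[ok], strand = strand, length = len[ok],
        fwd_mm = if (left_is_fwd) left$mismatches[i] else right$mismatches[ok],
        rev_mm = if (left_is_fwd) right$mismatches[ok] else left$mismatches[i],
        stringsAsFactors = FALSE)
    }
    rows
  }

  plus <- emit(f_sites[f_sites$orientation == "forward", , drop = FALSE], lf,
               NULL,
               r_sites[r_sites$orientation == "reverse", , drop = FALSE], lr,
               NULL, "+", TRUE)
  minus <- emit(r_sites[r_sites$orientation == "forward", , drop = FALSE], lr,
                NULL,
                f_sites[f_sites$orientation == "reverse", , drop = FALSE], lf,
                NULL, "-", FALSE)
  rows <- c(plus, minus)
  if (!length(rows)) return(.empty_amplicons())
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count distinct rRNA loci among predicted amplicons
#'
#' Amplicons on the same chromosome whose intervals reciprocally overlap by
#' at least 50% are merged (transitively) into one locus; the count of
#' merged loci approximates the number of distinct rRNA genes a primer
#' pair amplifies, collapsing duplicate hits from degenerate primer sites.
#'
#' @param amplicons data.frame from [predict_amplicons()], one target type.
#' @return Integer locus count.
#' @export
count_rrna_loci <- function(amplicons) {
  if (is.null(amplicons) || nrow(amplicons) == 0L) return(0L)
  if (length(unique(amplicons$target)) > 1L) {
    stop("count_rrna_loci expects amplicons of a single target type")
  }
  total <- 0L
  for (cid in unique(amplicons$chrom_id)) {
    a <- amplicons[amplicons$chrom_id == cid, , drop = FALSE]
    n <- nrow(a)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ov <- min(a$end[i], a$end[j]) - max(a$start[i], a$start[j]) + 1L
        if (ov <= 0L) next
        if (ov >= 0.5 * a$length[i] && ov >= 0.5 * a$length[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    total <- total + length(unique(vapply(seq_len(n), find, integer(1))))
  }
  total
}
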