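# Pairing 16S/23S rRNA genes into operon units and classifying genomes.
#
# Transcription direction decides the pairing pattern: reading the stored
# strand left to right, a sense operon appears as 16S(+) then 23S(+), an
# antisense operon as 23S(-) then 16S(-). The ITS is the gap between the
# two gene bodies (exclusive of both), computed with circular wraparound
# when the pair spans the origin.

#' Order rRNA features by start site within each chromosome
#'
#' Sorted ascending by (start, end, rna_type); the two tiebreakers make
#' the ordering deterministic when features share a start coordinate.
#'
#' @param features rRNA feature data.frame (see [read_rrna_features()]).
#' @return The same data.frame, sorted within chromosome; chromosome
#'   blocks keep their order of first appearance.
#' @export
order_features <- function(features) {
  if (nrow(features) == 0L) return(features)
  chrom_rank <- match(features$chrom_id, unique(features$chrom_id))
  o <- order(chrom_rank, features$start, features$end, features$rna_type)
  out <- features[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Internal transcribed spacer length between two rRNA genes
#'
#' The gap between the upstream gene's end and the downstream gene's
#' start, exclusive of both gene bodies. On a circular chromosome a
#' downstream start at or before the upstream end means the pair spans the
#' origin, and the spacer wraps: `(chrom_length - upstream_end) +
#' (downstream_start - 1)`.
#'
#' @param upstream_end End coordinate (1-based inclusive) of the upstream
#'   gene.
#' @param downstream_start Start coordinate of the downstream gene.
#' @param topology "circular" or "linear".
#' @param chrom_length Chromosome length in bp.
#' @return ITS length in bp. Overlapping annotations on a linear
#'   chromosome (negative gap) are clamped to 0 with a warning.
#' @examples
#' its_length(3503539, 437, "circular", 3504252)  # 1149
#' @export
its_length <- function(upstream_end, downstream_start, topology,
                       chrom_length) {
  stopifnot(topology %in% c("circular", "linear"),
            upstream_end >= 1, upstream_end <= chrom_length,
            downstream_start >= 1, downstream_start <= chrom_length)
  if (downstream_start > upstream_end) {
    return(as.integer(downstream_start - upstream_end - 1))
  }
  if (topology == "linear") {
    warning("overlapping features on a linear chromosome; ITS clamped to 0")
    return(0L)
  }
  as.integer((chrom_length - upstream_end) + (downstream_start - 1))
}

.pairable <- function(f, i, j) {
  (f$rna_type[i] == "16S" && f$strand[i] == "+" &&
     f$rna_type[j] == "23S" && f$strand[j] == "+") ||
    (f$rna_type[i] == "23S" && f$strand[i] == "-" &&
       f$rna_type[j] == "16S" && f$strand[j] == "-")
}

.empty_units <- function() {
  data.frame(chrom_id = character(), kind = character(),
             ssu_start = integer(), ssu_end = integer(),
             lsu_start = integer(), lsu_end = integer(),
             strand = character(), its_length = integer(),
             wrapped = logical(), linkage = character(),
             stringsAsFactors = FALSE)
}

#' Pair ordered rRNA features into operon units
#'
#' Single left-to-right scan over each chromosome's start-ordered
#' features: a sense 16S pairs with an immediately following sense 23S,
#' an antisense 23S with an immediately following antisense 16S. Any
#' intervening feature of the wrong type or strand breaks the pair.
#' On a circular chromosome, if the last and first features are both
#' unpaired after the scan and form a valid pair across the origin, they
#' are paired with `wrapped = TRUE`. All remaining features become
#' singles. Pairing never crosses replicons.
#'
#' @param features rRNA feature data.frame (one genome; partial features
#'   already removed). Sorted internally with [order_features()].
#' @param topologies Named character vector chrom_id -> topology.
#' @param chrom_lengths Named integer vector chrom_id -> length (bp).
#' @param its_threshold Linked/unlinked boundary in bp (default 1500);
#'   a pair with ITS strictly over the threshold is unlinked.
#' @return data.frame of operon units: `chrom_id`, `kind`
#'   ("pair"/"single"), 16S and 23S coordinates (NA for the absent
#'   partner of a single), `strand`, `its_length`, `wrapped`, `linkage`
#'   ("linked"/"unlinked"/"single").
#' @export
pair_operons <- function(features, topologies, chrom_lengths,
                         its_threshold = 1500L) {
  if (nrow(features) == 0L) return(.empty_units())
  feats <- order_features(features)
  units <- list()
  for (cid in unique(feats$chrom_id)) {
    f <- feats[feats$chrom_id == cid, , drop = FALSE]
    topo <- topologies[[cid]]
    L <- chrom_lengths[[cid]]
    if (is.null(topo) || is.null(L) || is.na(topo) || is.na(L)) {
      stop("missing topology or length for chromosome ", cid)
    }
    n <- nrow(f)
    consumed <- logical(n)
    paired <- list()
    i <- 1L
    while (i < n) {
      if (.pairable(f, i, i + 1L)) {
        paired[[length(paired) + 1L]] <- list(up = i, down = i + 1L,
                                              wrapped = FALSE)
        consumed[c(i, i + 1L)] <- TRUE
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    if (topo == "circular" && n >= 2L && !consumed[n] && !consumed[1L] &&
        .pairable(f, n, 1L)) {
      paired[[length(paired) + 1L]] <- list(up = n, down = 1L, wrapped = TRUE)
      consumed[c(n, 1L)] <- TRUE
    }
    for (p in paired) {
      up <- p$up; down <- p$down
      its <- its_length(f$end[up], f$start[down], topo, L)
      ssu <- if (f$rna_type[up] == "16S") up else down
      lsu <- if (ssu == up) down else up
      units[[length(units) + 1L]] <- data.frame(
        chrom_id = cid, kind = "pair",
        ssu_start = f$start[ssu], ssu_end = f$end[ssu],
        lsu_start = f$start[lsu], lsu_end = f$end[lsu],
        strand = f$strand[up], its_length = its, wrapped = p$wrapped,
        linkage = if (its <= its_threshold) "linked" else "unlinked",
        stringsAsFactors = FALSE)
    }
    for (i in which(!consumed)) {
      is_ssu <- f$rna_type[i] == "16S"
      units[[length(units) + 1L]] <- data.frame(
        chrom_id = cid, kind = "single",
        ssu_start = if (is_ssu) f$start[i] else NA_integer_,
        ssu_end = if (is_ssu) f$end[i] else NA_integer_,
        lsu_start = if (is_ssu) NA_integer_ else f$start[i],
        lsu_end = if (is_ssu) NA_integer_ else f$end[i],
        strand = f$strand[i], its_length = NA_integer_, wrapped = FALSE,
        linkage = "single", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, units)
  rownames(out) <- NULL
  out
}

#' Classify one operon unit as linked or unlinked
#'
#' A pair with ITS of at most `its_threshold` bp is linked; strictly over
#' the threshold, unlinked (so 1500 itself is linked under the default).
#'
#' @param unit One-row data.frame from [pair_operons()] with
#'   `kind = "pair"`.
#' @param its_threshold Boundary in bp (default 1500).
#' @return "linked" or "unlinked".
#' @export
classify_unit <- function(unit, its_threshold = 1500L) {
  if (nrow(unit) != 1L) stop("classify_unit expects a single unit row")
  if (unit$kind != "pair") {
    stop("classify_unit is defined for pairs only; got a single")
  }
  if (unit$its_length <= its_threshold) "linked" else "unlinked"
}

#' Classify a genome from its operon units
#'
#' A genome is linked when every unit is a linked pair, unlinked when it
#' has no linked pair at all, mixed when linked pairs coexist with
#' unlinked pairs or singles, and undetermined when it has no 16S/23S
#' features. Singles count as unlinked evidence: a lone 16S or 23S means
#' its partner sits elsewhere (other strand, other replicon, or far away),
#' the hallmark of operon disruption.
#'
#' @param units data.frame of all operon units of one genome.
#' @param genome_id Genome identifier echoed in the result.
#' @return One-row data.frame: `genome_id`, `status`
#'   ("linked"/"mixed"/"unlinked"/"undetermined"), `n_linked`,
#'   `n_unlinked`, `n_singles`, `singles_policy` (constant "unlinked").
#' @export
classify_genome <- function(units, genome_id = "genome") {
  n_linked <- sum(units$linkage == "linked")
  n_unlinked <- sum(units$linkage == "unlinked")
  n_singles <- sum(units$linkage == "single")
  status <- if (nrow(units) == 0L) {
    "undetermined"
  } else if (n_linked >= 1L && n_unlinked == 0L && n_singles == 0L) {
    "linked"
  } else if (n_linked == 0L) {
    "unlinked"
  } else {
    "mixed"
  }
  data.frame(genome_id = genome_id, status = status,
             n_linked = n_linked, n_unlinked = n_unlinked,
             n_singles = n_singles, singles_policy = "unlinked",
             stringsAsFactors = FALSE)
}

#' Pair and classify one genome in a single call
#'
#' @param chromosomes Named list of chromosome records.
#' @param features rRNA feature data.frame for the genome.
#' @param genome_id Genome identifier.
#' @param its_threshold Linked/unlinked ITS boundary in bp.
#' @return List with `units` (from [pair_operons()]) and `call` (from
#'   [classify_genome()]).
#' @export
call_genome <- function(chromosomes, features, genome_id = "genome",
                        its_threshold = 1500L) {
  topo <- vapply(chromosomes, `[[`, character(1), "topology")
  len <- vapply(chromosomes, `[[`, numeric(1), "length")
  units <- pair_operons(features, topo, len, its_threshold)
  list(units = units, call = classify_genome(units, genome_id))
}
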