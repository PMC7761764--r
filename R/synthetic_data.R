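# Synthetic bacterial genomes (FASTA + GFF3 + ground-truth manifest) for
# validating every pipeline stage: linked, unlinked, antisense,
# origin-spanning and single-gene operon configurations, planted primer
# site mutations, partial-annotation flags and annotation errors.
#
# rRNA templates embed exact realizations of the default primer sites, so
# screening failures occur only where the scenario plants them.

.P16S_F <- "AGRGTTYGATYHTGGCTCAG"
.P16S_F_REAL <- "AGAGTTTGATCATGGCTCAG"
.P16S_R <- "TACCTTGTTAYGACTT"
.P16S_R_REAL <- "TACCTTGTTACGACTT"
.P23S_F <- "GGAACTGAAACATCTAAGTA"
.P23S_F_REAL <- "GGAACTGAAACATCTAAGTA"
.P23S_R <- "ACCRCCCCAGTHAAACT"
.P23S_R_REAL <- "ACCACCCCAGTAAAACT"
.LEN_16S <- 1550L
.LEN_23S <- 2900L
.UNIT_GAP <- 2000L  # minimum background spacing between operon units

# Substitute n_sub positions of a primer-site realization with bases
# outside the degenerate primer's allowed set, so the mismatch count
# against the degenerate primer is exactly n_sub.
.mutate_site <- function(realization, degenerate, n_sub) {
  if (n_sub == 0L) return(realization)
  chars <- strsplit(realization, "", fixed = TRUE)[[1]]
  dchars <- strsplit(degenerate, "", fixed = TRUE)[[1]]
  if (n_sub > length(chars)) stop("more substitutions than primer positions")
  pos <- sample(seq_along(chars), n_sub)
  for (p in pos) {
    forbidden <- .IUPAC_SETS[[dchars[p]]]
    choices <- setdiff(c("A", "C", "G", "T"), forbidden)
    if (length(choices) == 0L) {
      stop("cannot plant a mismatch at an N position of the primer")
    }
    chars[p] <- sample(choices, 1L)
  }
  paste(chars, collapse = "")
}

#' Build a synthetic rRNA gene template carrying primer binding sites
#'
#' The 16S template (1550 bp) begins with a realization of the 27F site
#' and ends with the reverse complement of a 1492R realization; the 23S
#' template (2900 bp) analogously carries the 11a / 2241r sites. Interior
#' bases are pseudo-random at the requested AT fraction. Both defaults sit
#' inside their product-length windows by construction, so each template
#' yields exactly one amplicon at zero mismatches.
#'
#' @param rna_type "16S" or "23S".
#' @param at Interior AT fraction.
#' @param fwd_sub,rev_sub Substitutions to plant inside the forward /
#'   reverse primer site (each guaranteed to count as a mismatch against
#'   the degenerate primer).
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return Character scalar sequence.
#' @export
build_rrna_template <- function(rna_type = c("16S", "23S"), at = 0.5,
                                fwd_sub = 0L, rev_sub = 0L, seed = NULL) {
  rna_type <- match.arg(rna_type)
  if (!is.null(seed)) set.seed(seed)
  if (rna_type == "16S") {
    fwd <- .mutate_site(.P16S_F_REAL, .P16S_F, fwd_sub)
    rev <- .mutate_site(.P16S_R_REAL, .P16S_R, rev_sub)
    total <- .LEN_16S
  } else {
    fwd <- .mutate_site(.P23S_F_REAL, .P23S_F, fwd_sub)
    rev <- .mutate_site(.P23S_R_REAL, .P23S_R, rev_sub)
    total <- .LEN_23S
  }
  interior <- random_dna(total - nchar(fwd) - nchar(rev), at)
  paste0(fwd, interior, revcomp(rev))
}

# Re-randomize background windows that accidentally resemble a primer
# site within `max_mm` mismatches, so that in silico PCR finds only the
# sites the scenario planted. Zones (planted primer-site intervals) are
# never edited. The budget is scrubbed with a margin above the largest
# screening budget (4), making spurious amplicons impossible by
# construction rather than merely improbable.
.scrub_background <- function(sequence, zones, at, max_mm = 5L,
                              max_iter = 25L) {
  primers <- c(.P16S_F, .P16S_R, .P23S_F, .P23S_R)
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (p in primers) {
      sites <- find_primer_sites(sequence, p, max_mm)
      if (!nrow(sites)) next
      plen <- nchar(p)
      for (k in seq_len(nrow(sites))) {
        s0 <- sites$position[k]
        e0 <- s0 + plen - 1L
        in_zone <- any(zones$start <= e0 & zones$end >= s0)
        if (in_zone) next
        substr(sequence, s0, e0) <- random_dna(plen, at)
        dirty <- TRUE
      }
    }
    if (!dirty) return(sequence)
  }
  stop("could not scrub accidental primer sites from the background")
}

.LAYOUT_TYPES <- c("linked_pair", "unlinked_pair", "antisense_pair",
                   "wraparound_pair", "single_16S", "single_23S")

.default_its <- c(linked_pair = 300L, unlinked_pair = 5000L,
                  antisense_pair = 300L, wraparound_pair = 1149L,
                  single_16S = NA_integer_, single_23S = NA_integer_)

#' Describe a synthetic genome scenario
#'
#' @param genome_id Genome identifier (also the output file stem).
#' @param layouts data.frame with columns `type` (one of linked_pair,
#'   unlinked_pair, antisense_pair, wraparound_pair, single_16S,
#'   single_23S), and optionally `its` (bp, pairs only), `strand`
#'   ("+"/"-"; antisense_pair forces "-") and `chrom` (replicon index,
#'   default 1). At most one wraparound per chromosome.
#' @param topology Per-chromosome topology (recycled), default circular.
#' @param chrom_lengths Optional chromosome lengths (bp); when NA the
#'   length is whatever the layouts plus terminal padding require.
#' @param at Background/interior AT fraction.
#' @param pad Extra background appended to each chromosome (bp); this is
#'   the lever that gives genome classes different genome sizes.
#' @param wrap_tail For a wraparound pair of ITS t: bases between the
#'   upstream gene's end and the chromosome end (default floor(t/2)); the
#'   downstream gene then starts at t - wrap_tail + 1.
#' @param primer_mutations Optional data.frame with columns `layout`
#'   (index into `layouts`), `site` ("16S_fwd", "16S_rev", "23S_fwd",
#'   "23S_rev") and `n_sub`.
#' @param partial_features Indices (in emitted feature order) to flag
#'   `partial=true` in the GFF.
#' @param annotation_error "none", "missing_feature" (GFF omits the last
#'   feature) or "extra_feature" (GFF gains a phantom 16S); the sequence
#'   is never touched.
#' @param seed Integer seed controlling all randomness of the genome.
#' @return List of class `genome_scenario`.
#' @export
genome_scenario <- function(genome_id, layouts, topology = "circular",
                            chrom_lengths = NA, at = 0.5, pad = 2000L,
                            wrap_tail = NULL, primer_mutations = NULL,
                            partial_features = integer(),
                            annotation_error = c("none", "missing_feature",
                                                 "extra_feature"),
                            seed = 1L) {
  annotation_error <- match.arg(annotation_error)
  layouts <- as.data.frame(layouts, stringsAsFactors = FALSE)
  if (!all(layouts$type %in% .LAYOUT_TYPES)) {
    stop("unknown layout type(s): ",
         paste(setdiff(layouts$type, .LAYOUT_TYPES), collapse = ", "))
  }
  if (is.null(layouts$its)) layouts$its <- NA_integer_
  layouts$its <- ifelse(is.na(layouts$its),
                        .default_its[layouts$type], layouts$its)
  if (is.null(layouts$strand)) layouts$strand <- "+"
  layouts$strand[is.na(layouts$strand)] <- "+"
  layouts$strand[layouts$type == "antisense_pair"] <- "-"
  if (is.null(layouts$chrom)) layouts$chrom <- 1L
  bad <- layouts$type == "linked_pair" & layouts$its > 1500
  if (any(bad)) stop("linked_pair layouts require its <= 1500")
  bad <- layouts$type == "unlinked_pair" & layouts$its <= 1500
  if (any(bad)) stop("unlinked_pair layouts require its > 1500")
  n_chrom <- max(layouts$chrom)
  topology <- rep(topology, length.out = n_chrom)
  chrom_lengths <- rep(chrom_lengths, length.out = n_chrom)
  wrap_per_chrom <- tapply(layouts$type == "wraparound_pair",
                           factor(layouts$chrom, levels = seq_len(n_chrom)),
                           sum)
  if (any(wrap_per_chrom > 1, na.rm = TRUE)) {
    stop("at most one wraparound_pair per chromosome")
  }
  if (any(layouts$type == "wraparound_pair" &
            topology[layouts$chrom] != "circular")) {
    stop("wraparound_pair requires a circular chromosome")
  }
  structure(list(genome_id = genome_id, layouts = layouts,
                 topology = topology, chrom_lengths = chrom_lengths,
                 at = at, pad = as.integer(pad), wrap_tail = wrap_tail,
                 primer_mutations = primer_mutations,
                 partial_features = as.integer(partial_features),
                 annotation_error = annotation_error,
                 seed = as.integer(seed)),
            class = "genome_scenario")
}

# Substitution counts planted for one layout row, as c(fwd, rev) per gene.
.layout_subs <- function(spec, layout_idx, gene) {
  pm <- spec$primer_mutations
  if (is.null(pm)) return(c(0L, 0L))
  pm <- pm[pm$layout == layout_idx, , drop = FALSE]
  c(sum(pm$n_sub[pm$site == paste0(gene, "_fwd")]),
    sum(pm$n_sub[pm$site == paste0(gene, "_rev")]))
}

#' Realize a genome scenario as sequence, annotation and truth manifest
#'
#' Deterministic given the scenario's seed. When `dir` is given, writes
#' `<genome_id>.fna` and `<genome_id>.gff` (GFF3 with `region` lines
#' carrying `Is_circular=true` for circular replicons). Annotation errors
#' and partial flags affect the GFF only; the sequence always contains
#' every planted gene.
#'
#' @param spec A [genome_scenario()].
#' @param dir Optional output directory (created if needed).
#' @return List: `genome_id`, `chromosomes` (records), `features` (truth,
#'   including partial flags), `gff_features` (the annotation view),
#'   `units` (expected operon units: layout, kind, its, linkage),
#'   `expected_call`, `expected_verdict`, `files` (paths or NULL).
#' @export
simulate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "genome_scenario"))
  set.seed(spec$seed)
  n_chrom <- length(spec$topology)
  chrom_ids <- paste0(spec$genome_id, "_chr", seq_len(n_chrom))
  chroms <- vector("list", n_chrom)
  feats <- list()
  units <- list()

  emit_feat <- function(cid, type, strand, start, len) {
    data.frame(chrom_id = cid, rna_type = type, strand = strand,
               start = as.integer(start), end = as.integer(start + len - 1L),
               partial = FALSE, source = "annotation",
               stringsAsFactors = FALSE)
  }

  for (ci in seq_len(n_chrom)) {
    cid <- chrom_ids[ci]
    lay <- which(spec$layouts$chrom == ci)
    wrap_idx <- lay[spec$layouts$type[lay] == "wraparound_pair"]
    normal_idx <- setdiff(lay, wrap_idx)
    pieces <- character()
    pos <- 1L
    cfeats <- list()

    gene_block <- function(li, gene) {
      subs <- .layout_subs(spec, li, gene)
      build_rrna_template(gene, at = spec$at,
                          fwd_sub = subs[1], rev_sub = subs[2])
    }

    # head of a wraparound pair: downstream gene starts at ds = t - a + 1
    wrap <- NULL
    if (length(wrap_idx)) {
      li <- wrap_idx
      t_its <- spec$layouts$its[li]
      a <- if (is.null(spec$wrap_tail)) t_its %/% 2L else
        as.integer(spec$wrap_tail)
      if (a < 0L || a > t_its) stop("wrap_tail must lie in [0, its]")
      ds <- t_its - a + 1L
      strand <- spec$layouts$strand[li]
      down_gene <- if (strand == "+") "23S" else "16S"
      up_gene <- if (strand == "+") "16S" else "23S"
      down_seq <- gene_block(li, down_gene)
      if (strand == "-") down_seq <- revcomp(down_seq)
      pieces <- c(pieces, random_dna(ds - 1L, spec$at), down_seq)
      cfeats[[length(cfeats) + 1L]] <-
        cbind(emit_feat(cid, down_gene, strand, ds, nchar(down_seq)),
              layout = li)
      pos <- ds + nchar(down_seq)
      wrap <- list(li = li, a = a, up_gene = up_gene, strand = strand)
      units[[length(units) + 1L]] <- data.frame(
        layout = li, chrom_id = cid, kind = "pair", its = t_its,
        linkage = if (t_its <= 1500L) "linked" else "unlinked",
        wrapped = TRUE, stringsAsFactors = FALSE)
    }

    for (li in normal_idx) {
      gap <- .UNIT_GAP + sample.int(600L, 1L)
      pieces <- c(pieces, random_dna(gap, spec$at))
      pos <- pos + gap
      type <- spec$layouts$type[li]
      strand <- spec$layouts$strand[li]
      its <- spec$layouts$its[li]
      if (type %in% c("linked_pair", "unlinked_pair", "antisense_pair")) {
        first_gene <- if (strand == "+") "16S" else "23S"
        second_gene <- if (strand == "+") "23S" else "16S"
        s1 <- gene_block(li, first_gene)
        s2 <- gene_block(li, second_gene)
        if (strand == "-") { s1 <- revcomp(s1); s2 <- revcomp(s2) }
        pieces <- c(pieces, s1, random_dna(its, spec$at), s2)
        cfeats[[length(cfeats) + 1L]] <-
          cbind(emit_feat(cid, first_gene, strand, pos, nchar(s1)),
                layout = li)
        pos2 <- pos + nchar(s1) + its
        cfeats[[length(cfeats) + 1L]] <-
          cbind(emit_feat(cid, second_gene, strand, pos2, nchar(s2)),
                layout = li)
        pos <- pos2 + nchar(s2)
        units[[length(units) + 1L]] <- data.frame(
          layout = li, chrom_id = cid, kind = "pair", its = its,
          linkage = if (its <= 1500L) "linked" else "unlinked",
          wrapped = FALSE, stringsAsFactors = FALSE)
      } else {
        gene <- if (type == "single_16S") "16S" else "23S"
        s <- gene_block(li, gene)
        if (strand == "-") s <- revcomp(s)
        pieces <- c(pieces, s)
        cfeats[[length(cfeats) + 1L]] <-
          cbind(emit_feat(cid, gene, strand, pos, nchar(s)), layout = li)
        pos <- pos + nchar(s)
        units[[length(units) + 1L]] <- data.frame(
          layout = li, chrom_id = cid, kind = "single", its = NA_integer_,
          linkage = "single", wrapped = FALSE, stringsAsFactors = FALSE)
      }
    }

    # tail: wraparound upstream gene must end exactly `a` bp before the end
    target_len <- spec$chrom_lengths[ci]
    if (!is.null(wrap)) {
      up_seq <- gene_block(wrap$li, wrap$up_gene)
      if (wrap$strand == "-") up_seq <- revcomp(up_seq)
      if (is.na(target_len)) {
        target_len <- pos - 1L + .UNIT_GAP + spec$pad + nchar(up_seq) + wrap$a
      }
      up_start <- target_len - wrap$a - nchar(up_seq) + 1L
      gap <- up_start - pos
      if (gap < .UNIT_GAP) {
        stop("layouts overflow chromosome ", cid, ": need ",
             pos + .UNIT_GAP + nchar(up_seq) + wrap$a - 1L,
             " bp, have ", target_len)
      }
      pieces <- c(pieces, random_dna(gap, spec$at), up_seq,
                  random_dna(wrap$a, spec$at))
      cfeats[[length(cfeats) + 1L]] <-
        cbind(emit_feat(cid, wrap$up_gene, wrap$strand, up_start,
                        nchar(up_seq)), layout = wrap$li)
    } else {
      if (is.na(target_len)) target_len <- pos - 1L + .UNIT_GAP + spec$pad
      tail_len <- target_len - (pos - 1L)
      if (tail_len < 0L) {
        stop("layouts overflow chromosome ", cid, ": need ", pos - 1L,
             " bp, have ", target_len)
      }
      pieces <- c(pieces, random_dna(tail_len, spec$at))
    }
    seqs <- paste(pieces, collapse = "")
    stopifnot(nchar(seqs) == target_len)
    cf <- do.call(rbind, cfeats)
    zones <- if (is.null(cf)) {
      data.frame(start = integer(), end = integer())
    } else {
      # planted primer-binding ends of each gene (longest primer is 20 bp)
      data.frame(start = c(cf$start, pmax(cf$end - 25L, 1L)),
                 end = c(pmin(cf$start + 25L, target_len), cf$end))
    }
    seqs <- .scrub_background(seqs, zones, spec$at)
    chroms[[ci]] <- .new_chrom(cid, seqs, spec$topology[ci])
    feats[[ci]] <- do.call(rbind, cfeats)
  }
  names(chroms) <- chrom_ids
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  units <- do.call(rbind, units)
  rownames(units) <- NULL

  if (length(spec$partial_features)) {
    if (any(spec$partial_features > nrow(features))) {
      stop("partial_features index out of range")
    }
    features$partial[spec$partial_features] <- TRUE
  }

  # annotation view (what the GFF claims), possibly wrong on purpose
  gff_features <- features
  if (spec$annotation_error == "missing_feature") {
    gff_features <- gff_features[-nrow(gff_features), , drop = FALSE]
  } else if (spec$annotation_error == "extra_feature") {
    cid <- chrom_ids[1L]
    L <- chroms[[1L]]$length
    phantom_start <- L - .LEN_16S - 50L
    occupied <- features$chrom_id == cid &
      features$start <= phantom_start + .LEN_16S - 1L &
      features$end >= phantom_start
    if (any(occupied)) stop("no room for a phantom feature on ", cid)
    gff_features <- rbind(gff_features,
                          cbind(emit_feat(cid, "16S", "+", phantom_start,
                                          .LEN_16S), layout = NA_integer_))
  }

  # expected genome classification from the truth units (partial-flagged
  # features never reach the classifier, but partials also break
  # screening, so classification expectations assume no partial flags)
  complete_units <- units
  n_linked <- sum(complete_units$linkage == "linked")
  n_unlinked <- sum(complete_units$linkage == "unlinked")
  n_singles <- sum(complete_units$linkage == "single")
  expected_call <- if (nrow(complete_units) == 0L) "undetermined"
  else if (n_linked >= 1L && n_unlinked == 0L && n_singles == 0L) "linked"
  else if (n_linked == 0L) "unlinked"
  else "mixed"

  max_sub <- 0L
  if (!is.null(spec$primer_mutations) && nrow(spec$primer_mutations)) {
    max_sub <- max(spec$primer_mutations$n_sub)
  }
  expected_verdict <- if (spec$annotation_error != "none" ||
                            length(spec$partial_features)) {
    "excluded"
  } else if (max_sub <= 2L) {
    "pass_mm2"
  } else if (max_sub <= 4L) {
    "pass_mm4"
  } else {
    "excluded"
  }

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fna <- file.path(dir, paste0(spec$genome_id, ".fna"))
    gff <- file.path(dir, paste0(spec$genome_id, ".gff"))
    .write_fasta(chroms, fna)
    .write_gff(chroms, gff_features, gff)
    files <- c(fna = fna, gff = gff)
  }

  list(genome_id = spec$genome_id, chromosomes = chroms,
       features = features, gff_features = gff_features, units = units,
       expected_call = expected_call, expected_verdict = expected_verdict,
       files = files)
}

.write_fasta <- function(chroms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chroms) {
    writeLines(paste0(">", ch$id), con)
    starts <- seq(1L, ch$length, by = 70L)
    writeLines(substring(ch$sequence, starts,
                         pmin(starts + 69L, ch$length)), con)
  }
  invisible(path)
}

.write_gff <- function(chroms, features, path) {
  lines <- "##gff-version 3"
  for (ch in chroms) {
    lines <- c(lines,
               paste("##sequence-region", ch$id, 1L, ch$length))
  }
  for (ch in chroms) {
    attrs <- paste0("ID=", ch$id, ":1..", ch$length)
    if (ch$topology == "circular") {
      attrs <- paste0(attrs, ";Is_circular=true")
    }
    lines <- c(lines, paste(ch$id, "synthetic", "region", 1L, ch$length,
                            ".", "+", ".", attrs, sep = "\t"))
  }
  if (nrow(features)) {
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      attrs <- paste0("ID=rna", i, ";product=", f$rna_type,
                      " ribosomal RNA")
      if (isTRUE(f$partial)) attrs <- paste0(attrs, ";partial=true")
      lines <- c(lines, paste(f$chrom_id, "synthetic", "rRNA", f$start,
                              f$end, ".", f$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a cohort of synthetic genomes with a ground-truth manifest
#'
#' Builds `n_per_class` genomes per linkage class, cycling over scenario
#' variants so that all six operon layout types (linked, unlinked,
#' antisense, wraparound, single 16S, single 23S) occur in the cohort.
#' Class-conditional distributions mirror the direction of the real
#' symbiont contrast at reduced scale: unlinked genomes are generated
#' smaller and more AT-rich than linked genomes, and are labelled
#' symbionts.
#'
#' @param n_per_class Named integer vector, e.g.
#'   `c(linked = 10, mixed = 10, unlinked = 10)`.
#' @param seed Master seed; the cohort is fully reproducible from it.
#' @param dir Optional directory receiving `<id>.fna`, `<id>.gff`,
#'   `manifest.tsv` and `labels.tsv`.
#' @param at_by_class Background AT fraction per class (defaults 0.514 /
#'   0.501 / 0.649 for linked / mixed / unlinked).
#' @param pad_by_class Extra background padding (bp) per class, the
#'   genome-size lever (defaults 24000 / 16000 / 3000).
#' @return List: `manifest` (data.frame: genome_id, class, expected_call,
#'   expected_verdict, n16S, n23S, symbiont), `genomes` (list of
#'   [simulate_genome()] results), `labels`, `dir`.
#' @export
simulate_cohort <- function(n_per_class = c(linked = 10L, mixed = 10L,
                                            unlinked = 10L),
                            seed = 1L, dir = NULL,
                            at_by_class = c(linked = 0.514, mixed = 0.501,
                                            unlinked = 0.649),
                            pad_by_class = c(linked = 24000L,
                                             mixed = 16000L,
                                             unlinked = 3000L)) {
  stopifnot(all(names(n_per_class) %in% c("linked", "mixed", "unlinked")))
  variants <- list(
    linked = list(
      data.frame(type = c("linked_pair", "linked_pair"), its = c(250L, 400L)),
      data.frame(type = c("linked_pair", "antisense_pair"),
                 its = c(300L, 350L)),
      data.frame(type = c("wraparound_pair", "linked_pair"),
                 its = c(1149L, 500L)),
      data.frame(type = "linked_pair", its = 1500L)
    ),
    mixed = list(
      data.frame(type = c("linked_pair", "unlinked_pair"),
                 its = c(200L, 5000L)),
      data.frame(type = c("linked_pair", "single_16S"),
                 its = c(300L, NA), chrom = c(1L, 2L)),
      data.frame(type = c("linked_pair", "antisense_pair"),
                 its = c(400L, 2000L)),
      data.frame(type = c("wraparound_pair", "single_23S"),
                 its = c(800L, NA), strand = c("+", "-"))
    ),
    unlinked = list(
      data.frame(type = "unlinked_pair", its = 5000L),
      data.frame(type = c("single_16S", "single_23S"), its = c(NA, NA),
                 strand = c("+", "-")),
      data.frame(type = "antisense_pair", its = 5000L),
      data.frame(type = "wraparound_pair", its = 5000L),
      data.frame(type = "single_16S", its = NA)
    )
  )
  set.seed(seed)
  genomes <- list()
  manifest <- list()
  gi <- 0L
  for (cls in names(n_per_class)) {
    for (k in seq_len(n_per_class[[cls]])) {
      gi <- gi + 1L
      v <- variants[[cls]][[(k - 1L) %% length(variants[[cls]]) + 1L]]
      gid <- sprintf("SYN_%s_%03d", cls, k)
      at <- min(max(at_by_class[[cls]] + stats::runif(1, -0.02, 0.02),
                    0.05), 0.95)
      pad <- pad_by_class[[cls]] + sample.int(4000L, 1L)
      spec <- genome_scenario(gid, v, at = at, pad = pad,
                              seed = (seed %% 100000L) * 10000L + gi)
      sim <- simulate_genome(spec, dir = dir)
      stopifnot(sim$expected_call == cls)
      genomes[[gid]] <- sim
      pc <- profile_counts(sim$features)
      manifest[[gid]] <- data.frame(
        genome_id = gid, class = cls, expected_call = sim$expected_call,
        expected_verdict = sim$expected_verdict,
        n16S = pc[["n16S"]], n23S = pc[["n23S"]],
        symbiont = if (cls == "unlinked") "yes" else "no",
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  labels <- manifest[, c("genome_id", "symbiont")]
  if (!is.null(dir)) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(labels, file.path(dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, genomes = genomes, labels = labels, dir = dir)
}

#' Rotate the origin of a circular chromosome's feature coordinates
#'
#' Shifts every coordinate by `offset` modulo the chromosome length.
#' Offsets that would split a feature across the new origin are rejected
#' with an error (features are stored unwrapped).
#'
#' @param features Feature data.frame for one chromosome.
#' @param chrom_length Chromosome length (bp).
#' @param offset Rotation in bp (0 <= offset < chrom_length).
#' @return The rotated, re-sorted feature data.frame.
#' @export
rotate_features <- function(features, chrom_length, offset) {
  offset <- offset %% chrom_length
  ns <- (features$start - 1L + offset) %% chrom_length + 1L
  ne <- (features$end - 1L + offset) %% chrom_length + 1L
  if (any(ne < ns)) {
    stop("rotation by ", offset, " splits a feature across the origin")
  }
  out <- features
  out$start <- as.integer(ns)
  out$end <- as.integer(ne)
  order_features(out)
}

#' Reverse-complement transform of feature coordinates
#'
#' Mirrors coordinates (`start' = L - end + 1`) and flips strands, i.e.
#' the annotation of the reverse-complemented chromosome.
#'
#' @param features Feature data.frame for one chromosome.
#' @param chrom_length Chromosome length (bp).
#' @return Transformed, re-sorted feature data.frame.
#' @export
revcomp_features <- function(features, chrom_length) {
  out <- features
  out$start <- as.integer(chrom_length - features$end + 1L)
  out$end <- as.integer(chrom_length - features$start + 1L)
  out$strand <- ifelse(features$strand == "+", "-", "+")
  order_features(out)
}
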