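# Reading genome FASTA and GFF3 rRNA annotations.
#
# A chromosome record is a plain list with fields id, sequence, length and
# topology ("circular" or "linear"); a genome is a named list of such
# records. rRNA features are rows of a data.frame with 1-based inclusive
# GFF3 coordinates, the convention used by all downstream arithmetic.

.new_chrom <- function(id, sequence, topology = "circular") {
  stopifnot(topology %in% c("circular", "linear"))
  structure(list(id = id, sequence = toupper(sequence),
                 length = nchar(sequence), topology = topology),
            class = "chrom_record")
}

.empty_features <- function() {
  data.frame(chrom_id = character(), rna_type = character(),
             strand = character(), start = integer(), end = integer(),
             partial = logical(), source = character(),
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA file into chromosome records
#'
#' Each FASTA entry becomes one chromosome record (id = first token of the
#' header, sequence upper-cased). Topology is taken from the `topology`
#' map where supplied, otherwise every replicon defaults to circular --
#' the predominant topology of complete bacterial chromosomes -- and the
#' default is reported via a message.
#'
#' @param fasta_path Path to a FASTA (.fna) file.
#' @param topology Optional named character vector mapping chromosome id to
#'   "circular" or "linear" (see [detect_topology()]).
#' @param quiet Suppress the defaulting message.
#' @return Named list of chromosome records, each with fields `id`,
#'   `sequence`, `length`, `topology`.
#' @export
read_genome <- function(fasta_path, topology = NULL, quiet = FALSE) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dss) == 0L) stop("empty FASTA file: ", fasta_path)
  ids <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome ids in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  defaulted <- character()
  recs <- lapply(seq_along(dss), function(i) {
    topo <- topology[[ids[i]]]
    if (is.null(topo) || is.na(topo)) {
      topo <- "circular"
      defaulted <<- c(defaulted, ids[i])
    }
    .new_chrom(ids[i], as.character(dss[[i]]), topo)
  })
  names(recs) <- ids
  if (length(defaulted) && !quiet) {
    message("read_genome: no topology information for ",
            paste(defaulted, collapse = ", "), "; defaulting to circular")
  }
  recs
}

#' Read 16S/23S rRNA features from a GFF3 annotation
#'
#' Keeps features of type `rRNA` whose product/Name/gene attribute contains
#' "16S" or "23S" (case-insensitive); 5S and all other feature types are
#' dropped. Features flagged partial -- an attribute `partial=true`
#' (case-insensitive) or a Note containing "prediction is too short" -- are
#' removed, as incomplete gene models cannot be paired into operon units.
#'
#' @param gff_path Path to a GFF3 file.
#' @param quiet Suppress the message reporting removed partial features.
#' @return data.frame with columns `chrom_id`, `rna_type` ("16S"/"23S"),
#'   `strand` ("+"/"-"), `start`, `end` (1-based inclusive), `partial`
#'   (all FALSE after filtering), `source` ("annotation").
#' @export
read_rrna_features <- function(gff_path, quiet = FALSE) {
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  gr <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("cannot parse GFF3 '", gff_path, "' (check for ",
                             "end < start or malformed records): ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !any(df$type == "rRNA")) return(.empty_features())
  df <- df[df$type == "rRNA", , drop = FALSE]

  label_cols <- intersect(c("product", "Name", "gene"), names(df))
  label <- rep("", nrow(df))
  for (col in label_cols) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    label <- paste(label, v)
  }
  rna_type <- rep(NA_character_, nrow(df))
  rna_type[grepl("16S", label, ignore.case = TRUE)] <- "16S"
  rna_type[grepl("23S", label, ignore.case = TRUE)] <- "23S"
  keep <- !is.na(rna_type)
  df <- df[keep, , drop = FALSE]
  rna_type <- rna_type[keep]
  if (nrow(df) == 0L) return(.empty_features())

  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("rRNA feature with unknown strand symbol '",
         strand[!strand %in% c("+", "-")][1], "' in ", gff_path)
  }

  partial <- rep(FALSE, nrow(df))
  if ("partial" %in% names(df)) {
    v <- tolower(as.character(df$partial))
    partial <- partial | (!is.na(v) & v == "true")
  }
  if ("Note" %in% names(df)) {
    v <- vapply(df$Note, function(n) paste(as.character(n), collapse = " "),
                character(1))
    partial <- partial | grepl("prediction is too short", v, ignore.case = TRUE)
  }

  out <- data.frame(
    chrom_id = as.character(df$seqnames),
    rna_type = rna_type,
    strand = strand,
    start = as.integer(df$start),
    end = as.integer(df$end),
    partial = FALSE,
    source = "annotation",
    stringsAsFactors = FALSE
  )
  if (any(partial)) {
    if (!quiet) {
      message("read_rrna_features: removed ", sum(partial),
              " partial rRNA feature(s)")
    }
    out <- out[!partial, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Determine chromosome topology from a GFF3 file
#'
#' Reads `region` features carrying the `Is_circular=true` convention.
#' Chromosomes with no topology information default to circular (reported
#' via a message); entries of `override` always win, with a warning when
#' they contradict the file.
#'
#' @param gff_path Path to a GFF3 file.
#' @param override Optional named character vector id -> topology.
#' @param quiet Suppress the defaulting message.
#' @return Named character vector mapping chromosome id to "circular" or
#'   "linear".
#' @export
detect_topology <- function(gff_path, override = NULL, quiet = FALSE) {
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) NULL)
  topo <- character()
  ids <- character()
  if (!is.null(gr)) {
    ids <- GenomeInfoDb::seqlevels(gr)
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    reg <- df[df$type == "region", , drop = FALSE]
    if (nrow(reg) && "Is_circular" %in% names(reg)) {
      v <- tolower(as.character(reg$Is_circular))
      circ <- !is.na(v) & v == "true"
      topo <- ifelse(circ, "circular", "linear")
      names(topo) <- as.character(reg$seqnames)
      # regions lacking the attribute entirely stay unspecified
      topo <- topo[!is.na(as.character(reg$Is_circular)) | circ]
    }
  }
  missing_ids <- setdiff(ids, names(topo))
  if (length(missing_ids)) {
    if (!quiet) {
      message("detect_topology: no topology recorded for ",
              paste(missing_ids, collapse = ", "),
              "; defaulting to circular")
    }
    add <- rep("circular", length(missing_ids))
    names(add) <- missing_ids
    topo <- c(topo, add)
  }
  if (!is.null(override)) {
    for (id in names(override)) {
      if (id %in% names(topo) && topo[[id]] != override[[id]]) {
        warning("detect_topology: override '", override[[id]], "' for ", id,
                " contradicts file value '", topo[[id]], "'; override wins")
      }
      topo[[id]] <- override[[id]]
    }
  }
  topo
}

#' Load one genome (FASTA + GFF3) as chromosomes plus rRNA features
#'
#' @param fasta_path FASTA file.
#' @param gff_path GFF3 annotation for the same assembly.
#' @param topology_override Optional named vector id -> topology.
#' @param quiet Suppress informational messages.
#' @return List with elements `chromosomes` (list of chromosome records)
#'   and `features` (data.frame from [read_rrna_features()]).
#' @export
load_genome <- function(fasta_path, gff_path, topology_override = NULL,
                        quiet = FALSE) {
  topo <- detect_topology(gff_path, override = topology_override,
                          quiet = quiet)
  chroms <- read_genome(fasta_path, topology = topo, quiet = quiet)
  feats <- read_rrna_features(gff_path, quiet = quiet)
  bad <- !feats$chrom_id %in% names(chroms)
  if (any(bad)) {
    stop("features reference unknown chromosome(s): ",
         paste(unique(feats$chrom_id[bad]), collapse = ", "))
  }
  for (i in seq_len(nrow(feats))) {
    L <- chroms[[feats$chrom_id[i]]]$length
    if (feats$start[i] < 1L || feats$end[i] > L) {
      stop("feature outside chromosome bounds on ", feats$chrom_id[i],
           " [", feats$start[i], ", ", feats$end[i], "] vs length ", L)
    }
  }
  list(chromosomes = chroms, features = feats)
}
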