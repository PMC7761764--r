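# End-to-end orchestration: screen -> classify -> feature table -> stats,
# with deterministic TSV outputs and a run log echoing every effective
# parameter.

#' Assemble a pipeline configuration
#'
#' All analysis parameters live here with their standard defaults: ITS
#' linked/unlinked threshold 1500 bp, mismatch budgets 2 then 4, the
#' universal 16S/23S primer pairs with their product-length windows, and
#' the fixed singles-as-unlinked policy (echoed in outputs).
#'
#' @param its_threshold Linked/unlinked ITS boundary (bp), > 0.
#' @param mismatch_budgets Strictly increasing integer vector.
#' @param primer_pairs Named list of [primer_pair()] objects.
#' @param topology_override Optional named vector chrom_id -> topology.
#' @param seed Seed for any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(its_threshold = 1500L,
                            mismatch_budgets = c(2L, 4L),
                            primer_pairs = default_primer_pairs(),
                            topology_override = NULL, seed = 1L) {
  stopifnot(its_threshold > 0,
            !is.unsorted(mismatch_budgets, strictly = TRUE))
  structure(list(its_threshold = as.integer(its_threshold),
                 mismatch_budgets = as.integer(mismatch_budgets),
                 primer_pairs = primer_pairs,
                 topology_override = topology_override,
                 singles_policy = "unlinked", seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `its_threshold`, `mismatch_budgets`, `seed`, and
#' `primer_pairs` (a list of records with `target`, `forward`, `reverse`,
#' `min_product_len`, `max_product_len`). Missing keys keep defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  pairs <- default_primer_pairs()
  if (!is.null(y$primer_pairs)) {
    pairs <- lapply(y$primer_pairs, function(p) {
      primer_pair(p$target, p$forward, p$reverse,
                  p$min_product_len, p$max_product_len)
    })
    names(pairs) <- vapply(pairs, `[[`, character(1), "target")
  }
  pipeline_config(
    its_threshold = if (is.null(y$its_threshold)) 1500L else y$its_threshold,
    mismatch_budgets = if (is.null(y$mismatch_budgets)) c(2L, 4L) else
      unlist(y$mismatch_budgets),
    primer_pairs = pairs,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full linkage-classification pipeline on a genome directory
#'
#' Discovers genomes as `<id>.fna` / `<id>.gff` file pairs in
#' `input_dir`, screens each genome's annotated rRNA counts against in
#' silico PCR, classifies screened genomes into linked / mixed / unlinked
#' by operon pairing, computes the per-genome feature table (joining
#' `labels.tsv` symbiont labels when present), and runs Kruskal-Wallis +
#' Dunn comparisons of each feature across genome classes when at least
#' three classes have two or more genomes. Excluded genomes appear in
#' `screening.tsv` only.
#'
#' @param input_dir Directory of genome files (e.g. from
#'   [simulate_cohort()]).
#' @param output_dir Directory for TSV reports (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `screening`, `units`, `calls`,
#'   `features`, `stats` and `output_dir`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  fnas <- sort(list.files(input_dir, pattern = "\\.fna$", full.names = TRUE))
  if (!length(fnas)) stop("no .fna files found in ", input_dir)
  ids <- sub("\\.fna$", "", basename(fnas))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_path <- file.path(output_dir, "run_log.txt")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  logline <- function(...) writeLines(paste0(...), logf)
  logline("rrnalink pipeline run")
  logline("its_threshold=", config$its_threshold)
  logline("mismatch_budgets=", paste(config$mismatch_budgets, collapse = ","))
  logline("singles_policy=", config$singles_policy)
  for (p in config$primer_pairs) {
    logline("primer_pair target=", p$target, " fwd=", p$forward,
            " rev=", p$reverse, " window=(", p$min_product_len, ",",
            p$max_product_len, ")")
  }
  logline("seed=", config$seed)

  cohort <- list()
  for (i in seq_along(ids)) {
    gff <- file.path(input_dir, paste0(ids[i], ".gff"))
    if (!file.exists(gff)) stop("genome ", ids[i], ": missing GFF file ", gff)
    cohort[[ids[i]]] <- tryCatch(
      load_genome(fnas[i], gff,
                  topology_override = config$topology_override,
                  quiet = TRUE),
      error = function(e) stop("genome ", ids[i], ", stage annotation_io: ",
                               conditionMessage(e), call. = FALSE))
  }
  logline("genomes_read=", length(cohort))

  screening <- tryCatch(
    screen_cohort(cohort, pairs = config$primer_pairs,
                  budgets = config$mismatch_budgets),
    error = function(e) stop("stage concordance: ", conditionMessage(e),
                             call. = FALSE))
  .write_tsv(screening, file.path(output_dir, "screening.tsv"))
  passed <- screening$genome_id[screening$verdict != "excluded"]
  logline("genomes_passed_screening=", length(passed))

  units_all <- list()
  calls <- list()
  for (gid in passed) {
    g <- cohort[[gid]]
    res <- tryCatch(
      call_genome(g$chromosomes, g$features, genome_id = gid,
                  its_threshold = config$its_threshold),
      error = function(e) stop("genome ", gid, ", stage operon_classifier: ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(res$units)) {
      units_all[[gid]] <- cbind(genome_id = gid, res$units)
    }
    calls[[gid]] <- res$call
  }
  units <- if (length(units_all)) do.call(rbind, units_all) else
    cbind(genome_id = character(), .empty_units())
  rownames(units) <- NULL
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  .write_tsv(units, file.path(output_dir, "units.tsv"))
  .write_tsv(calls, file.path(output_dir, "genome_calls.tsv"))

  labels_path <- file.path(input_dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) {
    utils::read.delim(labels_path, stringsAsFactors = FALSE)
  } else NULL
  features <- build_feature_table(cohort[passed], calls,
                                  symbiont_labels = labels)
  .write_tsv(features, file.path(output_dir, "features.tsv"))

  stats_dir <- file.path(output_dir, "stats")
  if (!dir.exists(stats_dir)) dir.create(stats_dir)
  stats_out <- list()
  grp <- features$status
  eligible <- sum(table(grp) >= 2L) >= 3L
  if (eligible) {
    for (feat in c("genome_size", "genome_at", "n16S",
                   "mean_16S_len", "mean_23S_len")) {
      v <- features[[feat]]
      ok <- !is.na(v)
      if (sum(table(grp[ok]) >= 2L) < 3L) next
      kd <- kruskal_dunn(v[ok], grp[ok])
      stats_out[[feat]] <- cbind(feature = feat, kd$comparisons,
                                 H = kd$H, kw_p = kd$p_value,
                                 p_adjust = kd$p_adjust_method)
    }
  } else {
    logline("stats: skipped (need >= 3 status classes with n >= 2)")
  }
  stats_df <- if (length(stats_out)) do.call(rbind, stats_out) else NULL
  if (!is.null(stats_df)) {
    rownames(stats_df) <- NULL
    .write_tsv(stats_df, file.path(stats_dir, "feature_tests.tsv"))
  }
  logline("done")
  invisible(list(screening = screening, units = units, calls = calls,
                 features = features, stats = stats_df,
                 output_dir = output_dir))
}
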