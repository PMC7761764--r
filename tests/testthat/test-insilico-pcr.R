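# Degenerate primer matching, amplicon prediction and locus merging.

test_that("iupac_mismatches follows IUPAC set membership", {
  expect_equal(iupac_mismatches("R", "A"), 0L)
  expect_equal(iupac_mismatches("R", "C"), 1L)
  expect_equal(iupac_mismatches("AGRGTTYGATYHTGGCTCAG",
                                "AGAGTTTGATCATGGCTCAG"), 0L)
  expect_equal(iupac_mismatches("ACGT", "ACGN"), 1L)
  expect_equal(iupac_mismatches("NNNN", "ACGT"), 0L)
  expect_error(iupac_mismatches("ACG", "ACGT"), "length")
  # cross-check a degenerate window against the per-position oracle
  primer <- "AGRGTTYGATYHTGGCTCAG"
  set.seed(5)
  for (i in 1:20) {
    win <- paste(sample(c("A", "C", "G", "T"), nchar(primer), TRUE),
                 collapse = "")
    pc <- strsplit(primer, "")[[1]]
    wc <- strsplit(win, "")[[1]]
    oracle <- sum(vapply(seq_along(pc), function(j) {
      !wc[j] %in% iupac_sets_oracle[[pc[j]]]
    }, logical(1)))
    expect_equal(iupac_mismatches(primer, win), oracle)
  }
})

test_that("find_primer_sites locates planted sites in both orientations", {
  set.seed(11)
  fwd_real <- "AGAGTTTGATCATGGCTCAG"
  rev_real <- "TACCTTGTTACGACTT"
  s <- paste0(random_dna_oracle(100), fwd_real, random_dna_oracle(500),
              revcomp_oracle(rev_real), random_dna_oracle(100))
  hits <- find_primer_sites(s, "AGRGTTYGATYHTGGCTCAG", 0)
  expect_equal(hits$position, 101L)
  expect_equal(hits$orientation, "forward")
  expect_equal(hits$mismatches, 0L)
  rhits <- find_primer_sites(s, "TACCTTGTTAYGACTT", 0)
  expect_equal(rhits$position, 621L)
  expect_equal(rhits$orientation, "reverse")
})

test_that("mismatch budget gates planted substitutions", {
  tpl <- build_rrna_template("16S", fwd_sub = 3L, seed = 9L)
  at2 <- find_primer_sites(tpl, "AGRGTTYGATYHTGGCTCAG", 2)
  expect_false(any(at2$position == 1L))
  at4 <- find_primer_sites(tpl, "AGRGTTYGATYHTGGCTCAG", 4)
  hit <- at4[at4$position == 1L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 3L)
})

test_that("primer longer than the chromosome gives an empty result", {
  hits <- find_primer_sites("ACGT", "AGRGTTYGATYHTGGCTCAG", 2)
  expect_equal(nrow(hits), 0L)
})

test_that("predict_amplicons respects the strict product-length window", {
  pair16 <- default_primer_pairs()[["16S"]]
  set.seed(21)
  tpl <- build_rrna_template("16S")
  chrom <- list(id = "c", sequence = paste0(random_dna_oracle(200), tpl,
                                            random_dna_oracle(200)),
                length = 400 + nchar(tpl), topology = "linear")
  amps <- predict_amplicons(chrom, pair16, 0)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, nchar(tpl))
  expect_gt(amps$length, 1000)
  expect_lt(amps$length, 4000)
  expect_equal(amps$strand, "+")

  # sites 900 bp apart: below the exclusive 1000 bp bound
  s <- paste0(random_dna_oracle(50), "AGAGTTTGATCATGGCTCAG",
              random_dna_oracle(900 - 20 - 16),
              revcomp_oracle("TACCTTGTTACGACTT"), random_dna_oracle(50))
  expect_equal(nrow(predict_amplicons(s, pair16, 0)), 0L)

  # no sites at all
  expect_equal(nrow(predict_amplicons(random_dna_oracle(2000), pair16, 0)),
               0L)
})

test_that("amplicon prediction is strand-symmetric", {
  set.seed(33)
  spec <- genome_scenario("ss", data.frame(
    type = c("linked_pair", "single_16S"), its = c(300L, NA),
    strand = c("+", "-")), seed = 14L)
  sim <- simulate_genome(spec)
  chrom <- sim$chromosomes[[1]]
  rc <- list(id = chrom$id, sequence = revcomp(chrom$sequence),
             length = chrom$length, topology = chrom$topology)
  for (tgt in c("16S", "23S")) {
    pair <- default_primer_pairs()[[tgt]]
    a <- predict_amplicons(chrom, pair, 2)
    b <- predict_amplicons(rc, pair, 2)
    key <- function(x) {
      x <- x[order(x$length, x$fwd_mm, x$rev_mm), ]
      x[, c("length", "fwd_mm", "rev_mm")]
    }
    expect_equal(key(a), key(b), ignore_attr = TRUE)
  }
})

test_that("site sets are monotone in the mismatch budget", {
  set.seed(44)
  for (rep in 1:5) {
    s <- random_dna_oracle(1500)
    primer <- paste(sample(names(iupac_sets_oracle), 10, TRUE),
                    collapse = "")
    prev <- NULL
    for (m in 0:3) {
      cur <- find_primer_sites(s, primer, m)
      keyed <- paste(cur$position, cur$orientation)
      if (!is.null(prev)) expect_true(all(prev %in% keyed))
      prev <- keyed
    }
  }
})

test_that("find_primer_sites agrees with the brute-force scan", {
  set.seed(55)
  for (rep in 1:5) {
    s <- random_dna_oracle(sample(200:600, 1))
    primer <- paste(sample(names(iupac_sets_oracle), sample(6:10, 1), TRUE),
                    collapse = "")
    mm <- sample(0:2, 1)
    expect_equal(find_primer_sites(s, primer, mm),
                 brute_force_sites(s, primer, mm))
  }
})

test_that("count_rrna_loci merges at 50% reciprocal overlap", {
  amp <- function(chrom, start, end) {
    data.frame(chrom_id = chrom, target = "16S", start = start, end = end,
               strand = "+", length = end - start + 1L, fwd_mm = 0L,
               rev_mm = 0L, stringsAsFactors = FALSE)
  }
  expect_equal(count_rrna_loci(rbind(amp("c1", 100, 1600),
                                     amp("c1", 100, 1600))), 1L)
  expect_equal(count_rrna_loci(rbind(amp("c1", 100, 1600),
                                     amp("c2", 100, 1600))), 2L)
  # 40% reciprocal overlap: two loci
  expect_equal(count_rrna_loci(rbind(amp("c1", 1, 1000),
                                     amp("c1", 601, 1600))), 2L)
  expect_equal(count_rrna_loci(.empty_loci <- amp("c1", 1, 10)[0, ]), 0L)
  expect_error(count_rrna_loci(rbind(
    amp("c1", 1, 1000),
    transform(amp("c1", 1, 1000), target = "23S"))), "single target")
})

test_that("three well-separated planted 16S genes give three loci", {
  spec <- genome_scenario("tri", data.frame(
    type = rep("single_16S", 3), its = NA), seed = 77L)
  sim <- simulate_genome(spec)
  amps <- predict_amplicons(sim$chromosomes[[1]],
                            default_primer_pairs()[["16S"]], 2)
  expect_equal(count_rrna_loci(amps), 3L)
})
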