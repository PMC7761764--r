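# Operon pairing, ITS arithmetic and genome classification.

test_that("order_features sorts by start with end/type tiebreaks", {
  f <- make_features(list(type = "16S", start = 500, end = 2049),
                     list(type = "23S", start = 100, end = 2999),
                     list(type = "16S", start = 300, end = 1849))
  expect_equal(order_features(f)$start, c(100, 300, 500))
  g <- make_features(list(type = "23S", start = 100, end = 1200),
                     list(type = "16S", start = 100, end = 900))
  expect_equal(order_features(g)$end, c(900, 1200))  # shorter first
})

test_that("its_length handles linear gaps, abutting genes and wraparound", {
  expect_equal(its_length(3503539, 437, "circular", 3504252), 1149L)
  expect_equal(its_length(1000, 1201, "linear", 10000), 200L)
  expect_equal(its_length(1000, 1001, "linear", 10000), 0L)
  expect_equal(its_length(1000, 1201, "circular", 10000), 200L)
  expect_warning(out <- its_length(1000, 900, "linear", 10000), "clamped")
  expect_equal(out, 0L)
  expect_error(its_length(0, 100, "linear", 1000))
})

test_that("sense and antisense adjacency form pairs; wrong contexts do not", {
  topo <- c(chr1 = "circular")
  len <- c(chr1 = 50000)
  sense <- make_features(list(type = "16S", start = 100, end = 1649),
                         list(type = "23S", start = 1850, end = 4749))
  u <- pair_operons(sense, topo, len)
  expect_equal(u$kind, "pair")
  expect_equal(u$its_length, 200L)
  expect_equal(u$linkage, "linked")

  anti <- make_features(
    list(type = "23S", strand = "-", start = 100, end = 2999),
    list(type = "16S", strand = "-", start = 3300, end = 4849))
  u <- pair_operons(anti, topo, len)
  expect_equal(u$kind, "pair")
  expect_equal(u$strand, "-")
  expect_equal(u$its_length, 300L)

  # opposite strands never pair
  cross <- make_features(
    list(type = "16S", strand = "+", start = 100, end = 1649),
    list(type = "23S", strand = "-", start = 1850, end = 4749))
  u <- pair_operons(cross, topo, len)
  expect_equal(sort(u$kind), c("single", "single"))

  # an intervening feature breaks the pair
  inter <- make_features(
    list(type = "16S", start = 100, end = 1649),
    list(type = "16S", start = 2000, end = 3549),
    list(type = "23S", start = 3700, end = 6599))
  u <- pair_operons(inter, topo, len)
  expect_equal(sum(u$kind == "pair"), 1L)
  expect_equal(u$ssu_start[u$kind == "pair"], 2000)
  expect_equal(sum(u$kind == "single"), 1L)
})

test_that("circular chromosomes pair across the origin; linear do not", {
  f <- make_features(list(type = "23S", start = 437, end = 3336),
                     list(type = "16S", start = 3501990, end = 3503539))
  u <- pair_operons(f, c(chr1 = "circular"), c(chr1 = 3504252))
  expect_equal(u$kind, "pair")
  expect_true(u$wrapped)
  expect_equal(u$its_length, 1149L)
  expect_equal(u$linkage, "linked")

  ul <- pair_operons(f, c(chr1 = "linear"), c(chr1 = 3504252))
  expect_equal(sort(ul$kind), c("single", "single"))
})

test_that("pairing never crosses replicons", {
  f <- make_features(
    list(type = "16S", start = 100, end = 1649, chrom = "chr1"),
    list(type = "23S", start = 100, end = 2999, chrom = "chr2"))
  u <- pair_operons(f, c(chr1 = "circular", chr2 = "circular"),
                    c(chr1 = 20000, chr2 = 20000))
  expect_equal(sort(u$kind), c("single", "single"))
})

test_that("classify_unit applies the strict over-1500 rule", {
  mk <- function(its) data.frame(kind = "pair", its_length = its)
  expect_equal(classify_unit(mk(1500L)), "linked")
  expect_equal(classify_unit(mk(1501L)), "unlinked")
  expect_equal(classify_unit(mk(1149L)), "linked")
  expect_error(classify_unit(data.frame(kind = "single",
                                        its_length = NA_integer_)),
               "pairs only")
})

test_that("genome classification follows the unit composition", {
  mk_units <- function(linkages) {
    data.frame(chrom_id = rep("chr1", length(linkages)),
               kind = rep("x", length(linkages)), linkage = linkages,
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_genome(mk_units(rep("linked", 3)))$status, "linked")
  expect_equal(classify_genome(mk_units(c("linked", "unlinked")))$status,
               "mixed")
  expect_equal(classify_genome(mk_units(c("single", "single")))$status,
               "unlinked")
  expect_equal(classify_genome(mk_units(c("linked", "single")))$status,
               "mixed")
  expect_equal(classify_genome(mk_units(character(0)))$status,
               "undetermined")
})

test_that("every feature lands in exactly one unit", {
  set.seed(99)
  for (rep in 1:20) {
    fs <- random_feature_set()
    u <- pair_operons(fs$features, c(chr1 = "circular"),
                      c(chr1 = fs$length))
    expect_equal(2L * sum(u$kind == "pair") + sum(u$kind == "single"),
                 nrow(fs$features))
  }
})

test_that("rotation and strand transforms preserve ITS and genome call", {
  set.seed(123)
  for (rep in 1:10) {
    fs <- random_feature_set()
    base_units <- pair_operons(fs$features, c(chr1 = "circular"),
                               c(chr1 = fs$length))
    base_call <- classify_genome(base_units)
    its0 <- sort(base_units$its_length[base_units$kind == "pair"])

    off <- valid_rotation_offset(fs$features, fs$length)
    rot <- rotate_features(fs$features, fs$length, off)
    ru <- pair_operons(rot, c(chr1 = "circular"), c(chr1 = fs$length))
    expect_equal(sort(ru$its_length[ru$kind == "pair"]), its0)
    expect_equal(classify_genome(ru)$status, base_call$status)

    rc <- revcomp_features(fs$features, fs$length)
    cu <- pair_operons(rc, c(chr1 = "circular"), c(chr1 = fs$length))
    expect_equal(sort(cu$its_length[cu$kind == "pair"]), its0)
    expect_equal(classify_genome(cu)$status, base_call$status)
  }
})
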