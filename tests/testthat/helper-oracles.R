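# Independent oracles and small fixture builders shared across tests.
# Every oracle deliberately uses a different computational route than the
# package implementation it checks.

# Naive per-window IUPAC set-membership primer scan (both orientations).
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

random_dna_oracle <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

brute_force_sites <- function(sequence, primer, max_mm) {
  seq_chars <- strsplit(sequence, "")[[1]]
  out <- list()
  for (ori in c("forward", "reverse")) {
    pc <- strsplit(if (ori == "forward") primer else revcomp_oracle(primer),
                   "")[[1]]
    k <- length(pc)
    if (k > length(seq_chars)) next
    for (p in seq_len(length(seq_chars) - k + 1L)) {
      mm <- 0L
      for (j in seq_len(k)) {
        if (!seq_chars[p + j - 1L] %in% iupac_sets_oracle[[pc[j]]]) {
          mm <- mm + 1L
        }
      }
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          position = p, orientation = ori, mismatches = mm,
          stringsAsFactors = FALSE)
      }
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

# Closed-form Welch/Satterthwaite arithmetic.
welch_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Rank-formula Kruskal-Wallis H with tie correction.
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Direct sum-of-squares one-way F.
anova_f_oracle <- function(values, groups) {
  gm <- mean(values)
  ssb <- sum(tapply(values, groups,
                    function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups))
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Explicit GLS solve from a hand-built Brownian covariance matrix.
pgls_oracle <- function(V, y, x) {
  Vi <- solve(V)
  X <- cbind(1, x)
  C <- solve(t(X) %*% Vi %*% X)
  b <- C %*% t(X) %*% Vi %*% y
  r <- y - X %*% b
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (length(y) - 2)
  se <- sqrt(diag(C) * s2)
  list(intercept = unname(b[1]), slope = unname(b[2]),
       slope_se = unname(se[2]), t = unname(b[2] / se[2]))
}

# Feature table for a genome with no sequence (classification-only tests).
make_features <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom_id = r$chrom %||% "chr1", rna_type = r$type,
               strand = r$strand %||% "+", start = r$start, end = r$end,
               partial = FALSE, source = "annotation",
               stringsAsFactors = FALSE)
  }))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random non-overlapping feature set on one circular chromosome, for
# rotation/strand invariance checks. Uses the current RNG stream.
random_feature_set <- function(n_units = NULL) {
  if (is.null(n_units)) n_units <- sample(1:4, 1)
  pos <- 500L
  rows <- list()
  for (u in seq_len(n_units)) {
    kind <- sample(c("pair+", "pair-", "s16", "s23"), 1)
    its <- sample(c(100L, 800L, 1500L, 1501L, 3000L, 6000L), 1)
    if (kind == "pair+") {
      rows[[length(rows) + 1L]] <- list(type = "16S", strand = "+",
                                        start = pos, end = pos + 1549L)
      pos <- pos + 1550L + its
      rows[[length(rows) + 1L]] <- list(type = "23S", strand = "+",
                                        start = pos, end = pos + 2899L)
      pos <- pos + 2900L
    } else if (kind == "pair-") {
      rows[[length(rows) + 1L]] <- list(type = "23S", strand = "-",
                                        start = pos, end = pos + 2899L)
      pos <- pos + 2900L + its
      rows[[length(rows) + 1L]] <- list(type = "16S", strand = "-",
                                        start = pos, end = pos + 1549L)
      pos <- pos + 1550L
    } else if (kind == "s16") {
      rows[[length(rows) + 1L]] <- list(type = "16S",
                                        strand = sample(c("+", "-"), 1),
                                        start = pos, end = pos + 1549L)
      pos <- pos + 1550L
    } else {
      rows[[length(rows) + 1L]] <- list(type = "23S",
                                        strand = sample(c("+", "-"), 1),
                                        start = pos, end = pos + 2899L)
      pos <- pos + 2900L
    }
    pos <- pos + sample(2000:4000, 1)
  }
  L <- pos + sample(1000:3000, 1)
  feats <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom_id = "chr1", rna_type = r$type, strand = r$strand,
               start = r$start, end = r$end, partial = FALSE,
               source = "annotation", stringsAsFactors = FALSE)
  }))
  list(features = feats, length = L)
}

# Rotation offset that does not split any feature: picked from positions
# where the new origin falls between features.
valid_rotation_offset <- function(features, L) {
  repeat {
    off <- sample.int(L, 1)
    ns <- (features$start - 1L + off) %% L + 1L
    ne <- (features$end - 1L + off) %% L + 1L
    if (all(ne >= ns)) return(off)
  }
}

classify_from_features <- function(features, L, topology = "circular",
                                   its_threshold = 1500L) {
  units <- pair_operons(features, stats::setNames(topology, "chr1"),
                        stats::setNames(L, "chr1"), its_threshold)
  classify_genome(units)
}
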