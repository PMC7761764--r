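# Statistical comparisons between genome classes: rank and mean tests on
# genomic features, paired tests on functional category counts, PCA, and
# phylogenetic generalized least squares under Brownian motion.

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return One-row data.frame: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_t requires at least 2 observations per sample")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("welch_t requires nonzero variance in at least one sample")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Kruskal-Wallis rank sum test with Dunn's post hoc comparisons
#'
#' Tie-corrected H statistic, followed by Dunn z statistics for every
#' group pair with Holm-adjusted two-sided p-values (the adjustment
#' method is echoed in the output).
#'
#' @param values Numeric vector.
#' @param groups Grouping labels, at least 3 levels with n >= 2 each.
#' @param p_adjust Adjustment method for Dunn p-values (default "holm").
#' @return List: `H`, `df`, `p_value`, `comparisons` (data.frame with
#'   `group1`, `group2`, `z`, `p`, `p_adj`), `p_adjust_method`.
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "holm") {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 3L) {
    stop("kruskal_dunn needs >= 3 groups; use welch_t for two groups")
  }
  n_i <- table(groups)
  if (any(n_i < 2L)) stop("each group needs n >= 2")
  kw <- stats::kruskal.test(values, factor(groups))

  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(lev, 2)
  comp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n_i[[a]] + 1 / n_i[[b]]))
    comp$z[k] <- (rbar[[a]] - rbar[[b]]) / se
    comp$p[k] <- 2 * stats::pnorm(-abs(comp$z[k]))
  }
  comp$p_adj <- stats::p.adjust(comp$p, method = p_adjust)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, comparisons = comp,
       p_adjust_method = p_adjust)
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' @param values Numeric vector.
#' @param groups Grouping labels, >= 2 levels with n >= 2 each.
#' @return List: `F`, `df` (c(between, within)), `p_value`, `tukey`
#'   (data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L) stop("anova_tukey needs >= 2 groups")
  if (any(table(g) < 2L)) stop("each group needs n >= 2")
  if (stats::var(values) == 0) {
    # degenerate input: no variation anywhere
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    tk <- data.frame(comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1,
                     stringsAsFactors = FALSE)
    return(list(F = 0, df = c(nlevels(g) - 1L, length(values) - nlevels(g)),
                p_value = 1, tukey = tk))
  }
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = sm[["F value"]][1], df = sm[["Df"]],
       p_value = sm[["Pr(>F)"]][1], tukey = tukey)
}

#' Paired t-tests per functional category
#'
#' Compares mean gene counts of linked vs unlinked genomes category by
#' category, pairing rows (typically phyla: each phylum contributes one
#' linked mean and one unlinked mean).
#'
#' @param table_linked,table_unlinked Numeric matrices or data.frames with
#'   identical row names (pairing units) and column names (categories).
#' @return data.frame: `category`, `mean_linked`, `mean_unlinked`,
#'   `statistic`, `df`, `p_value`. Categories whose paired differences
#'   are constant get NA statistics with a warning (zero differences give
#'   t = 0, p = 1).
#' @export
paired_t_by_category <- function(table_linked, table_unlinked) {
  a <- as.matrix(table_linked)
  b <- as.matrix(table_unlinked)
  if (!identical(colnames(a), colnames(b))) {
    common <- intersect(colnames(a), colnames(b))
    if (length(common) == 0L) stop("tables share no category columns")
    a <- a[, common, drop = FALSE]
    b <- b[, common, drop = FALSE]
  }
  if (!identical(rownames(a), rownames(b))) {
    stop("tables must be paired on identical row names")
  }
  if (nrow(a) < 2L) stop("paired t needs >= 2 pairs")
  rows <- lapply(colnames(a), function(cat) {
    d <- a[, cat] - b[, cat]
    if (stats::var(d) == 0) {
      if (all(d == 0)) {
        stat <- 0; p <- 1; df <- length(d) - 1L
      } else {
        warning("constant nonzero paired difference in category ", cat,
                "; statistic undefined")
        stat <- NA_real_; p <- NA_real_; df <- length(d) - 1L
      }
    } else {
      ht <- stats::t.test(a[, cat], b[, cat], paired = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
      df <- unname(ht$parameter)
    }
    data.frame(category = cat, mean_linked = mean(a[, cat]),
               mean_unlinked = mean(b[, cat]), statistic = stat, df = df,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal component analysis of a feature matrix
#'
#' Columns are standardized (zero mean, unit variance) before the
#' decomposition; constant columns carry no information and are dropped
#' with a warning.
#'
#' @param mat Numeric matrix/data.frame, >= 2 rows and >= 2 non-constant
#'   columns.
#' @param n_components Number of components to keep (default: all).
#' @return List: `scores`, `loadings` (orthonormal), `explained_variance`
#'   (fractions, non-increasing), `dropped` (names of constant columns).
#' @export
pca_features <- function(mat, n_components = NULL) {
  m <- as.matrix(mat)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("pca_features needs >= 2 rows and columns")
  const <- apply(m, 2, function(col) stats::var(col) == 0)
  dropped <- colnames(m)[const]
  if (any(const)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 non-constant columns remain")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  k <- if (is.null(n_components)) ncol(pc$rotation) else
    min(n_components, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)], dropped = dropped)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits `y = intercept + slope * x` with error covariance proportional to
#' the Brownian-motion covariance of the tree: V[i, j] is the shared
#' root-to-ancestor path length of taxa i and j. The slope's standard
#' error comes from the GLS covariance with residual variance estimated
#' on n - 2 degrees of freedom, and the two-sided p-value from the t
#' distribution with n - 2 df.
#'
#' @param tree An `ape::phylo` tree (or path to a Newick file) whose tip
#'   set equals the data's taxa.
#' @param y Named numeric response, one value per tip.
#' @param x Named numeric predictor (e.g. linkage status coded 0/1).
#' @return List of class `pgls_fit`: `slope`, `intercept`, `slope_se`,
#'   `t_stat`, `p_value`, `df`, `sigma2`, `tree_taxa`.
#' @export
pgls_brownian <- function(tree, y, x) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  taxa <- tree$tip.label
  if (is.null(names(y)) || is.null(names(x))) {
    stop("y and x must be named by taxon")
  }
  miss_y <- setdiff(taxa, names(y))
  miss_x <- setdiff(taxa, names(x))
  extra <- setdiff(union(names(y), names(x)), taxa)
  if (length(miss_y) || length(miss_x) || length(extra)) {
    stop("taxa mismatch between tree and data; missing from y: [",
         paste(miss_y, collapse = ", "), "], missing from x: [",
         paste(miss_x, collapse = ", "), "], not in tree: [",
         paste(extra, collapse = ", "), "]")
  }
  y <- y[taxa]
  x <- x[taxa]
  n <- length(taxa)
  if (n < 3L) stop("pgls_brownian needs >= 3 taxa")
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular Brownian covariance matrix (zero-length shared ",
         "branches?): ", conditionMessage(e), call. = FALSE)
  })
  X <- cbind(intercept = 1, slope = as.numeric(x))
  XtVi <- t(X) %*% Vi
  coef_cov_unscaled <- solve(XtVi %*% X)
  b <- coef_cov_unscaled %*% (XtVi %*% as.numeric(y))
  r <- as.numeric(y) - X %*% b
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
  se <- sqrt(diag(coef_cov_unscaled) * sigma2)
  t_stat <- unname(b["slope", 1]) / se[["slope"]]
  structure(list(slope = unname(b["slope", 1]),
                 intercept = unname(b["intercept", 1]),
                 slope_se = se[["slope"]], t_stat = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df = n - 2),
                 df = n - 2L, sigma2 = sigma2, tree_taxa = taxa),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Brownian motion), n =", length(x$tree_taxa), "\n")
  cat(sprintf("  slope     %.6g (SE %.6g)\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  cat(sprintf("  t = %.4g on %d df, p = %.4g\n", x$t_stat, x$df, x$p_value))
  invisible(x)
}
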