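# Statistical procedures against direct-formula and matrix-algebra oracles.

test_that("welch_t matches the Satterthwaite arithmetic oracle", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 3, 4, 5)
  got <- welch_t(x, y)
  ora <- welch_oracle(x, y)
  expect_equal(got$statistic, ora$t, tolerance = 1e-12)
  expect_equal(got$df, ora$df, tolerance = 1e-12)
  expect_equal(got$p_value, ora$p, tolerance = 1e-12)
  # antisymmetry
  rev <- welch_t(y, x)
  expect_equal(rev$statistic, -got$statistic)
  expect_equal(rev$p_value, got$p_value)
  expect_error(welch_t(1, y), "at least 2")
  expect_error(welch_t(c(2, 2), c(2, 2)), "variance")
})

test_that("kruskal_dunn matches the rank-formula oracle and is shift-invariant", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- kruskal_dunn(v, g)
  expect_equal(got$H, 7.2, tolerance = 1e-12)
  expect_equal(got$H, kw_oracle(v, g), tolerance = 1e-12)
  shifted <- kruskal_dunn(v + 100, g)
  expect_equal(shifted$H, got$H)
  expect_equal(shifted$comparisons$z, got$comparisons$z)
  # identical groups: H = 0
  same <- kruskal_dunn(rep(c(5, 6), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(same$H, 0)
  expect_error(kruskal_dunn(1:4, rep(c("a", "b"), 2)), "welch_t")
  # tie-corrected case cross-checked against the oracle
  vt <- c(1, 1, 2, 3, 3, 3, 4, 5, 6)
  expect_equal(kruskal_dunn(vt, g)$H, kw_oracle(vt, g), tolerance = 1e-12)
  # Dunn p-values are Holm-adjusted and within [0,1]
  expect_true(all(got$comparisons$p_adj >= got$comparisons$p))
  expect_true(all(got$comparisons$p_adj >= 0 & got$comparisons$p_adj <= 1))
})

test_that("anova_tukey matches the sum-of-squares oracle", {
  v <- c(2.1, 2.5, 2.3, 3.9, 4.2, 4.0, 6.1, 6.5, 6.0)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- anova_tukey(v, g)
  expect_equal(got$F, anova_f_oracle(v, g), tolerance = 1e-12)
  expect_equal(got$df, c(2L, 6L))
  expect_equal(nrow(got$tukey), 3L)
  # equal-mean groups: F near 0 relative to noise; degenerate exact case
  flat <- anova_tukey(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$F, 0)
  expect_equal(flat$p_value, 1)
  # relabeling permutes pairwise rows only
  relab <- anova_tukey(v, c(a = "z", b = "b", c = "c")[g])
  expect_equal(relab$F, got$F)
  expect_equal(sort(abs(relab$tukey$diff)), sort(abs(got$tukey$diff)))
})

test_that("paired_t_by_category matches the paired-difference oracle", {
  linked <- matrix(c(59, 149, 202), ncol = 1,
                   dimnames = list(c("Campylobacterota", "Spirochaetota",
                                     "Chloroflexota"), "K"))
  unlinked <- matrix(c(32, 75, 99), ncol = 1,
                     dimnames = dimnames(linked))
  got <- paired_t_by_category(linked, unlinked)
  ora <- paired_t_oracle(linked[, 1], unlinked[, 1])
  expect_equal(got$statistic, ora$t, tolerance = 1e-12)
  expect_equal(got$df, ora$df)
  expect_equal(got$p_value, ora$p, tolerance = 1e-12)
  expect_equal(got$mean_linked, mean(c(59, 149, 202)))
  # reversal flips the sign
  revd <- paired_t_by_category(unlinked, linked)
  expect_equal(revd$statistic, -got$statistic)
  # identical tables: t = 0, p = 1
  same <- paired_t_by_category(linked, linked)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t_by_category(linked[1, , drop = FALSE],
                                    unlinked[1, , drop = FALSE]), "2 pairs")
})

test_that("pca_features reproduces the correlation-eigen oracle", {
  # perfectly collinear 2D data: one component carries everything
  m <- cbind(x = 1:10, y = 2 * (1:10) + 3)
  p <- pca_features(m)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(15)
  m2 <- matrix(rnorm(18), nrow = 6, ncol = 3,
               dimnames = list(NULL, c("f1", "f2", "f3")))
  p2 <- pca_features(m2)
  ev_oracle <- eigen(cor(m2))
  expect_equal(p2$explained_variance, ev_oracle$values / 3,
               tolerance = 1e-10)
  z <- scale(m2)
  for (k in 1:3) {
    expect_equal(abs(p2$scores[, k]), abs(as.numeric(z %*% ev_oracle$vectors[, k])),
                 tolerance = 1e-8)
  }
  # completeness: standardized data reconstructed from all components
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(recon, z, tolerance = 1e-10, ignore_attr = TRUE)
  # orthonormal loadings
  expect_equal(t(p2$loadings) %*% p2$loadings, diag(3),
               tolerance = 1e-10, ignore_attr = TRUE)

  m3 <- cbind(m2, const = 5)
  expect_warning(p3 <- pca_features(m3), "constant")
  expect_equal(p3$dropped, "const")
})

test_that("PGLS on a star tree equals ordinary least squares", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(8)
  x <- setNames(rnorm(6), tree$tip.label)
  y <- setNames(2 + 0.7 * x + rnorm(6, sd = 0.3), tree$tip.label)
  fit <- pgls_brownian(tree, y, x)
  ols <- summary(lm(y ~ x))
  expect_equal(fit$slope, ols$coefficients["x", "Estimate"],
               tolerance = 1e-10)
  expect_equal(fit$slope_se, ols$coefficients["x", "Std. Error"],
               tolerance = 1e-10)
  expect_equal(fit$p_value, ols$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("PGLS matches the explicit matrix-algebra oracle on 4 taxa", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:0.5):1);")
  V <- matrix(c(2, 1, 0, 0,
                1, 2, 0, 0,
                0, 0, 2.5, 1,
                0, 0, 1, 1.5), 4, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  y <- setNames(c(3.1, 2.8, 5.2, 4.9), colnames(V))
  x <- setNames(c(0, 0, 1, 1), colnames(V))
  fit <- pgls_brownian(tree, y, x)
  ora <- pgls_oracle(V, y, x)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(fit$slope_se, ora$slope_se, tolerance = 1e-10)
  expect_equal(fit$t_stat, ora$t, tolerance = 1e-10)
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  # nlme's corBrownian carries the correlation structure only, so the
  # cross-check uses an ultrametric tree (equal tip variances)
  set.seed(77)
  tree <- ape::rcoal(8)
  x <- setNames(rnorm(8), tree$tip.label)
  y <- setNames(1 + 0.4 * x + rnorm(8), tree$tip.label)
  fit <- pgls_brownian(tree, y, x)
  df <- data.frame(y = y, x = x, taxon = tree$tip.label)
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(1, phy = tree,
                                                form = ~taxon))
  sm <- summary(g)$tTable
  expect_equal(fit$slope, sm["x", "Value"], tolerance = 1e-6)
  expect_equal(fit$slope_se, sm["x", "Std.Error"], tolerance = 1e-6)
  expect_equal(fit$p_value, sm["x", "p-value"], tolerance = 1e-6)
})

test_that("PGLS is invariant to branch-length scaling and checks taxa", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):0.5);")
  y <- setNames(c(1, 2, 3, 5), c("A", "B", "C", "D"))
  x <- setNames(c(0, 1, 0, 1), c("A", "B", "C", "D"))
  fit1 <- pgls_brownian(tree, y, x)
  tree10 <- tree
  tree10$edge.length <- tree$edge.length * 10
  fit10 <- pgls_brownian(tree10, y, x)
  expect_equal(fit10$slope, fit1$slope, tolerance = 1e-10)
  expect_equal(fit10$t_stat, fit1$t_stat, tolerance = 1e-10)
  expect_error(pgls_brownian(tree, y[c("A", "B", "C")], x), "mismatch")
  expect_error(pgls_brownian(tree, c(y, E = 9), x), "mismatch")
})
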