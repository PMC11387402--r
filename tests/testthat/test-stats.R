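test_that("normality routing picks Welch only when both groups pass", {
  set.seed(21)
  a <- rnorm(50); b <- rnorm(50)
  expect_identical(route_test(a, b), "welch")
  heavy <- exp(rnorm(50, sd = 2))
  expect_identical(route_test(a, heavy), "mann_whitney")
  expect_warning(r <- route_test(c(1, 2), b), "n < 3")
  expect_identical(r, "mann_whitney")
})

test_that("Welch matches the formula oracle to 1e-10", {
  a <- c(4.1, 5.2, 6.3, 5.5, 4.9, 7.0)
  b <- c(3.2, 3.9, 4.4, 3.1, 5.0)
  got <- welch_t(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  # constant equal groups: statistic 0, p 1
  z <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_identical(z$statistic, 0)
  expect_identical(z$p, 1)
})

test_that("Mann-Whitney uses the exact null for small untied samples", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p, 0.1)
  expect_equal(got$p, oracle_mwu_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mann_whitney(c(1, 1, 1), c(1, 1, 1))$p, 1)
  # normal approximation close to exact enumeration at n = 8, no ties
  set.seed(9)
  for (i in 1:5) {
    a <- sample(seq(1, 100), 8)
    b <- sample(seq(101, 200), 8) / 1.9
    p_exact <- mann_whitney(a, b, exact = TRUE)$p
    p_norm <- mann_whitney(a, b, exact = FALSE)$p
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("Kruskal-Wallis + Dunn: oracle statistic, family size, guards", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_gt(kruskal_dunn(same)$p, 0.99)
  set.seed(4)
  apart <- list(a = rnorm(10), b = rnorm(10, 6), c = rnorm(10, 12))
  kd <- kruskal_dunn(apart)
  expect_lt(kd$p, 0.01)
  expect_equal(kd$statistic, oracle_kw_stat(apart), tolerance = 1e-12)
  expect_identical(nrow(kd$pairwise), 3L) # k(k-1)/2
  four <- c(apart, list(d = rnorm(10, 20)))
  expect_identical(nrow(kruskal_dunn(four)$pairwise), 6L)
  # a pairwise Dunn z of far-apart groups is significant after adjustment
  expect_lt(kd$pairwise$p_adj[kd$pairwise$group_a == "a" &
                                kd$pairwise$group_b == "c"], 0.05)
  expect_error(kruskal_dunn(same[1:2]), "two-group")
})

test_that("multiplicity adjustments: hand oracles and monotonicity", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_p(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  expect_equal(adjust_p(0.03, "BH"), 0.03)
  set.seed(14)
  p <- runif(40)
  adj <- adjust_p(p, "BH")
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p & adj <= 1))
  # monotone in the raw-p ordering, invariant to permutation
  o <- order(p)
  expect_true(!is.unsorted(adj[o]))
  perm <- sample(40)
  expect_equal(adjust_p(p[perm], "BH"), adj[perm])
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change is the mean ratio, antisymmetric on the log scale", {
  # group means like the published CALD vs noCALD>55 comparison
  a <- c(601, 601); b <- c(269, 269)
  fc <- fold_change(a, b)
  expect_equal(fc$fc, 601 / 269)
  expect_gt(fc$fc, 2.22); expect_lt(fc$fc, 2.24)
  expect_identical(fold_change(a, a)$log2fc, 0)
  expect_equal(fold_change(b, a)$log2fc, -fc$log2fc)
  expect_warning(z <- fold_change(a, c(0, 0)), "reference")
  expect_true(is.na(z$fc))
})

test_that("correlations match hand-computed rank and product-moment", {
  x <- 1:10
  expect_equal(correlate(x, x + 3, "spearman")$estimate, 1)
  expect_equal(correlate(x, -x, "pearson")$estimate, -1)
  set.seed(2)
  u <- rnorm(10); v <- u + rnorm(10)
  expect_equal(correlate(u, v, "spearman")$estimate,
               oracle_spearman(u, v), tolerance = 1e-12)
  expect_warning(z <- correlate(rep(1, 5), 1:5), "variance")
  expect_true(is.na(z$estimate))
})

test_that("volcano classification on planted fold changes", {
  set.seed(31)
  planted <- c(3.0, 2.0, 1.2, 0.4, 1.0)
  n <- 20
  ab <- tibble::tibble(lipid = sprintf("LPC(2%d:0)", seq_along(planted)))
  for (j in 1:n) ab[[paste0("a", j)]] <- planted * exp(rnorm(5, 0, 0.05))
  for (j in 1:n) ab[[paste0("b", j)]] <- exp(rnorm(5, 0, 0.05))
  v <- volcano(ab, paste0("a", 1:n), paste0("b", 1:n))
  counts <- attr(v, "counts")
  expect_identical(unname(counts), c(2L, 1L))
  expect_identical(v$label[1:2], c("elevated", "elevated"))
  expect_identical(v$label[4], "lower")
  # identical strata: nothing called
  v0 <- volcano(ab, paste0("a", 1:n), paste0("a", 1:n))
  expect_identical(unname(attr(v0, "counts")), c(0L, 0L))
  # degenerate thresholds on separable data: everything non-ns
  v1 <- volcano(ab[c(1, 2, 4), ], paste0("a", 1:n), paste0("b", 1:n),
                fc_thresh = 1, p_thresh = 1)
  expect_true(all(v1$label != "ns"))
  g <- glance(v)
  expect_identical(g$n_elevated, 2L)
  expect_identical(g$n_tested, 5L)
})

test_that("comparisons are invariant to row and column order", {
  set.seed(44)
  ab <- tibble::tibble(lipid = sprintf("PC(%d:0)", 30:39))
  for (s in c(paste0("x", 1:8), paste0("y", 1:8))) {
    ab[[s]] <- exp(rnorm(10, 0, 0.3))
  }
  r1 <- compare_lipids(ab, paste0("x", 1:8), paste0("y", 1:8))
  perm_rows <- sample(10)
  perm_a <- sample(paste0("x", 1:8))
  r2 <- compare_lipids(ab[perm_rows, c("lipid", perm_a, paste0("y", 1:8))],
                       perm_a, paste0("y", 1:8))
  expect_equal(tidy(r2), tidy(r1)[perm_rows, ])
})

test_that("PCA conserves variance; PLS-DA separates planted groups", {
  set.seed(6)
  ab <- tibble::tibble(lipid = sprintf("PC(%d:0)", 30:49))
  for (s in paste0("g1_", 1:6)) ab[[s]] <- exp(rnorm(20, 1, 0.2))
  for (s in paste0("g2_", 1:6)) ab[[s]] <- exp(rnorm(20, -1, 0.2))
  p <- pca_scores(ab)
  expect_equal(sum(p$explained_variance), 1)
  # duplicated samples get identical scores
  ab_dup <- ab
  ab_dup$g1_dup <- ab_dup$g1_1
  pd <- pca_scores(ab_dup)
  expect_equal(unlist(pd$scores[pd$scores$sample == "g1_dup", -1]),
               unlist(pd$scores[pd$scores$sample == "g1_1", -1]))
  # rank-1 construction: PC1 carries essentially all variance
  load_vec <- seq(0.1, 2, length.out = 20)
  score_vec <- seq(-3, 3, length.out = 12)
  rank1 <- tibble::tibble(lipid = ab$lipid)
  for (j in seq_along(score_vec)) {
    rank1[[paste0("s", j)]] <- exp(load_vec * score_vec[j])
  }
  p1 <- pca_scores(rank1)
  expect_gte(p1$explained_variance[1], 0.999)
  labels <- rep(c("g1", "g2"), each = 6)
  pl <- plsda_scores(ab, labels)
  expect_identical(nrow(pl$scores), 12L)
  # planted group separation shows on component 1
  c1 <- split(pl$scores$comp1, labels)
  expect_true(max(c1$g1) < min(c1$g2) || min(c1$g1) > max(c1$g2))
})
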