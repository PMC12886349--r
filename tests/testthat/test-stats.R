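test_that("paired Wilcoxon handles exact small-sample and degenerate cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  # all-positive differences at n = 6: smallest attainable two-sided p = 2/64
  w <- paired_wilcoxon(x, x + 1)
  expect_equal(w$p_value, 2 / 2^6)
  expect_gt(w$effect_r, 0)
  # identical vectors are flagged degenerate
  d <- paired_wilcoxon(x, x)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_equal(d$effect_r, 0)
  expect_error(paired_wilcoxon(1:4, 2:5), "at least 6")
  expect_error(paired_wilcoxon(1:6, 1:5), "equal length")
})

test_that("paired Wilcoxon detects a 1 SD shift essentially always at n = 96", {
  rej <- sapply(1:200, function(i) {
    set.seed(6000 + i)
    a <- rnorm(96)
    paired_wilcoxon(a, a + 1 + rnorm(96))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.99)
})

test_that("BH adjustment is block-wise, monotone and order-preserving", {
  expect_equal(bh_fdr(0.03), 0.03) # single p unchanged
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # blocks are adjusted independently
  p <- c(0.01, 0.02, 0.03, 0.04, 0.01, 0.02, 0.03, 0.04)
  blocks <- rep(c("a", "b"), each = 4)
  expect_equal(bh_fdr(p, blocks), rep(0.04, 8))
  set.seed(61)
  q <- runif(20)
  adj <- bh_fdr(q)
  expect_true(all(adj >= q))
  expect_equal(order(adj[order(q)]), 1:20) # within-block ordering preserved
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  x <- c(0.3, 1.2, 0.8, 2.5, 1.9, 0.1)
  y <- c(2, 5, 3, 6, 4, 1)
  rho <- cor(x, y, method = "spearman")
  perms <- gtools_permutations6()
  exact <- mean(apply(perms, 1, function(pp) {
    abs(cor(rank(x), rank(y)[pp])) >= abs(rho) - 1e-12
  }))
  r <- spearman_perm_boot(x, y, n_perm = 10000, n_boot = 200, seed = 1)
  expect_lt(abs(r$p_perm - exact), 0.01)
  expect_gte(r$p_perm, 1 / 10001)
})

test_that("permutation p is invariant to monotone transforms of either variable", {
  set.seed(62)
  x <- rnorm(12)
  y <- rnorm(12)
  r1 <- spearman_perm_boot(x, y, n_perm = 2000, n_boot = 100, seed = 5)
  r2 <- spearman_perm_boot(exp(x), y^3 + 10 * y, n_perm = 2000, n_boot = 100, seed = 5)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p_perm, r2$p_perm)
})

test_that("permutation test holds its nominal type-I error at n = 15", {
  rej <- sapply(1:500, function(i) {
    set.seed(7000 + i)
    spearman_perm_boot(rnorm(15), rnorm(15),
      n_perm = 200, n_boot = 10,
      seed = 7000 + i
    )$p_perm < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("bootstrap interval brackets the point estimate and perfect ranks give rho = 1", {
  set.seed(63)
  x <- rnorm(20)
  y <- x + rnorm(20, sd = 0.5)
  r <- spearman_perm_boot(x, y, n_perm = 500, n_boot = 2000, seed = 9)
  expect_gte(r$rho, r$ci[1])
  expect_lte(r$rho, r$ci[2])
  rp <- spearman_perm_boot(1:10, (1:10)^2, n_perm = 200, n_boot = 100, seed = 2)
  expect_equal(rp$rho, 1)
  expect_error(spearman_perm_boot(rep(1, 10), rnorm(10)), "constant")
})

test_that("deviance-clinical correlation emits one FDR-adjusted row per pair", {
  sp <- ref_space()
  fm <- ref_cohort()
  pat <- gen_cohort_features(tdc_cohort_spec(15, seed = 5), cohort = "patient")
  pat <- match_ages_to_reference(pat, fm, seed = 8)
  dv <- deviance_table(sp, fm, pat)
  # clinical axis constructed as a monotone function of one pair's distances
  sub <- dv[dv$pc_pair == "PC1-PC2", ]
  clin <- setNames(rank(sub$md_global), sub$subject)
  res <- correlate_deviance_clinical(dv, clin,
    distance = "global",
    n_perm = 500, n_boot = 200, seed = 3
  )
  expect_equal(nrow(res), 10)
  expect_equal(res$rho[res$pc_pair == "PC1-PC2"], 1)
  expect_true(res$significant[res$pc_pair == "PC1-PC2"])
  expect_true(all(res$p_fdr >= res$p_perm - 1e-12))
  expect_error(
    correlate_deviance_clinical(dv, clin[-1], distance = "global", n_perm = 10, n_boot = 10),
    "without clinical scores"
  )
})
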