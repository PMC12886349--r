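test_that("the additive severity rubric follows its worked arithmetic", {
  expect_equal(severity_rank(character(0)), 1L)
  expect_equal(severity_rank(c("epileptiform_discharge", "slow_pdr")), 8L)
  # duplicates and same-category aliases count once
  expect_equal(severity_rank(c("focal_transient", "focal_transient")), 2L)
  expect_equal(severity_rank(c("slow_pdr", "burst_suppression")), 5L)
  expect_error(severity_rank("spindles"), "unknown")
  # monotone: adding an abnormality never decreases the rank
  cats <- names(severity_rubric())
  for (k in 1:3) {
    expect_lte(severity_rank(cats[1:k]), severity_rank(cats[1:(k + 1)]))
  }
  # the packaged category sets reproduce the published rank where marked
  ab <- snare_eeg_abnormalities()
  for (i in which(ab$rank_reproducible)) {
    cats_i <- strsplit(ab$categories[i], ";")[[1]]
    expect_equal(severity_rank(cats_i[nzchar(cats_i)]), ab$published_rank[i])
  }
})

test_that("rank-based clinical PCA reproduces the published cohort structure", {
  cp <- clinical_pca(clinical_table())
  expect_equal(sum(cp$explained_pct[1:2]), 95.3, tolerance = 0.2)
  expect_equal(cp$explained_pct[1], 81.6, tolerance = 0.2)
  expect_equal(cp$explained_pct[2], 13.7, tolerance = 0.2)
  expect_equal(sum(cp$eigenvalues), 5, tolerance = 1e-9)
  expect_equal(sum(cp$explained_pct), 100, tolerance = 1e-9)
  # sign anchors: motor severity loads positively on PC1, EEG severity
  # negatively on PC2; adaptive functioning opposes PC1
  expect_gt(cp$loadings["gmfcs", 1], 0)
  expect_lt(cp$loadings["vineland_abc", 1], 0)
  expect_lt(cp$loadings["eeg_severity", 2], 0)
})

test_that("the clinical pipeline is invariant to monotone rescaling of scales", {
  tab <- clinical_table()
  cp <- clinical_pca(tab)
  warped <- tab
  warped$vineland_abc <- exp(warped$vineland_abc / 20) # strictly increasing
  warped$gmfcs <- warped$gmfcs^3
  warped$eeg_severity <- 10 * warped$eeg_severity + 2
  cp2 <- clinical_pca(warped)
  expect_equal(cp2$eigenvalues, cp$eigenvalues, tolerance = 1e-12)
  expect_equal(cp2$scores, cp$scores, tolerance = 1e-12)
  # flipping a scale's direction leaves the eigenvalues unchanged
  flipped <- tab
  flipped$macs <- -flipped$macs
  expect_equal(clinical_pca(flipped)$eigenvalues, cp$eigenvalues, tolerance = 1e-12)
})

test_that("identical rankings give a duplicate Spearman pair with rho = 1", {
  set.seed(51)
  tab <- data.frame(
    vineland_abc = sample(30:90, 12),
    gmfcs = sample(1:5, 12, replace = TRUE),
    macs = sample(1:5, 12, replace = TRUE),
    cfcs = sample(1:5, 12, replace = TRUE),
    eeg_severity = sample(1:8, 12, replace = TRUE)
  )
  tab$macs <- rank(tab$gmfcs) # identical ranking to gmfcs
  cp <- clinical_pca(tab)
  expect_equal(cp$correlation["gmfcs", "macs"], 1)
  expect_error(clinical_pca(transform(tab, cfcs = 3)), "constant")
})

test_that("adequacy diagnostics reproduce the published cohort values", {
  cp <- clinical_pca(clinical_table())
  expect_equal(cp$kmo, 0.83, tolerance = 0.01)
  expect_equal(cp$bartlett$chisq, 62.35, tolerance = 0.5)
  expect_lt(cp$bartlett$p_value, 0.05)
  expect_equal(cp$bartlett$df, 10)
  # identity correlation: chi2 exactly zero
  expect_equal(bartlett_sphericity(diag(5), 15)$chisq, 0)
  expect_error(kmo(matrix(1, 3, 3)), "singular")
})

test_that("variance-standardized clinical distance follows its closed form", {
  cp <- clinical_pca(clinical_table())
  md <- clinical_md(cp)
  expect_true(all(md >= 0))
  expect_equal(
    unname(md[1]),
    sqrt(cp$scores[1, 1]^2 / cp$eigenvalues[1] + cp$scores[1, 2]^2 / cp$eigenvalues[2])
  )
  # hand cases on raw scores
  expect_equal(unname(clinical_md(matrix(c(sqrt(2), 0), 1), eigenvalues = c(2, 0.5))), 1)
  expect_equal(
    unname(clinical_md(matrix(c(1, 1), 1), eigenvalues = c(2, 0.5))),
    sqrt(0.5 + 2)
  )
  expect_error(clinical_md(matrix(1, 1, 2), eigenvalues = c(1, 0)), "positive")
})
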