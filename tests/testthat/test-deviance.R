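test_that("MCD center is accurate on clean data and robust to gross outliers", {
  set.seed(41)
  clean <- matrix(rnorm(1000), 500, 2)
  ctr <- fit_mcd(clean)
  expect_lt(sqrt(sum(ctr$center^2)), 0.1) # within 0.1 SD of the true mean
  # 10% contamination at 10 SD barely moves the center
  contam <- clean
  contam[1:50, ] <- contam[1:50, ] + 10
  ctr2 <- fit_mcd(contam)
  expect_lt(sqrt(sum((ctr2$center - ctr$center)^2)), 0.2)
  expect_error(fit_mcd(matrix(rnorm(8), 4, 2)), "at least 5")
  # deterministic under its seed
  expect_identical(fit_mcd(clean, seed = 3)$center, fit_mcd(clean, seed = 3)$center)
})

test_that("Mahalanobis distance matches closed forms and a brute-force oracle", {
  id <- list(center = c(0, 0), cov = diag(2))
  expect_equal(mahal_dist(c(0, 0), id), 0)
  expect_equal(mahal_dist(c(3, 4), id), 5)
  anis <- list(center = c(0, 0), cov = matrix(c(4, 0, 0, 1), 2))
  expect_equal(mahal_dist(c(2, 1), anis), sqrt(2))
  # equivalence with explicit matrix inversion on random SPD matrices
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    S <- crossprod(A) + 0.1 * diag(2)
    u <- rnorm(2)
    x <- matrix(rnorm(20), 10, 2)
    oracle <- sqrt(mahalanobis(x, u, S)) # stats::mahalanobis inverts S itself
    expect_equal(mahal_dist(x, list(center = u, cov = S)), unname(oracle), tolerance = 1e-10)
  }
  expect_error(mahal_dist(c(1, 1), list(center = c(0, 0), cov = matrix(1, 2, 2))), "singular")
})

test_that("distances are invariant under invertible affine maps of the scores", {
  set.seed(43)
  scores <- matrix(rnorm(192), 96, 2)
  ctr <- fit_mcd(scores)
  md <- mahal_dist(scores, ctr)
  A <- matrix(c(2, 0.5, -1, 3), 2)
  b <- c(5, -2)
  tr <- sweep(scores %*% t(A), 2, b, "+")
  ctr_t <- list(center = drop(A %*% ctr$center) + b, cov = A %*% ctr$cov %*% t(A))
  expect_equal(mahal_dist(tr, ctr_t), md, tolerance = 1e-10)
})

test_that("jackknife excludes each subject from its own reference", {
  set.seed(44)
  scores <- matrix(rnorm(60), 30, 2)
  # a subject duplicated at the center of the others has ~zero distance
  center_pt <- matrix(apply(scores, 2, mean), 1)
  aug <- rbind(scores, center_pt)
  jk <- jackknife_md(aug)
  expect_lt(jk[31], quantile(jk[1:30], 0.2))
  # jackknife distances weakly exceed plain distances on average
  plain <- mahal_dist(aug, fit_mcd(aug))
  expect_gte(mean(jk), mean(plain) - 1e-9)
  expect_error(jackknife_md(scores[1:5, ]), "at least 6")
})

test_that("jackknifed squared distances are roughly chi-square(2) distributed", {
  set.seed(45)
  scores <- matrix(rnorm(192), 96, 2)
  jk <- jackknife_md(scores)
  # MCD support inflates tails slightly; compare at a loose KS tolerance
  ks <- suppressWarnings(ks.test(jk^2, "pchisq", df = 2))
  expect_gt(ks$p.value, 0.001)
  expect_lt(unname(ks$statistic), 0.2)
})

test_that("age-matched centers track local structure and never widen silently", {
  set.seed(46)
  n <- 200
  ages <- runif(n, 4, 18)
  # strong linear age trend in scores
  scores <- cbind(2 * (ages - 11) + rnorm(n, sd = 0.5), rnorm(n, sd = 0.5))
  young <- which.min(abs(ages - 6))
  res <- age_matched_md(scores[young, ], ages[young], scores, ages, window = 1, min_n = 10)
  glob <- mahal_dist(scores[young, ], fit_mcd(scores))
  # an age-typical subject far from the global center is near its age-matched one
  expect_lt(res$md, glob)
  expect_gte(res$n_support, 10)
  expect_error(
    age_matched_md(scores[young, ], 30, scores, ages, window = 1, min_n = 10),
    "only 0 reference"
  )
  # a window covering everyone reproduces the global support
  res_all <- age_matched_md(scores[young, ], ages[young], scores, ages, window = 100, min_n = 10)
  expect_equal(res_all$md, unname(glob), tolerance = 1e-9)
})

test_that("the deviance table covers every pair and both distance kinds", {
  sp <- ref_space()
  fm <- ref_cohort()
  pat <- gen_cohort_features(tdc_cohort_spec(12, seed = 5), cohort = "patient")
  pat <- match_ages_to_reference(pat, fm, seed = 8)
  dv <- deviance_table(sp, fm, pat, pairs = pc_pairs(5)[1:3, ])
  expect_equal(nrow(dv), 3 * 12)
  expect_true(all(dv$md_global >= 0))
  expect_true(all(dv$md_age >= 0))
  expect_true(all(dv$n_support_age >= 10))
})

test_that("eyes-closed boosts push most subjects away from the eyes-open center", {
  rp <- relpower_cohort()
  pr <- gen_state_pair(rp, alpha_boost = 2, theta_boost = 1.2)
  sp <- normative_space(rp)
  e1 <- predict(sp, pr$eor, pair = c(1, 2))
  e2 <- predict(sp, pr$ecr, pair = c(1, 2))
  ctr <- fit_mcd(e1)
  prop <- mean(mahal_dist(e2, ctr) > mahal_dist(e1, ctr))
  expect_gt(prop, 0.5)
})
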