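test_that("robust scaler centers the reference and freezes its parameters", {
  fm <- ref_cohort()
  sc <- fit_scaler(fm)
  Xs <- apply_scaler(sc, fm)
  expect_equal(unname(apply(Xs, 2, median)), rep(0, 35), tolerance = 1e-12)
  expect_equal(unname(apply(Xs, 2, IQR)), rep(1, 35), tolerance = 1e-12)
  # a patient row equal to a reference row scales identically
  X <- feature_values(fm)
  expect_equal(apply_scaler(sc, X[5, , drop = FALSE]), Xs[5, , drop = FALSE])
  # shifting one reference feature by c moves scaled patient values by -c/IQR
  shifted <- X
  shifted[, 3] <- shifted[, 3] + 2
  sc2 <- fit_scaler(shifted)
  expect_equal(
    unname(apply_scaler(sc2, X[1, , drop = FALSE])[, 3]),
    unname(apply_scaler(sc, X[1, , drop = FALSE])[, 3] - 2 / sc$scale[3])
  )
  const <- X
  const[, 2] <- 1
  expect_error(fit_scaler(const), "interquartile")
})

test_that("sparse PCA converges to classical PCA as sparsity vanishes", {
  fm <- ref_cohort()
  sp0 <- normative_space(fm, sparsity = 0)
  Xs <- apply_scaler(sp0$scaler, feature_values(fm))
  pc <- prcomp(Xs, center = TRUE, scale. = FALSE)
  cs <- abs(colSums(sp0$loadings * pc$rotation[, 1:5]))
  expect_true(all(cs > 0.99))
})

test_that("sparse PCA recovers planted disjoint supports", {
  L <- matrix(0, 35, 2)
  L[1:5, 1] <- 1 / sqrt(5)
  L[6:10, 2] <- 1 / sqrt(5)
  fm <- gen_cohort_features(cohort_spec(300, L, comp_var = c(10, 5), noise_var = 0.1, seed = 4))
  sp <- normative_space(fm, n_components = 2, sparsity = 3)
  supports <- apply(coef(sp) != 0, 2, which, simplify = FALSE)
  expect_setequal(lapply(supports, unname), list(1:5, 6:10))
})

test_that("the default space is sparse, ordered, and captures > 70% variance", {
  sp <- ref_space()
  zeros <- mean(coef(sp) == 0)
  expect_gt(zeros, 0.3)
  expect_lt(zeros, 0.6)
  expect_true(all(diff(sp$explained_variance) <= 1e-12))
  expect_gt(max(sp$cumulative_variance), 0.7)
  expect_true(all(sp$explained_variance > 0 & sp$explained_variance <= 1))
})

test_that("fitting uses the reference only: patient rows cause no leakage", {
  fm <- ref_cohort()
  sp <- ref_space()
  pat <- gen_cohort_features(tdc_cohort_spec(15, seed = 5), cohort = "patient")
  # refit on reference alone after 'seeing' patients changes nothing
  sp2 <- normative_space(fm)
  expect_identical(coef(sp), coef(sp2))
  expect_identical(predict(sp, pat), predict(sp2, pat))
})

test_that("projection is affine, pair-restricted and error-checked", {
  sp <- ref_space()
  fm <- ref_cohort()
  X <- feature_values(fm)
  # a row at the reference feature-space median projects to the score origin
  med <- matrix(sp$scaler$center, 1)
  colnames(med) <- sp$features
  expect_equal(unname(drop(predict(sp, med))), rep(0, 5), tolerance = 1e-12)
  # affine: predict(a*x + b*y) relates linearly
  a <- X[1, , drop = FALSE]
  b <- X[2, , drop = FALSE]
  mid <- (a + b) / 2
  expect_equal(predict(sp, mid), (predict(sp, a) + predict(sp, b)) / 2, tolerance = 1e-10)
  expect_equal(nrow(pc_pairs(5)), 10)
  expect_equal(nrow(pc_pairs(3)), 3)
  expect_equal(ncol(predict(sp, fm, pair = c(1, 3))), 2)
  expect_error(predict(sp, fm, pair = c(2, 2)), "distinct")
  expect_error(normative_space(feature_values(fm)[1:20, ]), "must exceed")
})
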