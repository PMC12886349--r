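test_that("parcel time-series generator is deterministic and validates its spec", {
  spec <- signal_spec(n_parcels = 2, duration = 20, dfa_exponents = c(
    delta = 0.5, theta = 0.5, alpha = 0.5, beta = 0.5, beta_gamma = 0.5
  ), seed = 7)
  a <- gen_parcel_timeseries(spec)
  b <- gen_parcel_timeseries(spec)
  expect_identical(a$signals, b$signals)
  expect_error(signal_spec(rel_power = c(delta = 0.9, theta = 0.3, alpha = 0, beta = 0, beta_gamma = 0)), "sum")
  expect_error(signal_spec(fs = 60), "twice the highest band edge")
  expect_warning(
    gen_parcel_timeseries(signal_spec(n_parcels = 1, duration = 30, seed = 1)),
    "100 s"
  )
})

test_that("planted spectral power and LRTC exponents are recovered from generated signals", {
  spec <- signal_spec(
    n_parcels = 1, duration = 180,
    rel_power = c(delta = 0.1, theta = 0.1, alpha = 0.6, beta = 0.05, beta_gamma = 0.05),
    dfa_exponents = c(delta = 0.5, theta = 0.5, alpha = 0.8, beta = 0.5, beta_gamma = 0.5),
    seed = 42
  )
  sim <- gen_parcel_timeseries(spec)
  bp <- band_powers(welch_psd(sim$signals[1, ], sim$fs))
  alpha_rel <- sum(bp$relative_pct[bp$band == "alpha"]) / 100
  expect_lt(abs(alpha_rel - 0.6), 0.05)
  env <- amplitude_envelope(sim$signals[1, ], sim$fs, band_scheme()$band_edges$alpha)
  expect_lt(abs(dfa(env, sim$fs)$exponent - 0.8), 0.08)
})

test_that("cohort feature generator plants covariance, rank and age structure", {
  L <- matrix(0, 35, 2)
  L[1:5, 1] <- 1 / sqrt(5)
  L[6:10, 2] <- 1 / sqrt(5)
  spec <- cohort_spec(500, L, comp_var = c(4, 2), noise_var = 0.2, seed = 9)
  fm <- gen_cohort_features(spec)
  X <- feature_values(fm)
  expect_identical(X, feature_values(gen_cohort_features(spec)))
  emp <- cov(X)
  theo <- L %*% diag(c(4, 2)) %*% t(L) + 0.2 * diag(35)
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.2)
  # zero noise, one component -> rank-1 covariance
  fm1 <- gen_cohort_features(cohort_spec(50, L[, 1, drop = FALSE],
    comp_var = 4,
    noise_var = 0, seed = 3
  ))
  expect_equal(sum(eigen(cov(feature_values(fm1)))$values > 1e-8), 1)
  expect_error(cohort_spec(10, L, comp_var = c(0, 1)), "positive")
})

test_that("state pairs renormalise relative power and preserve pairing", {
  rp <- relpower_cohort()
  # unit boosts leave the cohort untouched
  same <- gen_state_pair(rp, alpha_boost = 1, theta_boost = 1)
  expect_equal(feature_values(same$ecr), feature_values(rp), tolerance = 1e-12)
  pr <- gen_state_pair(rp, alpha_boost = 2, theta_boost = 1.3)
  for (st in pr) {
    X <- feature_values(st)
    for (net in network_labels()) {
      sums <- rowSums(X[, grep(paste0("_", net, "$"), colnames(X))])
      expect_equal(unname(sums), rep(100, nrow(X)), tolerance = 1e-9)
    }
  }
  # boosted alpha shares are larger in the eyes-closed member of each pair
  a_cols <- grep("^alpha_", colnames(feature_values(rp)))
  expect_true(all(feature_values(pr$ecr)[, a_cols] > feature_values(pr$eor)[, a_cols]))
  expect_error(gen_state_pair(rp, alpha_boost = 0), "positive")
})

test_that("ordinal clinical cohorts follow the latent copula correlation", {
  spec0 <- clinical_cohort_spec(2000, latent_corr = diag(5), seed = 5)
  tab0 <- gen_clinical_cohort(spec0)
  r0 <- cor(as.matrix(tab0[, -1]), method = "spearman")
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)
  # strong latent correlation between two many-level scales
  r <- diag(5)
  r[1, 2] <- r[2, 1] <- 0.9
  dimnames(r) <- dimnames(default_clinical_corr())
  tab <- gen_clinical_cohort(clinical_cohort_spec(2000, latent_corr = r, seed = 6))
  implied <- 6 / pi * asin(0.9 / 2) # large-sample Spearman of a bivariate Gaussian
  expect_equal(cor(tab[[2]], tab[[3]], method = "spearman"), implied, tolerance = 0.1)
  # all outputs stay within the declared level sets
  sc <- default_clinical_scales()
  for (nm in names(sc)) expect_true(all(tab0[[nm]] %in% sc[[nm]]$levels))
  bad <- diag(5)
  bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(clinical_cohort_spec(10, latent_corr = bad), "eigenvalue")
})
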