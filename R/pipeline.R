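# End-to-end orchestration: synthetic cohorts -> normative spaces ->
# deviances -> clinical severity axes -> deviance-clinical correlations,
# with a manifest for provenance.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with defaults mirroring the
#' study-design constants: 5 sparse components at sparsity 1.5, a +/- 12
#' month age window with minimum support 10, and 15000 permutations and
#' bootstraps at alpha 0.05. All randomness flows from `seed` via fixed
#' per-stage offsets.
#'
#' @param n_reference reference cohort size
#' @param n_patients patient cohort size
#' @param n_components,sparsity sparse-PCA options
#' @param age_window,min_n age-matching controls (years, minimum support)
#' @param n_perm,n_boot,alpha statistics options
#' @param alpha_boost,theta_boost eyes-closed state boosts for the paired
#'   relative-power validation
#' @param seed master seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(n_reference = 96, n_patients = 15, n_components = 5,
                            sparsity = 1.5, age_window = 1, min_n = 10,
                            n_perm = 15000, n_boot = 15000, alpha = 0.05,
                            alpha_boost = 1.6, theta_boost = 1.2, seed = 42L) {
  cfg <- list(
    n_reference = n_reference, n_patients = n_patients,
    n_components = n_components, sparsity = sparsity,
    age_window = age_window, min_n = min_n,
    n_perm = n_perm, n_boot = n_boot, alpha = alpha,
    alpha_boost = alpha_boost, theta_boost = theta_boost,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  b <- as.integer(charToRaw(s))
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages end to end on synthetic data: (1) simulate reference,
#' state-pair and patient feature cohorts for the three biomarkers (absolute
#' power, relative power, LRTC); (2) fit one normative space per biomarker
#' on the reference eyes-open data; (3) tabulate global and age-matched
#' Mahalanobis deviances for the patients over all component pairs; (4)
#' simulate an ordinal clinical cohort and fit the rank-based clinical PCA;
#' (5) correlate deviances with both clinical axes for both distance kinds,
#' yielding 3 biomarkers x 10 pairs x 2 distances x 2 axes = 120
#' correlation rows with within-block FDR. Patient features are drawn from
#' the reference-generating process plus a deviation whose direction and
#' magnitude are free parameters of the generator, not fixed by the study
#' design.
#'
#' Identical configuration and seed give byte-identical outputs; when
#' `out_dir` is supplied, result CSVs and a JSON manifest (config, seeds,
#' stage log, config hash) are written there.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory for CSVs and the manifest
#' @return invisibly, a list with `features`, `spaces`, `deviance`,
#'   `clinical`, `correlations`, `state_contrast`, `manifest`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- config$seed + c(
    simulate = 101L, patients = 202L, clinical = 303L,
    mcd = 404L, stats = 505L
  )
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  # -- simulate ---------------------------------------------------------
  biomarkers <- c("absolute", "relative", "lrtc")
  features <- list()
  for (i in seq_along(biomarkers)) {
    bm <- biomarkers[i]
    ref <- if (bm == "relative") {
      gen_relpower_cohort(config$n_reference, seed = seeds[["simulate"]] + i)
    } else {
      gen_cohort_features(tdc_cohort_spec(config$n_reference, seed = seeds[["simulate"]] + i))
    }
    pat_spec <- tdc_cohort_spec(config$n_patients, seed = seeds[["patients"]] + i)
    pat <- gen_cohort_features(pat_spec, cohort = "patient")
    # age-matched recruitment: every patient age has enough reference
    # subjects in its +/- window for covariance estimation
    pat <- match_ages_to_reference(pat, ref,
      window = config$age_window,
      min_n = config$min_n, seed = seeds[["patients"]] + 50L + i
    )
    # planted patient deviation: shift the low-frequency features upward
    lowf <- grep("^delta_|^theta_", feature_cols(pat))
    pat[, feature_cols(pat)[lowf]] <- pat[, feature_cols(pat)[lowf]] + 1.5
    features[[bm]] <- list(reference = ref, patients = pat)
  }
  pair <- gen_state_pair(features$relative$reference,
    alpha_boost = config$alpha_boost, theta_boost = config$theta_boost
  )
  note("simulate: %d reference, %d patients, 3 biomarkers", config$n_reference, config$n_patients)

  # -- fit --------------------------------------------------------------
  spaces <- lapply(features, function(f) {
    normative_space(f$reference,
      n_components = config$n_components,
      sparsity = config$sparsity
    )
  })
  note(
    "fit: %d components, sparsity %g, cum. var %s",
    config$n_components, config$sparsity,
    paste(sprintf("%.0f%%", 100 * vapply(spaces, function(s) max(s$cumulative_variance), 1)),
      collapse = "/"
    )
  )

  # -- deviate ----------------------------------------------------------
  deviance <- list()
  for (bm in biomarkers) {
    deviance[[bm]] <- deviance_table(
      spaces[[bm]], features[[bm]]$reference, features[[bm]]$patients,
      window = config$age_window, min_n = config$min_n, seed = seeds[["mcd"]]
    )
  }
  note("deviate: %d rows per biomarker", nrow(deviance[[1]]))

  # -- state contrast (relative power, eyes open vs closed) -------------
  sc_pairs <- pc_pairs(config$n_components)
  contrast <- lapply(seq_len(nrow(sc_pairs)), function(r) {
    pr <- sc_pairs[r, ]
    ctr <- fit_mcd(predict(spaces$relative, pair$eor, pair = pr), seed = seeds[["mcd"]])
    md_eor <- mahal_dist(predict(spaces$relative, pair$eor, pair = pr), ctr)
    md_ecr <- mahal_dist(predict(spaces$relative, pair$ecr, pair = pr), ctr)
    w <- paired_wilcoxon(md_eor, md_ecr)
    data.frame(
      pc_pair = sprintf("PC%d-PC%d", pr[1], pr[2]),
      prop_increased = mean(md_ecr > md_eor),
      statistic = w$statistic, p_value = w$p_value, effect_r = w$effect_r
    )
  })
  contrast <- do.call(rbind, contrast)
  contrast$p_fdr <- bh_fdr(contrast$p_value)
  note("state contrast: median %.0f%% of subjects increased", 100 * stats::median(contrast$prop_increased))

  # -- clinical ---------------------------------------------------------
  clin_tab <- gen_clinical_cohort(clinical_cohort_spec(config$n_patients, seed = seeds[["clinical"]]))
  cp <- clinical_pca(clin_tab)
  note("clinical: PC1+PC2 = %.1f%%", sum(cp$explained_pct[1:2]))

  # -- correlate --------------------------------------------------------
  corr <- list()
  for (bm in biomarkers) {
    for (dk in c("global", "age")) {
      for (ax in c("PC1_clin", "PC2_clin")) {
        sc <- stats::setNames(cp$scores[, ax], clin_tab$patient)
        dv <- deviance[[bm]]
        names(sc) <- unique(dv$subject)[seq_along(sc)] # align synthetic ids
        res <- correlate_deviance_clinical(dv, sc,
          distance = dk, axis = ax,
          n_perm = config$n_perm, n_boot = config$n_boot,
          seed = seeds[["stats"]], alpha = config$alpha
        )
        res <- cbind(biomarker = bm, res)
        corr[[length(corr) + 1L]] <- res
      }
    }
  }
  corr <- do.call(rbind, corr)
  note("correlate: %d correlation rows", nrow(corr))

  manifest <- list(
    config = unclass(config), seeds = as.list(seeds),
    stages = c("simulate", "features", "fit", "deviate", "clinical", "correlate"),
    log = log, config_hash = config_hash(config),
    n_correlations = nrow(corr)
  )
  out <- list(
    features = features, spaces = spaces, deviance = deviance,
    clinical = cp, clinical_table = clin_tab, correlations = corr,
    state_contrast = contrast, manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (bm in biomarkers) {
      utils::write.csv(deviance[[bm]], file.path(out_dir, paste0("deviance_", bm, ".csv")),
        row.names = FALSE
      )
    }
    utils::write.csv(corr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(contrast, file.path(out_dir, "state_contrast.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(out)
}
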