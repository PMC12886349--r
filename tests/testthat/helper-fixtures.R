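# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; nothing is read from disk except the packaged clinical
# tables.

fix <- local({
  e <- new.env()
  function(name, builder) {
    if (!exists(name, envir = e, inherits = FALSE)) {
      assign(name, builder(), envir = e)
    }
    get(name, envir = e)
  }
})

ref_cohort <- function() {
  fix("ref_cohort", function() gen_cohort_features(tdc_cohort_spec(96, seed = 2)))
}

ref_space <- function() {
  fix("ref_space", function() normative_space(ref_cohort()))
}

relpower_cohort <- function() {
  fix("relpower_cohort", function() gen_relpower_cohort(96, seed = 3))
}

clinical_table <- function() {
  fix("clinical_table", function() snare_clinical_scales())
}
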