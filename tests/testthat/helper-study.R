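# Shared fixtures: the default synthetic study is generated once per test run
# and cached, since several files exercise different stages of the same study.

.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 17L) {
  key <- paste0("study_", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- make_plasma_study(default_scenario(seed))
  }
  .study_cache[[key]]
}

default_invitro <- function(seed = 17L) {
  key <- paste0("invitro_", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- make_invitro_suite(default_scenario(seed))
  }
  .study_cache[[key]]
}

default_pipeline <- function(seed = 17L) {
  key <- paste0("pipeline_", seed)
  if (is.null(.study_cache[[key]])) {
    study <- default_study(seed)
    .study_cache[[key]] <- run_pipeline(study$features, study$design,
                                        spectra = study$spectra,
                                        invitro = default_invitro(seed))
  }
  .study_cache[[key]]
}

# independent pooled-variance t-test oracle (hand-coded, never t.test)
oracle_student_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}
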