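# The full-scale study (all 593,775 patterns, ~148k valid, three cohorts)
# takes well under a minute; it is computed once and shared by the
# study-level assertions.
study_cache <- new.env(parent = emptyenv())

full_study <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(study_cache[[key]])) {
    study <- run_study(seed)
    study_cache[[key]] <- list(study = study, stats = study_statistics(study))
  }
  study_cache[[key]]
}
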