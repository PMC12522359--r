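# Seeded cohort fixtures shared across test files (computed once per run).
# n = 20 at 256x256 is the study size the end-to-end checks use.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

clean_cohort <- function() memo("clean", generate_cohort(20, base_seed = 11,
                                                         artifact_fraction = 0))
artifact_cohort <- function() memo("artifact",
                                   generate_cohort(20, base_seed = 11,
                                                   artifact_fraction = 1))
clean_results <- function() memo("clean_res",
                                 segment_cohort(clean_cohort(),
                                                prompt_mode = "mask"))
artifact_results <- function() memo("artifact_res",
                                    segment_cohort(artifact_cohort(),
                                                   prompt_mode = "mask"))
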