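# Shared fixtures, generated in code.

# small library: 10 target genes + 2 essential genes (4 guides each) + 12 NTC
small_library <- function() compose_library(10, 2, 12, 4)

# seeded random count table over a library, two columns named ctrl/trt
random_count_table <- function(library, seed, samples = c("ctrl", "trt"),
                               lambda = 300) {
  m <- with_seed_test(seed, {
    matrix(stats::rpois(nrow(library) * length(samples), lambda),
           nrow = nrow(library),
           dimnames = list(library$guide_id, samples))
  })
  count_table(m, library)
}

child_seed_test <- child_seed

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# default-condition simulated screen used by several suites (null unless
# fitness/sensitization supplied); full study-scale library
study_screen <- function(seed, fitness = numeric(), sensitization = list(),
                         doublings = c(DMSO = 15, OLA = 15),
                         n_target = 356, n_essential = 63, n_ntc = 324) {
  lib <- compose_library(n_target, n_essential, n_ntc, 4)
  model <- effect_model(fitness = fitness, sensitization = sensitization,
                        doublings = doublings)
  simulate_screen(lib, model, seed = seed)
}
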