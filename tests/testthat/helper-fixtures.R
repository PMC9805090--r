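# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small cohort for fast module-level tests; ... overrides the defaults.
tiny_config <- function(...) {
  args <- modifyList(list(
    n_samples = 60, n_probes = 600, n_truth_dmps = 10, effect_sizes = 0.08,
    n_markers_per_type = 20, n_clock_cpgs = 10, n_mqtl_pairs = 3,
    n_null_snvs = 10, seed = 42L
  ), list(...))
  do.call(simulation_config, args)
}

tiny_cohort <- function() {
  memo("tiny", simulate_cohort(tiny_config()))
}

# Study-scale cohort used by the end-to-end property checks.
study_cohort <- function() {
  memo("study", simulate_cohort(
    simulation_config(n_samples = 200, n_probes = 2000, n_truth_dmps = 50,
                      effect_sizes = 0.05, seed = 7L)
  ))
}

# Memoized study-cohort DMP scan, shared by the DMR and acceptance tests.
study_dmps <- function() {
  memo("study_dmps", {
    co <- study_cohort()
    test_dmps(get_beta(co$beta), co$group)
  })
}

# A hand-built 6-probe methylation matrix with known quality failures.
handmade_matrix <- function() {
  probes <- paste0("p", 1:6)
  samples <- paste0("s", 1:4)
  beta <- matrix(0.5, 6, 4, dimnames = list(probes, samples))
  detp <- matrix(0.001, 6, 4, dimnames = list(probes, samples))
  beads <- matrix(10L, 6, 4, dimnames = list(probes, samples))
  detp["p1", ] <- 0.5              # fails detection everywhere
  beads["p2", ] <- 1L              # fails bead count everywhere
  methylation_matrix(beta, design_type = rep("II", 6),
                     detection_p = detp, bead_count = beads)
}

handmade_annotation <- function() {
  probe_annotation(
    probe_id = paste0("p", 1:6),
    chromosome = c("1", "1", "2", "2", "3", "X"),
    position = c(100L, 5000L, 100L, 5000L, 100L, 100L),
    non_cpg = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    snp_related = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    multi_hit = FALSE
  )
}
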