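# Shared fixtures: a fixed canonical structure and small task configurations,
# plus cohort simulation helpers. Everything is generated in code at test
# time; seeds are fixed per test for determinism.

fixed_structure <- function() make_structure(seed = 1)

short_config <- function(n_blocks = 2L) task_config(n_blocks = n_blocks)

# projection of the reference parameter pattern onto a spec's free space
pattern_free <- function(spec) {
  as.numeric(creditmap:::project_params(spec, empirical_pattern_params()))
}

sim_cohort <- function(spec, free, n_subjects, config = task_config()) {
  lapply(seq_len(n_subjects), function(i)
    simulate_session(free, spec, structure = make_structure(),
                     config = config))
}

random_full_params <- function() {
  model_params(c_mf = runif(4, -1, 1), c_mb = runif(4, -1, 1),
               f_mf = runif(1, 0.05, 0.95), f_mb = runif(1, 0.05, 0.95),
               pr = runif(1, -0.5, 0.5), f_p = runif(1, 0.05, 0.95))
}
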