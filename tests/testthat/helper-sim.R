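# Shared fixture builders. Everything is generated in code at test time.

walker_config <- function(spacing = 20, q = 0.005, n = 20000, seed = 3,
                          trap_on = TRUE, p_return = 0.5, E = 1) {
  sim_config(dna_length_bp = 400L, site1_pos = 150L,
             site2_pos = 150L + as.integer(spacing),
             q = q, p_return = p_return, trap_on = trap_on,
             E = E, n_molecules = as.integer(n), rng_seed = as.integer(seed))
}

population_config <- function(n = 10000, rebind = 0.002, seed = 5, E = 1,
                              trap_on = FALSE) {
  sim_config(n_molecules = as.integer(n), rebind_rate = rebind, E = E,
             trap_on = trap_on, rng_seed = as.integer(seed))
}

# standard 12-point log-spaced titration design spanning 0.05-50 uM
titration_design <- function() exp(seq(log(0.05e-6), log(50e-6), length.out = 12))
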