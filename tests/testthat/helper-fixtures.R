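# Small panel configurations reused across tests. Seeds are fixed fixture
# parameters chosen up front.

quick_config <- function(n_states = 3L, seed = 101L, ...) {
  panel_config(n_states = n_states, start_year = 2004, end_year = 2015,
               seed = seed, ...)
}

# Noise-free multiplicative ground truth: known seasonal pattern, linear
# trend, no cycle, no irregular noise.
noiseless_config <- function(n_states = 1L, seed = 202L,
                             seasonal_indices = default_seasonal_indices(), ...) {
  panel_config(n_states = n_states, start_year = 2004, end_year = 2015,
               irregular_sd = 0, cycle_amplitude = 0,
               seasonal_indices = seasonal_indices, seed = seed, ...)
}
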