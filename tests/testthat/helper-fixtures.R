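## Shared fixtures: everything is generated in code at test time.

default_cfg <- function(...) generator_config(...)

## trace matrix built directly from sampled kinetics (bypasses
## simulate_dataset; used where only traces are needed)
make_trace_matrix <- function(kin, cfg, n_pre = 5L) {
  tr <- t(vapply(seq_len(nrow(kin)), function(j)
    synthesize_trace(kin$amplitude[j], kin$dwell_s[j], kin$tau_s[j],
                     kin$f_model[j], cfg, n_pre = n_pre)$values,
    numeric(length(seq(-n_pre * cfg$frame_interval_s, 1.0 + 1e-9,
                       by = cfg$frame_interval_s)))))
  dt <- cfg$frame_interval_s
  attr(tr, "frame_interval_s") <- dt
  attr(tr, "event_index") <- n_pre + 1L
  attr(tr, "n_pre") <- n_pre
  attr(tr, "t_s") <- seq(-n_pre * dt, 1.0 + 1e-9, by = dt)
  tr
}

## noiseless single trace straight from the generative model
noiseless_trace <- function(A = 1, dwell = 0, tau = 0.5, f = 1,
                            cfg = generator_config()) {
  synthesize_trace(A, dwell, tau, f, cfg, noise_sd = 0)
}

## bounded child seed for parameterised test cases
derive_seed_for_test <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
               2147483647)
}
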