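# shared fixtures: packaged defaults and a cheap ensemble size for tests
default_a1 <- function(...) a1_params(...)
default_net <- function(...) network_params(...)

quick_buildup <- function(df, n_triplets = 10, adapting = TRUE, n = 100,
                          seed = 1, a1 = default_a1(), net = default_net()) {
  a1$adapting <- adapting
  condition_buildup(make_triplet_sequence(n_triplets, df, 420), a1, net,
                    n_trials = n, master_seed = seed)
}
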