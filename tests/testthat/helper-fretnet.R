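# Shared fixtures for the fretnet test suite.

# A rate_system with arbitrary positive rates (not via the samplers), for
# cross-checking the linear first-passage solve against time integration.
random_rate_system <- function(n, k_d = 1, rate_scale = 2) {
  k_da <- runif(n, 0, rate_scale)
  k_dd <- matrix(0, n, n)
  if (n > 1) {
    k_dd[upper.tri(k_dd)] <- runif(n * (n - 1) / 2, 0, rate_scale)
    k_dd <- k_dd + t(k_dd)
  }
  structure(list(k_da = k_da, k_dd = k_dd, k_d = k_d, k_a = 0,
                 n_donors = n), class = "rate_system")
}

# Absorption probability at the end of a long time integration.
phi_by_integration <- function(system, initial_donor,
                               horizon = 40 / system$k_d, n_times = 4001) {
  tc <- integrate_populations(system, initial_donor, horizon = horizon,
                              n_times = n_times)
  tc$captured[nrow(tc)]
}

fast_iv <- case_spec("iv")

all_platonic <- c("D2A", "D4A", "D6A", "D8A", "D12A", "D20A")
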