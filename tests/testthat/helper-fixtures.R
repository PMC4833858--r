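# Shared fixtures: all synthetic, built in code.

biexp_curve <- function(t, f_fast, k_fast, f_slow, k_slow, plateau) {
  plateau + f_fast * exp(-k_fast * t) + f_slow * exp(-k_slow * t)
}

# random mass-action system with 0..n_acc acceptor pools, valid by construction
make_random_system <- function(seed, n_acc = NULL) {
  set.seed(seed)
  if (is.null(n_acc)) n_acc <- sample(0:5, 1)
  koff <- sort(10^runif(2, -5, -2))   # core slower than surface
  surface <- acceptor_pool("surface", runif(1, 1, 100), 10^runif(1, -4, -1),
                           koff[2], runif(1, 40, 90))
  core <- acceptor_pool("core", runif(1, 1, 100), 10^runif(1, -4, -1),
                        koff[1], runif(1, 40, 90))
  acceptors <- lapply(seq_len(n_acc), function(i) {
    acceptor_pool(paste0("acc", i), runif(1, 1, 500), 10^runif(1, -4, -1),
                  10^runif(1, -6, -3), runif(1, 40, 90))
  })
  exchange_system(donor_particle_pools(surface, core),
                  acceptors = acceptors,
                  temperature_c = runif(1, 20, 41),
                  total_drug = runif(1, 0.5, 2))
}

# independent closed-form solution of the linear system via matrix exponential
expm_trajectory <- function(system, times) {
  A <- build_rate_matrix(system)
  x0 <- system$state0
  t(vapply(times, function(t) {
    as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% x0)
  }, numeric(length(x0))))
}

# simulated, fitted half-life of one archetype condition
archetype_half_life <- function(drug, fraction, temperature_c,
                                duration_s = 86400, interval_s = 240) {
  sys <- archetype_system(drug, "FBS", fraction, temperature_c)
  tr <- simulate_exchange(sys, seq(0, duration_s, interval_s),
                          spectral = spectral_params())
  y <- normalize_ratio_series(tr$fret_ratio, "first_point")
  fit <- fit_two_compartment(tr$time_s, y)
  as.numeric(half_life_of_fit(fit))
}

make_test_trace <- function(n = 20, seed = 42) {
  set.seed(seed)
  kinetic_trace(times = cumsum(runif(n, 0.5, 20)),
                i_donor = runif(n, 100, 1000),
                i_fret = runif(n, 10, 100),
                condition = list(temperature_c = 37, acceptor_medium = "FBS",
                                 acceptor_fraction = 0.25,
                                 particle_conc_mg_ml = 1),
                label = "random-trace",
                extra = list(instrument = "synthetic-reader", well = "B07"))
}
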