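test_that("arrhenius_rate matches its closed form and limits", {
  expect_equal(arrhenius_rate(1e-3, 0, 350, 298), 1e-3)
  expect_equal(arrhenius_rate(2.7e-4, 75, 310.15, 310.15), 2.7e-4)
  # hand evaluation of the stated formula
  expect_equal(arrhenius_rate(1e-3, 60, 310.15, 298.15),
               1e-3 * exp(-(60000 / 8.314) * (1 / 310.15 - 1 / 298.15)),
               tolerance = 1e-12)
  expect_equal(arrhenius_rate(1e-3, 60, 310.15, 298.15), 2.551082e-3,
               tolerance = 1e-6)
  expect_error(arrhenius_rate(1e-3, 60, -5, 298), "positive")
})

test_that("rate matrices conserve mass by construction", {
  for (seed in 1:20) {
    A <- build_rate_matrix(make_random_system(seed))
    expect_lt(max(abs(colSums(A))), 1e-15 * max(abs(A), 1))
  }
  # all-zero rates give the zero matrix
  z <- acceptor_pool("z", 0, 0, 0, 0)
  sys0 <- exchange_system(donor_particle_pools(z, z), temperature_c = 37)
  expect_true(all(build_rate_matrix(sys0) == 0))
})

test_that("donor-only system sits at detailed balance and stays there", {
  surface <- acceptor_pool("s", 10, 0.01, 1e-3, 65)
  core <- acceptor_pool("c", 10, 0.002, 1e-4, 80)
  sys <- exchange_system(donor_particle_pools(surface, core),
                         temperature_c = 37, total_drug = 2)
  x0 <- sys$state0
  # closed-form two-balance solution: pool/free = capture/k_off at T_ref = 37 C
  expect_equal(x0[["surface"]] / x0[["free"]], 0.01 * 10 / 1e-3, tolerance = 1e-12)
  expect_equal(x0[["core"]] / x0[["free"]], 0.002 * 10 / 1e-4, tolerance = 1e-12)
  traj <- simulate_exchange(sys, seq(0, 86400, 3600))
  for (col in c("surface", "core", "free")) {
    expect_equal(traj[[col]], rep(x0[[col]], nrow(traj)), tolerance = 1e-9)
  }
})

test_that("a strong sink acceptor reduces donor decay to its off-rates", {
  surface <- acceptor_pool("s", 10, 1e-4, 2e-3, 65)
  core <- acceptor_pool("c", 10, 1e-5, 5e-5, 80)
  sink <- acceptor_pool("sink", 1000, 10, 0, 0)   # capture >> recapture
  sys <- exchange_system(donor_particle_pools(surface, core),
                         acceptors = list(sink), temperature_c = 37)
  tg <- seq(0, 20000, 100)
  traj <- simulate_exchange(sys, tg)
  s0 <- sys$state0[["surface"]]; c0 <- sys$state0[["core"]]
  expect_equal(traj$surface, s0 * exp(-2e-3 * tg), tolerance = 1e-3)
  expect_equal(traj$core, c0 * exp(-5e-5 * tg), tolerance = 1e-3)
})

test_that("trajectories conserve total drug", {
  for (seed in 1:20) {
    sys <- make_random_system(seed)
    traj <- simulate_exchange(sys, seq(0, 50000, 500))
    totals <- rowSums(traj[, setdiff(names(traj), "time_s")])
    expect_lt(max(abs(totals - sys$total_drug)) / sys$total_drug, 1e-9)
  }
})

test_that("stiff integration agrees with the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  times <- c(0, 10, 100, 1000, 10000, 60000)
  for (seed in 1:10) {
    sys <- make_random_system(seed, n_acc = sample(0:6, 1))
    traj <- simulate_exchange(sys, times)
    oracle <- expm_trajectory(sys, times)
    got <- as.matrix(traj[, setdiff(names(traj), "time_s")])
    expect_lt(max(abs(got - oracle)) / sys$total_drug, 1e-6)
  }
})

test_that("without acceptors the FRET observable is time-invariant", {
  sys <- archetype_system("C12", medium = "PBS")
  traj <- simulate_exchange(sys, seq(0, 86400, 600), spectral = spectral_params())
  expect_lt(max(abs(traj$fret_ratio - traj$fret_ratio[1])) / traj$fret_ratio[1],
            1e-9)
})

test_that("t_grid validation and integration failure reporting", {
  sys <- archetype_system("CA")
  expect_error(simulate_exchange(sys, c(5, 10)), "start at 0")
  expect_error(simulate_exchange(sys, c(0, 10, 10)), "strictly increasing")
})

test_that("equilibrium distribution is the unique stationary state", {
  # symmetric two-pool donor: equal share in each sub-pool
  p <- acceptor_pool("p", 10, 0.01, 1e-3, 60)
  sys <- exchange_system(donor_particle_pools(p, p), temperature_c = 37)
  eq <- equilibrium_distribution(sys)
  expect_equal(sum(eq), 1, tolerance = 1e-12)
  expect_equal(eq[["surface"]], eq[["core"]], tolerance = 1e-9)
  # absorbing acceptor takes everything
  sink <- acceptor_pool("sink", 100, 1, 0, 0)
  sys2 <- exchange_system(donor_particle_pools(p, p), acceptors = list(sink),
                          temperature_c = 37)
  eq2 <- equilibrium_distribution(sys2)
  expect_equal(eq2[["sink"]], 1, tolerance = 1e-9)
  # random system: stationary state matches long-horizon integration
  for (seed in c(4, 17, 23)) {
    sys3 <- make_random_system(seed, n_acc = 3)
    eq3 <- equilibrium_distribution(sys3)
    t_long <- 200 / min(vapply(c(list(sys3$donor$surface_pool, sys3$donor$core_pool),
                                 sys3$acceptors),
                               function(p) max(.Machine$double.eps,
                                               fretrelease:::.pool_koff(p, sys3$temperature_k)),
                               numeric(1)))
    traj <- simulate_exchange(sys3, c(0, t_long))
    final <- unlist(traj[2, setdiff(names(traj), "time_s")]) / sys3$total_drug
    expect_equal(unname(final), unname(eq3), tolerance = 1e-6)
  }
  # degenerate and non-unique cases error
  z <- acceptor_pool("z", 0, 0, 0, 0)
  expect_error(equilibrium_distribution(
    exchange_system(donor_particle_pools(z, z), temperature_c = 37)),
    "all rates are zero")
  two_sinks <- exchange_system(
    donor_particle_pools(p, p),
    acceptors = list(acceptor_pool("s1", 10, 1, 0, 0),
                     acceptor_pool("s2", 10, 1, 0, 0)),
    temperature_c = 37)
  expect_error(equilibrium_distribution(two_sinks), "not unique")
})

test_that("descriptor mapping moves barriers and loading split the right way", {
  base <- exchange_base_config()
  d1 <- map_descriptors_to_params(drug_descriptor_map(logd = 3, chi = 2))
  d2 <- map_descriptors_to_params(drug_descriptor_map(logd = 7, chi = 2))
  expect_gt(d2$surface_pool$ea_off_kj_mol, d1$surface_pool$ea_off_kj_mol)
  expect_lt(d2$surface_pool$release_rate_ref, d1$surface_pool$release_rate_ref)
  expect_equal(d1$core_fraction_initial, d2$core_fraction_initial, tolerance = 1e-12)
  c1 <- map_descriptors_to_params(drug_descriptor_map(logd = 5, chi = 0.5))
  c2 <- map_descriptors_to_params(drug_descriptor_map(logd = 5, chi = 3.5))
  expect_gt(c1$core_fraction_initial, c2$core_fraction_initial)
  # extreme immiscibility: essentially no core loading
  cx <- map_descriptors_to_params(drug_descriptor_map(logd = 5, chi = 1e6))
  expect_lte(cx$core_fraction_initial, 1e-6)
  expect_error(drug_descriptor_map(5, 2, ea_slope = -1), "ea_slope")
  expect_error(map_descriptors_to_params(drug_descriptor_map(logd = 40, chi = 2)),
               "core barrier")
})

test_that("hydrophobicity and miscibility each slow simulated release", {
  hl <- function(logd, chi) {
    sys <- exchange_system(
      map_descriptors_to_params(drug_descriptor_map(logd, chi)),
      acceptors = default_acceptor_pools("FBS", 1), temperature_c = 37)
    tr <- simulate_exchange(sys, seq(0, 43200, 240), spectral = spectral_params())
    fit <- fit_two_compartment(tr$time_s,
                               normalize_ratio_series(tr$fret_ratio, "first_point"))
    as.numeric(half_life_of_fit(fit))
  }
  # equal chi, higher logd -> longer half-life
  expect_gt(hl(7, 3), hl(4, 3))
  # equal logd, lower chi (better miscibility) -> longer half-life
  expect_gt(hl(5, 0.5), hl(5, 3))
})
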