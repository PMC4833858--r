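test_that("zero-noise traces equal the forward model exactly and seeds reproduce", {
  sys <- archetype_system("CA", "FBS", 1, 37)
  tg <- seq(0, 1800, 30)
  clean <- noise_model(multiplicative_sigma = 0, additive_sigma = 0, seed = 5)
  tr <- generate_trace(sys, spectral_params(), clean, tg)
  truth <- attr(tr, "truth")
  expect_identical(tr$i_donor, truth$i_donor)
  expect_identical(tr$i_fret, truth$i_fret)
  noisy <- noise_model(multiplicative_sigma = 0.02, additive_sigma = 1, seed = 7)
  t1 <- generate_trace(sys, spectral_params(), noisy, tg)
  t2 <- generate_trace(sys, spectral_params(), noisy, tg)
  expect_identical(t1$i_donor, t2$i_donor)
  expect_identical(t1$i_fret, t2$i_fret)
  t3 <- generate_trace(sys, spectral_params(), noise_model(0.02, 1, seed = 8), tg)
  expect_false(identical(t1$i_donor, t3$i_donor))
})

test_that("multiplicative noise has the declared coefficient of variation", {
  cal <- generate_calibration_series(c(2, 5, 8),
                                     noise = noise_model(multiplicative_sigma = 0.01,
                                                         seed = 12),
                                     replicates = 100)
  cv_donor <- stats::sd(cal$i_donor / cal$i_donor_true - 1)
  cv_fret <- stats::sd(cal$i_fret / cal$i_fret_true - 1)
  expect_lt(abs(cv_donor - 0.01), 0.003)
  expect_lt(abs(cv_fret - 0.01), 0.003)
})

test_that("photobleaching is common-mode and cancels in the ratio", {
  sys <- archetype_system("OLA", "FBS", 0.5, 37)
  tg <- seq(0, 3600, 60)
  bleach <- noise_model(multiplicative_sigma = 0, photobleach_rate = 1e-4, seed = 1)
  none <- noise_model(multiplicative_sigma = 0, seed = 1)
  tr_b <- generate_trace(sys, spectral_params(), bleach, tg)
  tr_0 <- generate_trace(sys, spectral_params(), none, tg)
  expect_lt(max(abs(tr_b$i_fret / tr_b$i_donor - tr_0$i_fret / tr_0$i_donor)), 1e-12)
  expect_true(all(tr_b$i_donor < tr_0$i_donor * c(1 + 1e-12, rep(1, length(tg) - 1))))
})

test_that("noise-free calibration series recovers the forward-model line exactly", {
  loads <- seq(1, 9, 2)
  cal_tab <- generate_calibration_series(loads, noise = noise_model(0, 0, 0, seed = 3),
                                         replicates = 2)
  cal <- calibrate_loading(cal_tab$load, cal_tab$ratio)
  direct <- calibrate_loading(loads, fret_ratio(predict_intensities(loads)))
  expect_equal(cal$slope, direct$slope, tolerance = 1e-12)
  expect_equal(cal$intercept, direct$intercept, tolerance = 1e-12)
  # 1% noise, 5 replicates: slope recovered within 2%
  noisy <- generate_calibration_series(loads, noise = noise_model(0.01, seed = 9),
                                       replicates = 5)
  cal_n <- calibrate_loading(noisy$load, noisy$ratio)
  expect_lt(abs(cal_n$slope - direct$slope) / direct$slope, 0.02)
})

test_that("panel generation writes the full condition grid with a consistent manifest", {
  out <- withr::local_tempdir()
  spec <- panel_spec(drugs = c("CA", "C12", "OLA", "PLGA2k"),
                     serum_fractions = c(0.25, 1.0), temperatures_c = 37,
                     duration_s = 14400, interval_s = 240)
  manifest <- generate_panel(spec, noise_model(multiplicative_sigma = 0.01, seed = 2), out)
  expect_equal(nrow(manifest), 8)  # 4 drugs x 2 fractions x 1 temperature
  expect_true(all(file.exists(file.path(out, manifest$file))))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  # ground-truth half-lives obey the archetype ordering at every condition
  for (fr in unique(manifest$serum_fraction)) {
    sub <- manifest[manifest$serum_fraction == fr, ]
    hl <- sub$true_half_life_s[match(c("CA", "C12", "OLA", "PLGA2k"), sub$drug)]
    expect_true(all(diff(hl) > 0))
  }
  # trace files parse and carry their conditions
  tr <- read_trace(file.path(out, manifest$file[1]))
  expect_equal(tr$condition$acceptor_fraction, manifest$serum_fraction[1])
  expect_equal(tr$condition$temperature_c, manifest$temperature_c[1])
})

test_that("fits on generated traces recover manifest ground truth", {
  out <- withr::local_tempdir()
  spec <- panel_spec(drugs = c("CA", "C12"), serum_fractions = 1, temperatures_c = 37,
                     duration_s = 14400, interval_s = 120)
  manifest <- generate_panel(spec, noise_model(multiplicative_sigma = 0.01, seed = 21), out)
  fits <- fit_trace_files(out)
  for (i in seq_len(nrow(manifest))) {
    hl <- as.numeric(half_life_of_fit(fits[[manifest$label[i]]]))
    expect_lt(abs(hl - manifest$true_half_life_s[i]) / manifest$true_half_life_s[i],
              0.10)
  }
})

test_that("buffer-only traces are flat", {
  sys <- archetype_system("CA", medium = "PBS")
  tr <- generate_trace(sys, noise = noise_model(0, 0, 0, seed = 1),
                       t_grid = seq(0, 7200, 60))
  ratio <- tr$i_fret / tr$i_donor
  expect_lt(max(abs(ratio - ratio[1])) / ratio[1], 1e-9)
})

test_that("pool snapshots are proper fractions matching the long-time limit", {
  p <- acceptor_pool("p", 10, 0.01, 1e-3, 60)
  sink <- acceptor_pool("sink", 100, 1, 0, 0)
  sys <- exchange_system(donor_particle_pools(p, p), acceptors = list(sink),
                         temperature_c = 37)
  snap <- generate_pool_snapshot(sys, t_end = 7200)
  expect_equal(sum(snap$fraction), 1, tolerance = 1e-12)
  expect_gt(snap$fraction[snap$pool == "sink"], 0.999)
  # equilibrating system: snapshot at t >> 1/k_slow matches the stationary state
  sys2 <- archetype_system("CA", "FBS", 1, 37)
  snap2 <- generate_pool_snapshot(sys2, t_end = 5e7)
  eq <- equilibrium_distribution(sys2)
  expect_equal(snap2$fraction, unname(eq[snap2$pool]), tolerance = 1e-6)
})
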