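test_that("solubility parameter and molar volume match independent manual summation", {
  tab <- fedors_table()
  # expected values are literal spreadsheet-style sums over the table entries
  cases <- list(
    list(comp = molecule_composition("deca-methylene", c(CH2 = 10)),
         e = 10 * 4940, v = 10 * 16.1),
    list(comp = molecule_composition("alkane", c(CH3 = 2, CH2 = 8)),
         e = 2 * 4710 + 8 * 4940, v = 2 * 33.5 + 8 * 16.1),
    list(comp = molecule_composition("aryl-acid", c(phenyl = 1, COOH = 1, CH2 = 3)),
         e = 31940 + 27630 + 3 * 4940, v = 71.4 + 28.5 + 3 * 16.1),
    list(comp = molecule_composition("lactide-like", c(CH3 = 1, CH = 1, COO = 1)),
         e = 4710 + 3430 + 18000, v = 33.5 - 1.0 + 18.0),
    list(comp = molecule_composition("ether-ol", c(CH2 = 4, O = 2, OH = 1)),
         e = 4 * 4940 + 2 * 3350 + 29800, v = 4 * 16.1 + 2 * 3.8 + 10.0),
    list(comp = molecule_composition("branched", c(CH3 = 3, CH = 1, C = 1, CH2 = 2)),
         e = 3 * 4710 + 3430 + 1470 + 2 * 4940,
         v = 3 * 33.5 - 1.0 - 19.2 + 2 * 16.1))
  for (cs in cases) {
    expect_equal(compute_molar_volume(cs$comp, tab), cs$v, tolerance = 1e-9)
    expect_equal(compute_solubility_parameter(cs$comp, tab), sqrt(cs$e / cs$v),
                 tolerance = 1e-9)
  }
  # worked reference point: 10 x CH2
  expect_equal(compute_solubility_parameter(cases[[1]]$comp, tab),
               17.5166331, tolerance = 1e-6)
})

test_that("descriptors are invariant under uniform scaling of group counts", {
  tab <- fedors_table()
  base <- molecule_composition("x", c(CH3 = 2, CH2 = 5, COO = 1))
  tripled <- molecule_composition("x3", c(CH3 = 6, CH2 = 15, COO = 3))
  expect_equal(compute_solubility_parameter(base, tab),
               compute_solubility_parameter(tripled, tab), tolerance = 1e-12)
  expect_equal(3 * compute_molar_volume(base, tab),
               compute_molar_volume(tripled, tab), tolerance = 1e-12)
})

test_that("degenerate compositions and unknown groups give descriptive errors", {
  tab <- fedors_table()
  expect_error(molecule_composition("empty"), "non-empty group counts")
  expect_error(molecule_composition("zero", c(CH2 = 0)), "non-empty group counts")
  expect_error(molecule_composition("neg", c(CH2 = -1)), "non-negative")
  comp <- molecule_composition("odd", c(unobtainium = 2))
  expect_error(compute_solubility_parameter(comp, tab), "unobtainium")
  expect_error(compute_molar_volume(comp, tab), "unobtainium")
  # correction-only composition with non-positive total volume
  neg <- molecule_composition("correction-only", c(C = 2))
  expect_error(compute_molar_volume(neg, tab), "not positive")
  # zero cohesive energy table -> delta = 0
  ztab <- group_table("G", 0, 10)
  expect_equal(compute_solubility_parameter(molecule_composition("z", c(G = 3)), ztab), 0)
  # supplied descriptors pass through
  sup <- molecule_composition("sup", supplied_delta = 21.5, supplied_molar_volume = 123.4)
  expect_identical(compute_molar_volume(sup, tab), 123.4)
  expect_identical(compute_solubility_parameter(sup, tab), 21.5)
})

test_that("chi follows the Flory-Huggins form with its scaling structure", {
  # dimensional hand-calculation: V = 100 cm^3/mol, ddelta = 2 MPa^0.5, 298.15 K
  expect_equal(compute_chi(100, 22, 20, 298.15),
               (100e-6 * 4e6) / (8.314 * 298.15), tolerance = 1e-12)
  expect_equal(compute_chi(100, 22, 20, 298.15), 0.1613672, tolerance = 1e-6)
  # zero iff equal deltas; symmetric; linear in V; quadratic in ddelta
  expect_identical(compute_chi(250, 19.3, 19.3, 310), 0)
  set.seed(7)
  for (i in 1:25) {
    V <- runif(1, 10, 500); da <- runif(1, 10, 30); db <- runif(1, 10, 30)
    Tk <- runif(1, 270, 330)
    chi <- compute_chi(V, da, db, Tk)
    expect_gte(chi, 0)
    expect_equal(chi, compute_chi(V, db, da, Tk), tolerance = 1e-12)
    expect_equal(compute_chi(2 * V, da, db, Tk), 2 * chi, tolerance = 1e-12)
    expect_equal(compute_chi(V, db + 2 * (da - db), db, Tk), 4 * chi,
                 tolerance = 1e-12)
  }
  expect_error(compute_chi(-5, 20, 22, 298), "positive")
  expect_error(compute_chi(100, 20, 22, 0), "positive")
})

test_that("additive hydrophobicity estimator defers to supplied log D", {
  frag <- c(CH2 = 0.5)
  sup <- molecule_composition("sup", c(CH2 = 3), supplied_logd = 14.6)
  est <- estimate_logd_additive(sup, frag)
  expect_equal(as.numeric(est), 14.6)
  expect_false(attr(est, "estimated"))
  add <- estimate_logd_additive(molecule_composition("a", c(CH2 = 12)), frag)
  expect_equal(as.numeric(add), 6.0)
  expect_true(attr(add, "estimated"))
  expect_error(estimate_logd_additive(molecule_composition("b", c(OH = 1)), frag),
               "OH")
})

test_that("zone classification obeys its corner cases and monotonicity", {
  th <- zone_thresholds(chi_lo = 1, chi_hi = 3, logd_lo = 4, logd_hi = 8)
  expect_identical(classify_zone(0, -5, th), "slow_release")       # perfect miscibility
  expect_identical(classify_zone(0, 100, th), "slow_release")
  expect_identical(classify_zone(5, 2, th), "fast_release")        # immiscible + hydrophilic
  expect_identical(classify_zone(2, 6, th), "intermediate")
  expect_error(zone_thresholds(chi_lo = 3, chi_hi = 1), "chi_lo < chi_hi")
  # monotone: decreasing chi or increasing logd never moves slow -> fast
  rank_of <- c(fast_release = 1, intermediate = 2, slow_release = 3)
  set.seed(11)
  for (i in 1:50) {
    a <- sort(runif(2, 0, 5)); b <- sort(runif(2, -2, 12))
    th <- zone_thresholds(a[1], a[2] + 0.01, b[1], b[2] + 0.01)
    chi <- runif(1, 0, 6); logd <- runif(1, -3, 13)
    z0 <- rank_of[classify_zone(chi, logd, th)]
    expect_gte(rank_of[classify_zone(chi - runif(1, 0, 2), logd, th)], z0)
    expect_gte(rank_of[classify_zone(chi, logd + runif(1, 0, 2), th)], z0)
  }
})

test_that("composition files round trip through CSV and JSON", {
  csv <- system.file("extdata", "example_compositions.csv", package = "fretrelease")
  comps <- read_compositions(csv)
  expect_length(comps, 5)
  nm <- vapply(comps, `[[`, character(1), "name")
  expect_true("PLGA_repeat" %in% nm)
  drug <- comps[[which(nm == "drug_CA")]]
  expect_equal(drug$supplied_logd, 3)
  expect_equal(drug$group_counts[["CH2"]], 4)
  res <- characterize_compatibility(drug, comps[[which(nm == "PLGA_repeat")]],
                                    temperature_k = 310.15)
  expect_true(res$chi > 0)
  expect_true(res$zone %in% c("fast_release", "slow_release", "intermediate"))
})

test_that("group tables validate and round trip", {
  tab <- fedors_table()
  expect_error(group_table(c("A", "A"), c(1, 2), c(1, 2)), "unique")
  expect_error(group_table("A", 100, -5), "non-positive molar volume")
  path <- withr::local_tempfile(fileext = ".csv")
  write_group_table(tab, path)
  back <- read_group_table(path)
  expect_equal(back$entries$e_coh_j_per_mol, tab$entries$e_coh_j_per_mol)
  expect_equal(back$entries$v_cm3_per_mol, tab$entries$v_cm3_per_mol)
  expect_equal(back$entries$group, tab$entries$group)
})
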