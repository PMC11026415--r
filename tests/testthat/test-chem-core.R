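test_that("phosphate fractions follow the triprotic closed form", {
  # half-equivalence symmetry at pH = pKa2
  f <- phosphate_fractions(6.98, acid_default)
  expect_equal(f$f_h2po4, f$f_hpo4, tolerance = 1e-10)
  expect_lt(f$f_h3po4 + f$f_po4, 1e-3)

  # fully deprotonated fractions at the high-pH working points
  f <- phosphate_fractions(c(10.3, 10.8, 11.3), acid_default)
  expect_equal(f$f_po4, c(0.0095, 0.029, 0.087), tolerance = 0.01)

  # partition property: sums to one over random pH draws
  set.seed(11)
  ph <- stats::runif(1000, 0, 14)
  f <- phosphate_fractions(ph, acid_default)
  expect_equal(f$f_h3po4 + f$f_h2po4 + f$f_hpo4 + f$f_po4,
               rep(1, 1000), tolerance = 1e-12)

  expect_error(phosphate_fractions(NaN), "finite")
  expect_error(phosphate_fractions(15), "0, 14")
})

test_that("ionic strength sums charge-weighted concentrations", {
  # 1:1 salt identity
  inv <- ion_inventory(c(na = 0.01, cl = 0.01), volume_l = 1)
  expect_equal(ionic_strength(inv), 0.01)
  # 2:1 salt, hand summation: 0.5*(0.020*1 + 0.010*4) = 0.03
  inv <- ion_inventory(c(na = 0.020, hpo4 = 0.010), volume_l = 1)
  expect_equal(ionic_strength(inv), 0.03)
  # empty inventory and neutral species contribute nothing
  expect_equal(ionic_strength(ion_inventory(volume_l = 1)), 0)
  expect_equal(ionic_strength(ion_inventory(c(cahpo4 = 1), volume_l = 1)), 0)
  # charged ion pairs do contribute
  inv <- ion_inventory(c(cah2po4 = 0.01, capo4 = 0.01), volume_l = 1)
  expect_equal(ionic_strength(inv), 0.01)
  expect_error(ion_inventory(c(na = 1), volume_l = 0), "positive")
})

test_that("Davies coefficients match hand evaluation and stay in range", {
  expect_identical(davies_gamma(0, 0.5), 1)
  expect_equal(davies_gamma(1, 0.02), 0.871, tolerance = 1e-3)
  expect_equal(davies_gamma(3, 0.03), 0.232, tolerance = 1e-3)
  expect_error(davies_gamma(1, -0.1), "non-negative")

  # gamma non-increasing in |z| at fixed I, equal to 1 at z = 0
  for (I in c(0.001, 0.01, 0.05, 0.1)) {
    g <- davies_gamma(0:3, I)
    expect_identical(g[1], 1)
    expect_true(all(diff(g) < 0))
  }

  # containment in the working-range values at printed (2 dp) precision
  for (I in c(0.015, 0.03)) {
    expect_gte(round(davies_gamma(1, I), 2), 0.84)
    expect_lte(round(davies_gamma(1, I), 2), 0.89)
    expect_gte(round(davies_gamma(2, I), 2), 0.50)
    expect_lte(round(davies_gamma(2, I), 2), 0.62)
    expect_gte(round(davies_gamma(3, I), 2), 0.21)
    expect_lte(round(davies_gamma(3, I), 2), 0.33)
  }
})

test_that("activities combine gamma and concentration with c0 = 1 M", {
  inv <- ion_inventory(c(ca_free = 1e-4 * 0.05, na = 0.02 * 0.05),
                       volume_l = 0.05)
  act <- activities(inv, ionic_strength = 0.02)
  a_ca <- act$activity[act$species == "ca_free"]
  # gamma(2) = gamma(1)^4 under Davies
  expect_equal(a_ca, davies_gamma(1, 0.02)^4 * 1e-4, tolerance = 1e-10)
  expect_equal(a_ca, 5.75e-5, tolerance = 1e-2)
  # zero amount -> zero activity; neutral species -> activity = concentration
  expect_equal(act$activity[act$species == "po4"], 0)
  inv2 <- ion_inventory(c(cahpo4 = 0.001), volume_l = 1)
  act2 <- activities(inv2, ionic_strength = 0.05)
  expect_equal(act2$activity[act2$species == "cahpo4"], 0.001)
})

test_that("equilibrate reduces to the free-speciation limits", {
  # no calcium: no pairs, phosphate split matches phosphate_fractions
  eq <- equilibrate(0, 5e-4, 8.3, k_revised, acid_default, volume_l = 0.05)
  expect_equal(eq$ca_bound_mol, 0)
  expect_equal(eq$n_cah2po4 + eq$n_cahpo4 + eq$n_capo4, 0)
  st <- speciation_state(0, 5e-4, 8.3, k_revised, acid_default,
                         volume_l = 0.05)
  f <- phosphate_fractions(8.3, acid_default)
  inv <- st$inventory
  expect_equal(inv$amount_mol[inv$species == "hpo4"] / 5e-4, f$f_hpo4,
               tolerance = 1e-12)
  # zero constants: free calcium equals the total
  eq0 <- equilibrate(1e-4, 5e-4, 8.3, binding_constants(0, 0, 0),
                     acid_default, volume_l = 0.05)
  expect_equal(eq0$ca_free_mol, 1e-4)
})

test_that("equilibrate agrees with a brute-force fixed-point oracle", {
  eq <- equilibrate(1e-4, 5e-4, 8.3, k_revised, acid_default,
                    volume_l = 0.05, na_mol = 8e-4)
  or <- oracle_fixed_point(1e-4, 5e-4, 8.3, 0.05, k_revised, acid_default,
                           na = 8e-4)
  expect_equal(eq$ca_bound_mol, or$bound, tolerance = 1e-8)
  expect_equal(eq$ionic_strength, or$I, tolerance = 1e-8)
  expect_equal(c(eq$n_cah2po4, eq$n_cahpo4, eq$n_capo4), or$n,
               tolerance = 1e-8)
})

test_that("equilibrate conserves calcium and phosphate mass", {
  set.seed(7)
  for (i in 1:50) {
    n_ca <- stats::runif(1, 0, 2e-4)
    n_p <- stats::runif(1, 1e-4, 1e-3)
    ph <- stats::runif(1, 3, 11.5)
    eq <- equilibrate(n_ca, n_p, ph, k_revised, acid_default,
                      volume_l = 0.05, na_mol = 1e-3)
    pairs <- eq$n_cah2po4 + eq$n_cahpo4 + eq$n_capo4
    expect_equal(eq$ca_free_mol + pairs, n_ca, tolerance = 1e-12)
    expect_equal(eq$p_free_mol + pairs, n_p, tolerance = 1e-12)
    expect_equal(eq$ca_bound_mol, pairs, tolerance = 1e-12)
  }
})
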