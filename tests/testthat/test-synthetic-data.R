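test_that("protocol and artifact constructors validate their fields", {
  expect_s3_class(titration_protocol(), "titration_protocol")
  expect_error(titration_protocol(buffer_conc = -1), "positive")
  expect_error(titration_protocol(replicates = 0), ">= 1")
  expect_error(artifact_model(enrichment = 0.5), ">= 1")
  expect_error(artifact_model(sequestered_fraction = 1.5), "0, 1")
})

test_that("zero binding and zero noise reproduce the no-binding line", {
  sim <- simulate_titration(small_protocol(9.8, n_steps = 15),
                            binding_constants(0, 0, 0), acid_default,
                            noise_cv = 0)
  expect_equal(sim$free_ca_mol_per_l, sim$added_ca_mol / sim$volume_l,
               tolerance = 1e-12)
})

test_that("simulation is bit-reproducible from the seed", {
  p <- small_protocol(9.8, n_steps = 15, replicates = 2, seed = 99)
  s1 <- simulate_titration(p, k_revised, acid_default, noise_cv = 0.01)
  s2 <- simulate_titration(p, k_revised, acid_default, noise_cv = 0.01)
  expect_identical(s1, s2)
  p2 <- p; p2$seed <- 100L
  s3 <- simulate_titration(p2, k_revised, acid_default, noise_cv = 0.01)
  expect_false(identical(s1$free_ca_mol_per_l, s3$free_ca_mol_per_l))
})

test_that("generated curves satisfy the titration-curve invariants", {
  for (ph in c(4.3, 8.3, 11.3)) {
    sim <- simulate_titration(small_protocol(ph, n_steps = 20,
                                             replicates = 2),
                              k_revised, acid_default, noise_cv = 0.02)
    expect_silent(validate_titration_curve(sim))
  }
})

test_that("replicate noise averages back to the noise-free curve", {
  p <- small_protocol(9.8, n_steps = 20, replicates = 120, seed = 5)
  noisy <- simulate_titration(p, k_revised, acid_default, noise_cv = 0.01)
  clean <- simulate_titration(small_protocol(9.8, n_steps = 20),
                              k_revised, acid_default, noise_cv = 0)
  avg <- tapply(noisy$free_ca_mol_per_l, noisy$added_ca_mol, mean)
  rel <- abs(avg - clean$free_ca_mol_per_l) / clean$free_ca_mol_per_l
  expect_lt(max(rel), 0.01 / sqrt(120) * 3)
})

test_that("the dosing-tip artifact depresses and de-linearises the curve", {
  p <- small_protocol(9.8, n_steps = 40)
  clean <- simulate_titration(p, k_revised, acid_default, noise_cv = 0)
  art <- simulate_titration(p, k_revised, acid_default, noise_cv = 0,
                            artifact = artifact_model("premature_separation"))
  m <- seq_len(min(nrow(clean), nrow(art)))
  expect_true(all(art$free_ca_mol_per_l[m] <=
                    clean$free_ca_mol_per_l[m] + 1e-15))
  expect_gt(max(art$sequestered_ca_mol), 0)
  # apparent binding is inflated: the pre-nucleation slope drops
  expect_lt(prenucleation_slope(art)$slope,
            prenucleation_slope(clean)$slope - 0.05)
  # sequestration conserves mass: solution + sequestered = dosed
  in_solution <- art$free_ca_mol_per_l * art$volume_l + art$ca_bound_mol
  expect_equal(in_solution + art$sequestered_ca_mol, art$added_ca_mol,
               tolerance = 1e-12)
})

test_that("acid-titration generator is seeded and matches its pKa inputs", {
  a1 <- simulate_acid_titration(n_steps = 50, noise_sd = 0.01, seed = 3)
  a2 <- simulate_acid_titration(n_steps = 50, noise_sd = 0.01, seed = 3)
  expect_identical(a1, a2)
  # round trip: half-equivalence pH values equal the generator's constants
  full <- simulate_acid_titration(n_steps = 300)
  est <- estimate_pka(full)
  expect_lt(max(abs(est$pka - c(2.58, 6.98))), 0.01)
  # near-strong first step: low pKa1 pushes the first buffer region away
  strong <- simulate_acid_titration(acid = acid_constants(pka1 = 1.2),
                                    n_steps = 300)
  expect_lt(strong$ph[1], full$ph[1])
  v_eq <- find_equivalence_points(strong, 2)
  expect_equal(v_eq[1], 5, tolerance = 0.02)
})
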