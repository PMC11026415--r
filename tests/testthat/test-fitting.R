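test_that("direct K1 inverts the generating model exactly on clean data", {
  prot <- small_protocol(4.3, n_steps = 25)
  sim <- simulate_titration(prot, binding_constants(4.5, 0, 0),
                            acid_default, noise_cv = 0)
  est <- fit_k1_direct(sim, acid_default, prot)
  expect_equal(est$k1, 4.5, tolerance = 1e-6)
  expect_lt(est$k1_sd, 1e-5)
})

test_that("direct K1 carries a bounded attribution bias under full binding", {
  # with all three pairs active ~10-15% of the pH 4.3 binding is the
  # neutral pair; attributing everything to K1 inflates it, but the
  # estimate stays inside the reported +-2.4 uncertainty
  prot <- small_protocol(4.3, n_steps = 25)
  sim <- simulate_titration(prot, binding_preset("revised_25C"),
                            acid_default, noise_cv = 0)
  est <- fit_k1_direct(sim, acid_default, prot)
  expect_gt(est$k1, 4.5)
  expect_lt(abs(est$k1 - 4.5), 2.4)
})

test_that("direct K1 is unbiased to within 10% under 1% electrode noise", {
  prot <- small_protocol(4.3, n_steps = 25, replicates = 3)
  k1s <- vapply(1:100, function(seed) {
    p <- prot; p$seed <- seed
    sim <- simulate_titration(p, binding_constants(4.5, 0, 0),
                              acid_default, noise_cv = 0.01)
    suppressWarnings(mean(vapply(split_replicates(sim), function(cc)
      fit_k1_direct(cc, acid_default, p)$k1, numeric(1))))
  }, numeric(1))
  expect_lt(abs(mean(k1s) - 4.5) / 4.5, 0.10)
})

test_that("direct K1 handles zero binding and inconsistent points", {
  prot <- small_protocol(4.3, n_steps = 15)
  sim <- simulate_titration(prot, binding_constants(1e-9, 0, 0),
                            acid_default, noise_cv = 0)
  est <- fit_k1_direct(sim, acid_default, prot)
  expect_lt(abs(est$k1), 1e-6)
  # a curve identically on the no-binding line has no usable point
  free <- c(1, 2, 3) * 1e-5
  sim3 <- tibble::tibble(replicate = "r1", added_ca_mol = free * 0.05,
                         free_ca_mol_per_l = free, ph = 4.3,
                         volume_l = 0.05, temperature_k = 298.15)
  expect_warning(expect_error(fit_k1_direct(sim3, acid_default, prot),
                              "No usable points"), "Skipping")
  expect_error(fit_k1_direct(dplyr::mutate(sim, ph = 8), acid_default, prot),
               "pH <= 5")
})

test_that("global fit recovers the generating constants from clean curves", {
  prot <- titration_protocol(n_steps = 40)
  sims <- lapply(c(8.3, 9.8, 10.8, 11.3), function(ph)
    simulate_titration(small_protocol(ph, n_steps = 40),
                       binding_preset("revised_25C"), acid_default,
                       noise_cv = 0))
  fit <- fit_binding_constants(dplyr::bind_rows(sims), fix_k1 = 4.5,
                               init = binding_constants(5, 300, 3e4),
                               protocol = prot)
  expect_lt(abs(fit$estimates$k2 - 470) / 470, 1e-3)
  expect_lt(abs(fit$estimates$k3 - 50000) / 50000, 1e-3)
  expect_equal(fit$convergence, 0L)
  td <- tidy(fit)
  expect_identical(td$term, c("K1", "K2", "K3"))
  expect_identical(td$source[1], "fixed")
  gl <- glance(fit)
  expect_identical(gl$n_ph, 4L)
  expect_lt(gl$sse, 1e-18)
})

test_that("K3 is flagged unidentifiable without high-pH curves", {
  sims <- lapply(c(6.3, 6.8), function(ph)
    simulate_titration(small_protocol(ph, n_steps = 12),
                       binding_preset("revised_25C"), acid_default,
                       noise_cv = 0))
  expect_warning(
    fit_binding_constants(dplyr::bind_rows(sims), fix_k1 = 4.5,
                          init = binding_preset("revised_25C"),
                          protocol = titration_protocol(n_steps = 12),
                          n_starts = 1, reltol = 1e-6),
    "weakly identifiable")
})

test_that("fit is invariant to curve ordering", {
  sims <- lapply(c(8.3, 10.8), function(ph)
    simulate_titration(small_protocol(ph, n_steps = 15),
                       binding_preset("revised_25C"), acid_default,
                       noise_cv = 0))
  prot <- titration_protocol(n_steps = 15)
  f1 <- fit_binding_constants(dplyr::bind_rows(sims), fix_k1 = 4.5,
                              init = binding_constants(5, 300, 3e4),
                              protocol = prot, n_starts = 1)
  f2 <- fit_binding_constants(dplyr::bind_rows(rev(sims)), fix_k1 = 4.5,
                              init = binding_constants(5, 300, 3e4),
                              protocol = prot, n_starts = 1)
  expect_equal(f1$estimates$k2, f2$estimates$k2, tolerance = 1e-8)
  expect_equal(f1$estimates$k3, f2$estimates$k3, tolerance = 1e-8)
})

test_that("stochastic recovery stays within the reported error bounds", {
  # reduced-size recovery study: duplicate curves at three pH values per set
  prot25 <- titration_protocol(n_steps = 20)
  res <- t(vapply(1:25, function(seed) {
    sims <- lapply(c(8.3, 10.8, 11.3), function(ph)
      simulate_titration(small_protocol(ph, n_steps = 20, replicates = 2,
                                        seed = 1000 + seed),
                         binding_preset("revised_25C"), acid_default,
                         noise_cv = 0.01))
    fit <- fit_binding_constants(dplyr::bind_rows(sims), fix_k1 = 4.5,
                                 init = binding_constants(4.5, 350, 4e4),
                                 protocol = prot25, n_starts = 1,
                                 reltol = 1e-9)
    c(fit$estimates$k2, fit$estimates$k3)
  }, numeric(2)))
  expect_lt(abs(stats::median(res[, 1]) - 470), 50)
  expect_lt(abs(stats::median(res[, 2]) - 50000), 8000)
})

test_that("tolerance-scan error bounds bracket the optimum", {
  sims <- lapply(c(8.3, 10.8, 11.3), function(ph)
    simulate_titration(small_protocol(ph, n_steps = 15, replicates = 2),
                       binding_preset("revised_25C"), acid_default,
                       noise_cv = 0.01))
  curves <- dplyr::bind_rows(sims)
  prot <- titration_protocol(n_steps = 15)
  fit <- fit_binding_constants(curves, fix_k1 = 4.5,
                               init = binding_constants(5, 400, 4e4),
                               protocol = prot, n_starts = 1)
  fit <- binding_error_bounds(fit, curves, tolerance = 0.05,
                              span = 0.8, n_grid = 8)
  b <- fit$bounds
  expect_true(all(b$lower[2:3] <= c(fit$estimates$k2, fit$estimates$k3)))
  expect_true(all(b$upper[2:3] >= c(fit$estimates$k2, fit$estimates$k3)))
  # K2/K3 are well identified here: two-sided, sensible magnitudes
  expect_false(any(b$one_sided[2:3]))
  expect_lt(b$half_width[3], 50000)
  td <- tidy(fit)
  expect_true(all(c("lower", "upper") %in% names(td)))
})
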