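test_that("titration-curve validation reports the offending row", {
  good <- tibble::tibble(replicate = "r1", added_ca_mol = c(1, 2, 3) * 1e-6,
                         free_ca_mol_per_l = c(1, 2, 3) * 1e-5,
                         ph = 8.3, volume_l = 0.05, temperature_k = 298.15)
  expect_silent(validate_titration_curve(good))
  bad <- good
  bad$free_ca_mol_per_l[2] <- bad$added_ca_mol[2] / bad$volume_l[2] * 1.01
  expect_error(validate_titration_curve(bad), "Row 2.*no-binding")
  bad2 <- good
  bad2$added_ca_mol[3] <- bad2$added_ca_mol[2]
  expect_error(validate_titration_curve(bad2), "Row 3.*increasing")
})

test_that("direct model reduces to the no-binding limit when K = 0", {
  out <- direct_free_calcium(1e-5, 1.9e-4, 5e-4, 9.8, 0.05,
                             binding_constants(0, 0, 0), acid_default,
                             na_mol = 1e-3)
  expect_equal(out$free_ca_pred_mol_per_l, 1e-5 / 0.05, tolerance = 1e-12)
  expect_equal(out$a_ca_pred,
               davies_gamma(2, out$ionic_strength) * 1e-5 / 0.05,
               tolerance = 1e-12)
  expect_error(
    direct_free_calcium(1e-5, 3e-4, 5e-4, 9.8, 0.05, k_revised),
    "negative")
})

test_that("direct model inverts noise-free predictive curves (round trip)", {
  for (ph in c(4.3, 8.3, 10.8)) {
    pc <- predict_curve(small_protocol(ph, n_steps = 15), k_revised,
                        acid_default)
    out <- direct_free_calcium(pc$added_ca_mol, pc$free_ca_mol_per_l,
                               pc$total_p_mol[1], ph, pc$volume_l,
                               k_revised, acid_default,
                               na_mol = pc$na_mol, cl_mol = pc$cl_mol)
    expect_equal(out$free_ca_pred_mol_per_l, pc$free_ca_mol_per_l,
                 tolerance = 1e-8)
    # mole balance across the predicted pairs
    expect_equal(out$n_cah2po4 + out$n_cahpo4 + out$n_capo4,
                 pc$added_ca_mol - out$free_ca_pred_mol_per_l * pc$volume_l,
                 tolerance = 1e-10)
  }
})

test_that("single-pair conditions match the analytic quadratic", {
  # pH 4.3 with only K1 active: b solves a quadratic in closed form
  ph <- 4.3; v <- 0.05; n_ca <- 1e-4; n_p <- 5e-4
  k1 <- 4.5
  k <- binding_constants(k1, 0, 0)
  eq <- equilibrate(n_ca, n_p, ph, k, acid_default, volume_l = v,
                    na_mol = 1e-4)
  # analytic solution at the converged gammas (independent algebra)
  f2 <- phosphate_fractions(ph, acid_default)$f_h2po4
  g2 <- eq$gamma2
  alpha <- g2 * k1 * f2 / v   # gamma_anion/gamma_pair = 1 for the +1 pair
  b <- ((alpha * (n_ca + n_p) + 1) -
          sqrt((alpha * (n_ca + n_p) + 1)^2 - 4 * alpha^2 * n_ca * n_p)) /
    (2 * alpha)
  expect_equal(eq$ca_bound_mol, b, tolerance = 1e-10)
  ps <- predictive_solve(n_ca, n_p, ph, v, k, acid_default, na_mol = 1e-4)
  expect_equal(ps$ca_bound_mol, b, tolerance = 1e-10)
})

test_that("predictive solve satisfies its residuals and the mass balances", {
  set.seed(3)
  for (i in 1:25) {
    n_ca <- stats::runif(1, 1e-6, 2e-4)
    n_p <- stats::runif(1, 1e-4, 1e-3)
    ph <- stats::runif(1, 3, 11.5)
    ps <- predictive_solve(n_ca, n_p, ph, 0.05, k_revised, acid_default,
                           na_mol = 1e-3)
    expect_lt(ps$residual, 1e-10)
    expect_true(all(c(ps$n_cah2po4, ps$n_cahpo4, ps$n_capo4) >= 0))
    expect_equal(ps$ca_bound_mol + ps$ca_free_mol, n_ca, tolerance = 1e-12)
    expect_lte(ps$ca_bound_mol, min(n_ca, n_p) * (1 + 1e-12))
  }
  ps0 <- predictive_solve(1e-4, 5e-4, 8.3, 0.05, binding_constants(0, 0, 0))
  expect_equal(ps0$ca_free_mol, 1e-4)
})

test_that("predictive solve and equilibrate agree (dual formulations)", {
  for (ph in c(8.3, 9.3, 10.3, 11.3)) {
    eq <- equilibrate(1.2e-4, 5e-4, ph, k_revised, acid_default,
                      volume_l = 0.052, na_mol = 9e-4, cl_mol = 2e-4)
    ps <- predictive_solve(1.2e-4, 5e-4, ph, 0.052, k_revised, acid_default,
                           na_mol = 9e-4, cl_mol = 2e-4)
    expect_equal(ps$ca_bound_mol, eq$ca_bound_mol, tolerance = 1e-8)
  }
  # with frozen gammas handed over, agreement is to solver precision
  eq <- equilibrate(1e-4, 5e-4, 9.8, k_revised, acid_default,
                    volume_l = 0.05, na_mol = 9e-4)
  ps <- predictive_solve(1e-4, 5e-4, 9.8, 0.05, k_revised, acid_default,
                         gammas = c(eq$gamma1, eq$gamma2, eq$gamma3))
  expect_equal(ps$ca_bound_mol, eq$ca_bound_mol, tolerance = 1e-10)
})

test_that("predicted free calcium decreases weakly in each constant", {
  base <- c(4.5, 470, 50000)
  for (i in 1:3) {
    kv <- base; kv[i] <- kv[i] * 10
    eq1 <- equilibrate(1e-4, 5e-4, 9.8, do.call(binding_constants, as.list(base)),
                       acid_default, volume_l = 0.05, na_mol = 9e-4)
    eq2 <- equilibrate(1e-4, 5e-4, 9.8, do.call(binding_constants, as.list(kv)),
                       acid_default, volume_l = 0.05, na_mol = 9e-4)
    expect_lte(eq2$ca_free_mol, eq1$ca_free_mol)
  }
})

test_that("predicted curves sit below the no-binding line and are quasi-static", {
  expect_equal(nrow(predict_curve(small_protocol(9.8, n_steps = 0),
                                  k_revised)), 0)
  pc <- predict_curve(small_protocol(9.8, n_steps = 20), k_revised)
  expect_true(all(pc$free_ca_mol_per_l < pc$added_ca_mol / pc$volume_l))
  # doubling the dose rate leaves the curve as a function of added Ca alone
  fast <- small_protocol(9.8, n_steps = 20)
  fast$dose_rate_ml_min <- fast$dose_rate_ml_min * 2
  pc2 <- predict_curve(fast, k_revised)
  expect_equal(pc2$free_ca_mol_per_l, pc$free_ca_mol_per_l, tolerance = 1e-14)
})

test_that("pre-nucleation slope recovers limiting and analytic values", {
  base <- tibble::tibble(replicate = "r1", added_ca_mol = (1:20) * 1e-6,
                         ph = 4.3, volume_l = 0.05, temperature_k = 298.15)
  ident <- base
  ident$free_ca_mol_per_l <- ident$added_ca_mol / ident$volume_l
  expect_equal(prenucleation_slope(ident)$slope, 1, tolerance = 1e-12)
  bound <- base
  bound$free_ca_mol_per_l <- 0
  expect_equal(prenucleation_slope(bound)$slope, 0, tolerance = 1e-12)
  expect_error(prenucleation_slope(base[1:2, ]), "at least 3")

  # analytic slope of the one-pair closed form at pH 4.3, K1 = 4.5: the
  # anion and pair coefficients cancel (both |z| = 1), leaving
  # free/added -> 1/(1 + gamma_Ca K1 f_H2PO4 c_P) in the dilute-Ca limit
  pc <- predict_curve(small_protocol(4.3, n_steps = 20),
                      binding_constants(4.5, 0, 0), acid_default)
  sl <- prenucleation_slope(pc)$slope
  f2 <- phosphate_fractions(4.3, acid_default)$f_h2po4
  g <- davies_gamma(1:2, mean(pc$ionic_strength))
  s_analytic <- 1 / (1 + g[2] * 4.5 * f2 *
                       (pc$total_p_mol[1] / mean(pc$volume_l)))
  expect_equal(sl, s_analytic, tolerance = 0.02)
})

test_that("truncation finds the pre-nucleation prefix", {
  pc <- predict_curve(small_protocol(9.8, n_steps = 30), k_revised)
  expect_identical(nrow(truncate_prenucleation(pc)), 30L)
  # nucleation drop injected at a known dose index
  drop_at <- 22
  pc2 <- pc
  idx <- drop_at:nrow(pc2)
  pc2$free_ca_mol_per_l[idx] <- pc2$free_ca_mol_per_l[drop_at - 1] *
    exp(-0.25 * seq_along(idx))
  tr <- truncate_prenucleation(pc2, window = 10, threshold = 0.01)
  expect_lte(abs(nrow(tr) - drop_at), 10)
  # convex curve with no linear regime signals an empty regime
  conv <- pc
  conv$free_ca_mol_per_l <- (seq_len(30))^2 * 1e-7
  expect_error(truncate_prenucleation(conv, window = 10, threshold = 1e-4),
               class = "capion_empty_regime")
  expect_error(truncate_prenucleation(pc[1:5, ], window = 10), "at least")
})
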