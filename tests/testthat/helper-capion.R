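# Shared fixtures: the revised/legacy constant sets and small protocols used
# throughout the suite. Everything is generated in code; no data files.

k_revised <- binding_preset("revised_25C")
k_revised37 <- binding_preset("revised_37C")
k_legacy <- binding_preset("legacy_25C")
acid_default <- acid_constants()

small_protocol <- function(ph, n_steps = 25, replicates = 1, seed = 1L, ...) {
  titration_protocol(target_ph = ph, n_steps = n_steps,
                     replicates = replicates, seed = seed, ...)
}

# Independent brute-force oracle for the coupled pair equilibria: plain
# fixed-point iteration on the three pair amounts (no quadratic, no Newton),
# with the Davies coefficients refreshed from the inventory each sweep.
oracle_fixed_point <- function(n_ca, n_p, ph, v, k, acid, na = 0, cl = 0,
                               iters = 20000) {
  f <- capion::phosphate_fractions(ph, acid)
  fr <- c(f$f_h3po4, f$f_h2po4, f$f_hpo4, f$f_po4)
  kk <- c(k$k1, k$k2, k$k3)
  n <- c(0, 0, 0)
  I <- 0
  for (i in seq_len(iters)) {
    g <- capion::davies_gamma(1:3, I)
    nb <- sum(n)
    ca_free <- n_ca - nb
    p_free <- n_p - nb
    a_ca <- g[2] * ca_free / v
    a_an <- c(g[1] * fr[2], g[2] * fr[3], g[3] * fr[4]) * p_free / v
    g_pair <- c(g[1], 1, g[1])
    n_new <- kk * a_ca * a_an / g_pair * v
    ch <- 10^(-ph) / g[1]
    coh <- 10^(-(acid$pkw - ph)) / g[1]
    I_new <- 0.5 * ((na + cl) / v + 4 * ca_free / v +
                      (fr[2] + 4 * fr[3] + 9 * fr[4]) * p_free / v +
                      (n_new[1] + n_new[3]) / v + ch + coh)
    if (max(abs(n_new - n)) < 1e-18 && abs(I_new - I) < 1e-16) {
      n <- n_new
      break
    }
    n <- 0.5 * n + 0.5 * n_new
    I <- 0.5 * I + 0.5 * I_new
  }
  list(n = n, bound = sum(n), I = I)
}
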