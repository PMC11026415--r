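# ---------------------------------------------------------------------------
# Titration protocol and artifact descriptions
# ---------------------------------------------------------------------------

#' Describe a calcium-into-phosphate titration protocol
#'
#' The default protocol mirrors the potentiometric setup the package
#' emulates: 0.005 M CaCl2 titrant dosed at 0.01 mL/min into 50.00 g of
#' 0.010 M phosphate buffer held at constant pH by counter-titration with
#' 0.1 M NaOH/HCl, in triplicate, with the titrant acidified (0.05 M HCl) to
#' suppress phase separation at the dosing tip. Buffer mass is converted to
#' volume with a dilute-aqueous density of 1.000 g/mL.
#'
#' @param buffer_mass_g Buffer mass, grams.
#' @param buffer_conc Total phosphate concentration of the buffer, mol/L.
#' @param buffer_density_g_ml Buffer density used for the mass-to-volume
#'   conversion, g/mL.
#' @param titrant_conc CaCl2 titrant concentration, mol/L.
#' @param titrant_hcl_conc HCl concentration in the acidified titrant, mol/L.
#' @param acidified_titrant Whether the titrant carries the HCl spike.
#' @param dose_rate_ml_min Dosing rate, mL/min (kept for provenance; the
#'   pre-nucleation equilibria are quasi-static and rate-independent).
#' @param dose_step_ml Titrant volume per recorded dose step, mL.
#' @param n_steps Number of dose steps.
#' @param target_ph Constant pH held by the counter-titration.
#' @param temperature_k Temperature, kelvin.
#' @param counter_conc Counter-titrant (NaOH/HCl) concentration, mol/L.
#' @param replicates Number of replicate curves to simulate.
#' @param seed RNG seed for the simulator.
#'
#' @return An object of class `titration_protocol`.
#' @export
#' @examples
#' titration_protocol(target_ph = 9.8)
titration_protocol <- function(buffer_mass_g = 50.00,
                               buffer_conc = 0.010,
                               buffer_density_g_ml = 1.000,
                               titrant_conc = 0.005,
                               titrant_hcl_conc = 0.05,
                               acidified_titrant = TRUE,
                               dose_rate_ml_min = 0.01,
                               dose_step_ml = 0.04,
                               n_steps = 50,
                               target_ph = 9.8,
                               temperature_k = 298.15,
                               counter_conc = 0.1,
                               replicates = 3,
                               seed = 1L) {
  p <- list(buffer_mass_g = buffer_mass_g, buffer_conc = buffer_conc,
            buffer_density_g_ml = buffer_density_g_ml,
            titrant_conc = titrant_conc, titrant_hcl_conc = titrant_hcl_conc,
            acidified_titrant = acidified_titrant,
            dose_rate_ml_min = dose_rate_ml_min,
            dose_step_ml = dose_step_ml, n_steps = n_steps,
            target_ph = target_ph, temperature_k = temperature_k,
            counter_conc = counter_conc, replicates = replicates,
            seed = as.integer(seed))
  pos <- c("buffer_mass_g", "buffer_conc", "buffer_density_g_ml",
           "titrant_conc", "dose_rate_ml_min", "dose_step_ml",
           "temperature_k", "counter_conc")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      abort(sprintf("`%s` must be a positive number.", nm))
    }
  }
  if (p$replicates < 1) abort("`replicates` must be >= 1.")
  if (p$n_steps < 0) abort("`n_steps` must be >= 0.")
  structure(p, class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "<titration_protocol> %.2f g of %.3g M phosphate buffer at pH %.2f, %s\n",
    x$buffer_mass_g, x$buffer_conc, x$target_ph,
    sprintf("%.3g M CaCl2 x %d steps of %.3g mL (%d replicate%s, %.2f K)",
            x$titrant_conc, x$n_steps, x$dose_step_ml, x$replicates,
            if (x$replicates > 1) "s" else "", x$temperature_k)))
  invisible(x)
}

#' Describe the dosing-tip phase-separation artifact
#'
#' Models the premature phase separation that can occur at the titrant
#' dosing tip: the locally overconcentrated calcium raises the local
#' ion-activity product (IAP); when the enriched IAP
#' `enrichment * a_Ca * (a_HPO4 + a_PO4)` exceeds `sequestration_iap`, a
#' fixed fraction of that dose's calcium (with matching phosphate) is
#' sequestered into a separated phase before it can equilibrate with the
#' bulk. A separate bulk-IAP cutoff ends the curve at nucleation proper.
#'
#' @param mode `"none"` or `"premature_separation"`.
#' @param enrichment Local overconcentration factor at the tip (>= 1).
#' @param sequestration_iap Enriched-IAP threshold above which dose-local
#'   sequestration occurs.
#' @param sequestered_fraction Fraction of the dose's calcium removed when
#'   the threshold is exceeded, in \[0, 1\].
#' @param nucleation_iap Bulk ion-activity product at which the curve is
#'   truncated (nucleation of solids).
#'
#' @return An object of class `artifact_model`.
#' @export
#' @examples
#' artifact_model("premature_separation")
artifact_model <- function(mode = c("none", "premature_separation"),
                           enrichment = 50,
                           sequestration_iap = 2.5e-7,
                           sequestered_fraction = 0.5,
                           nucleation_iap = 2.5e-7) {
  mode <- match.arg(mode)
  if (enrichment < 1) abort("`enrichment` must be >= 1.")
  if (sequestered_fraction < 0 || sequestered_fraction > 1) {
    abort("`sequestered_fraction` must lie in [0, 1].")
  }
  if (sequestration_iap <= 0 || nucleation_iap <= 0) {
    abort("IAP thresholds must be positive.")
  }
  structure(list(mode = mode, enrichment = enrichment,
                 sequestration_iap = sequestration_iap,
                 sequestered_fraction = sequestered_fraction,
                 nucleation_iap = nucleation_iap),
            class = "artifact_model")
}

# bulk ion-activity product used for both thresholds
bulk_iap <- function(eq, acid) {
  f <- phosphate_fractions_mat(eq$ph, acid)
  a_hpo4 <- eq$gamma2 * f[, 3] * eq$p_free_mol / eq$volume_l
  a_po4 <- eq$gamma3 * f[, 4] * eq$p_free_mol / eq$volume_l
  eq$a_ca * (a_hpo4 + a_po4)
}

# ---------------------------------------------------------------------------
# Calcium-into-phosphate titration simulator
# ---------------------------------------------------------------------------

#' Simulate calcium-into-phosphate titration curves
#'
#' Generates replicate titration curves with the chemical and statistical
#' structure the analysis assumes: per dose step the totals and volume are
#' updated (titrant, optional acidification, stoichiometric counter-titrant),
#' the solution is equilibrated self-consistently, multiplicative log-normal
#' noise with coefficient of variation `noise_cv` is applied to the
#' free-calcium electrode reading, and the curve ends at the bulk nucleation
#' cutoff. In artifact mode, doses whose locally enriched ion-activity
#' product exceeds the sequestration threshold lose a fixed fraction of their
#' calcium (and matching phosphate) to a separated phase before
#' equilibration; sequestered amounts are returned for mass accounting.
#'
#' Reproducible: the same protocol seed yields bit-identical curves.
#'
#' @param protocol A [titration_protocol()].
#' @param k A [binding_constants()] object (generator truth).
#' @param acid An [acid_constants()] object.
#' @param noise_cv Coefficient of variation of the multiplicative ISE noise
#'   (0 disables noise).
#' @param artifact An [artifact_model()].
#'
#' @return A titration-curve tibble over all replicates, with extra columns
#'   `free_ca_true_mol_per_l` (noise-free reading), `sequestered_ca_mol`,
#'   `sequestered_p_mol` (cumulative), and the model bookkeeping columns of
#'   [predict_curve()].
#' @export
#' @examples
#' sim <- simulate_titration(titration_protocol(n_steps = 10, replicates = 1),
#'                           k = binding_preset("revised_25C"))
simulate_titration <- function(protocol, k, acid = acid_constants(),
                               noise_cv = 0.01,
                               artifact = artifact_model("none")) {
  p <- protocol
  if (!inherits(p, "titration_protocol")) {
    abort("`protocol` must be a titration_protocol().")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  path <- if (artifact$mode == "none") {
    pc <- run_schedule(p, k, acid)
    pc$sequestered_ca_mol <- 0
    pc$sequestered_p_mol <- 0
    pc
  } else {
    run_schedule_artifact(p, k, acid, artifact)
  }
  # truncate at the bulk nucleation cutoff
  f <- phosphate_fractions_mat(p$target_ph, acid)
  a_hpo4 <- path$gamma2 * f[3] * path$p_free_mol / path$volume_l
  a_po4 <- path$gamma3 * f[4] * path$p_free_mol / path$volume_l
  iap <- path$a_ca * (a_hpo4 + a_po4)
  over <- which(iap > artifact$nucleation_iap)
  if (length(over)) path <- path[seq_len(over[1] - 1), ]
  if (nrow(path) == 0) {
    abort("Nucleation cutoff reached before the first dose step.")
  }

  # replicates differ only in the electrode-noise stream
  sdlog <- sqrt(log1p(noise_cv^2))
  reps <- vector("list", p$replicates)
  for (r in seq_len(p$replicates)) {
    cc <- path
    cc$replicate <- sprintf("rep%d", r)
    cc$free_ca_true_mol_per_l <- cc$free_ca_mol_per_l
    if (noise_cv > 0) {
      set.seed((p$seed %% 1000003L) * 17L + r)
      eps <- stats::rnorm(nrow(cc))
      # mean-unbiased multiplicative log-normal reading, clamped at the
      # no-binding line (the invariant any physical reading satisfies)
      cc$free_ca_mol_per_l <- pmin(
        cc$free_ca_mol_per_l * exp(sdlog * eps - sdlog^2 / 2),
        cc$added_ca_mol / cc$volume_l)
    }
    reps[[r]] <- cc
  }
  out <- dplyr::bind_rows(reps)
  validate_titration_curve(out, tol = 1e-9)
  out
}

# Sequential schedule with dose-local sequestration (artifact mode); the
# sequestered pool feeds back on later equilibria, so steps cannot be
# solved independently.
run_schedule_artifact <- function(p, k, acid, artifact) {
  init <- init_buffer(p, acid)
  v <- init$volume_l; na <- init$na_mol; cl <- init$cl_mol
  n_p <- init$n_p; ph <- p$target_ph
  f <- phosphate_fractions_mat(ph, acid)
  dv <- p$dose_step_ml / 1000
  n_ca <- 0; seq_ca <- 0; seq_p <- 0
  prev_ph_content <- init$proton_content
  cols <- c("added_ca_mol", "free_ca_mol_per_l", "volume_l", "ca_bound_mol",
            "n_cah2po4", "n_cahpo4", "n_capo4", "ionic_strength",
            "gamma1", "gamma2", "gamma3", "a_ca", "p_free_mol",
            "na_mol", "cl_mol", "sequestered_ca_mol", "sequestered_p_mol")
  m <- matrix(0, p$n_steps, length(cols), dimnames = list(NULL, cols))
  iap_of <- function(eq) {
    a_hpo4 <- eq$g2 * f[3] * eq$p_free / v
    a_po4 <- eq$g3 * f[4] * eq$p_free / v
    (eq$g2 * eq$ca_free / v) * (a_hpo4 + a_po4)
  }
  for (s in seq_len(p$n_steps)) {
    dosed_ca <- p$titrant_conc * dv
    n_ca <- n_ca + dosed_ca
    cl <- cl + 2 * dosed_ca
    hcl_dosed <- if (p$acidified_titrant) p$titrant_hcl_conc * dv else 0
    cl <- cl + hcl_dosed
    v <- v + dv
    eq <- eq_core(n_ca - seq_ca, n_p - seq_p, ph, v, k, acid, na, cl)
    if (artifact$enrichment * iap_of(eq) > artifact$sequestration_iap) {
      dca <- artifact$sequestered_fraction * dosed_ca
      seq_ca <- seq_ca + dca
      seq_p <- seq_p + min(dca, n_p - seq_p)
      eq <- eq_core(n_ca - seq_ca, n_p - seq_p, ph, v, k, acid, na, cl)
    }
    ph_content <- phosphate_proton_content(
      list(ph = ph, p_free_mol = eq$p_free,
           n_cah2po4 = eq$n1, n_cahpo4 = eq$n2), acid)
    released <- (prev_ph_content - ph_content) + hcl_dosed
    if (released > 0) {
      v <- v + released / p$counter_conc
      na <- na + released
    } else {
      v <- v - released / p$counter_conc
      cl <- cl - released
    }
    eq <- eq_core(n_ca - seq_ca, n_p - seq_p, ph, v, k, acid, na, cl)
    prev_ph_content <- phosphate_proton_content(
      list(ph = ph, p_free_mol = eq$p_free,
           n_cah2po4 = eq$n1, n_cahpo4 = eq$n2), acid)
    m[s, ] <- c(n_ca, eq$ca_free / v, v, eq$b, eq$n1, eq$n2, eq$n3,
                eq$I, eq$g1, eq$g2, eq$g3, eq$g2 * eq$ca_free / v,
                eq$p_free, na, cl, seq_ca, seq_p)
  }
  out <- as_tibble(as.data.frame(m))
  out$replicate <- "model"
  out$ph <- ph
  out$temperature_k <- p$temperature_k
  out$total_p_mol <- n_p
  out
}

# ---------------------------------------------------------------------------
# Phosphoric-acid titration simulator (pKa protocol)
# ---------------------------------------------------------------------------

#' Simulate a phosphoric-acid/NaOH titration curve
#'
#' Computes pH per dose from the exact proton/charge balance of the
#' H3PO4/NaOH system. The supplied [acid_constants()] are treated as
#' operational constants anchored to the working ionic-strength range
#' (I below about 0.05); at higher ionic strength a Davies-predicted drift
#' relative to that anchor is applied, reproducing the observed flattening
#' of the apparent pKa2 below I ~ 0.05 and its decrease above.
#'
#' @param acid An [acid_constants()] object (generator truth).
#' @param acid_conc Phosphoric-acid concentration, mol/L.
#' @param acid_volume_ml Initial acid volume, mL.
#' @param base_conc NaOH titrant concentration, mol/L.
#' @param dose_step_ml Base volume per dose step, mL.
#' @param n_steps Number of dose steps.
#' @param compensate_dilution If `TRUE`, co-dose `co_acid_conc` phosphoric
#'   acid at the same rate as the base (dilution compensation).
#' @param co_acid_conc Concentration of the co-dosed acid, mol/L.
#' @param nacl_mol Background NaCl amount for ionic-strength adjustment, mol.
#' @param noise_sd Gaussian noise standard deviation on the pH readings
#'   (0 disables noise).
#' @param seed RNG seed.
#'
#' @return A tibble of class columns `volume_ml` (added base) and `ph`, plus
#'   `ionic_strength`; attributes `base_conc` and `acid_mol` (initial acid
#'   amount).
#' @export
#' @examples
#' ac <- simulate_acid_titration(n_steps = 60)
simulate_acid_titration <- function(acid = acid_constants(),
                                    acid_conc = 0.010,
                                    acid_volume_ml = 50,
                                    base_conc = 0.1,
                                    dose_step_ml = 0.05,
                                    n_steps = 300,
                                    compensate_dilution = FALSE,
                                    co_acid_conc = 0.020,
                                    nacl_mol = 0,
                                    noise_sd = 0,
                                    seed = 1L) {
  if (acid_conc <= 0 || base_conc <= 0 || acid_volume_ml <= 0) {
    abort("Concentrations and volumes must be positive.")
  }
  v0 <- acid_volume_ml / 1000
  n_acid0 <- acid_conc * v0
  dvb <- dose_step_ml / 1000
  set.seed((as.integer(seed) %% 1000003L) * 29L + 7L)
  noise <- if (noise_sd > 0) stats::rnorm(n_steps + 1, 0, noise_sd) else
    numeric(n_steps + 1)

  vols <- numeric(n_steps + 1)
  phs <- numeric(n_steps + 1)
  ionic <- numeric(n_steps + 1)
  I <- 0
  for (s in 0:n_steps) {
    vb <- s * dvb
    n_base <- base_conc * vb
    n_acid <- n_acid0 + if (compensate_dilution) co_acid_conc * vb else 0
    v <- v0 + vb + if (compensate_dilution) vb else 0
    # two-pass ionic-strength refresh around the charge-balance root
    for (pass in 1:2) {
      eff <- effective_acid_at_I(acid, I)
      root <- stats::uniroot(
        function(ph) charge_balance_residual(ph, n_acid, n_base, nacl_mol,
                                             v, eff, I),
        interval = c(0.5, 13.9), tol = 1e-12)
      ph <- root$root
      I <- acid_titration_ionic_strength(ph, n_acid, n_base, nacl_mol, v, eff)
    }
    vols[s + 1] <- vb * 1000
    phs[s + 1] <- ph + noise[s + 1]
    ionic[s + 1] <- I
  }
  out <- tibble(volume_ml = vols, ph = phs, ionic_strength = ionic)
  attr(out, "base_conc") <- base_conc
  attr(out, "acid_mol") <- n_acid0
  attr(out, "acid_volume_ml") <- acid_volume_ml
  attr(out, "co_acid_conc") <- co_acid_conc
  attr(out, "compensate_dilution") <- compensate_dilution
  out
}

# Operational constants anchored below I_anchor; Davies-predicted drift
# relative to the anchor applies above it.
effective_acid_at_I <- function(acid, I, I_anchor = 0.05) {
  if (I <= I_anchor) return(acid)
  dterm <- function(x) sqrt(x) / (1 + sqrt(x)) - 0.3 * x
  d_excess <- dterm(I) - dterm(I_anchor)
  # mixed-constant shifts: pKa_j drift = -0.5085 * (z_A^2 - z_HA^2) * dD
  # steps 1..3 have (z_A^2 - z_HA^2) = 1, 3, 5
  acid_constants(
    pka1 = acid$pka1 - 0.5085 * 1 * d_excess,
    pka2 = acid$pka2 - 0.5085 * 3 * d_excess,
    pka3 = acid$pka3 - 0.5085 * 5 * d_excess,
    temperature = acid$temperature, pkw = acid$pkw
  )
}

charge_balance_residual <- function(ph, n_acid, n_base, nacl_mol, v, acid, I) {
  f <- phosphate_fractions_mat(ph, acid)
  g1 <- davies_gamma(1, I)
  ch <- 10^(-ph) / g1
  coh <- 10^(-(acid$pkw - ph)) / g1
  c_na <- (n_base + nacl_mol) / v
  c_cl <- nacl_mol / v
  c_p <- n_acid / v
  c_na + ch - coh - c_cl - (f[2] + 2 * f[3] + 3 * f[4]) * c_p
}

acid_titration_ionic_strength <- function(ph, n_acid, n_base, nacl_mol, v,
                                          acid) {
  f <- phosphate_fractions_mat(ph, acid)
  g1 <- davies_gamma(1, 0.02)  # mild approximation for the H/OH terms
  ch <- 10^(-ph) / g1
  coh <- 10^(-(acid$pkw - ph)) / g1
  c_p <- n_acid / v
  # Na+ = base + NaCl, Cl- = NaCl, both |z| = 1
  0.5 * ((n_base + 2 * nacl_mol) / v +
           (f[2] + 4 * f[3] + 9 * f[4]) * c_p + ch + coh)
}
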