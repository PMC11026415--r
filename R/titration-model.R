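# ---------------------------------------------------------------------------
# Titration curve container helpers
# ---------------------------------------------------------------------------

#' Validate a titration-curve table
#'
#' A titration curve is a tibble with one row per dose point and columns
#' `replicate`, `added_ca_mol`, `free_ca_mol_per_l`, `ph`, `volume_l`,
#' `temperature_k`. Within each replicate, added calcium must be strictly
#' increasing, the measured free-calcium concentration must not exceed the
#' no-binding line `added_ca_mol / volume_l`, and volume must be
#' non-decreasing.
#'
#' @param curve A data frame to validate.
#' @param tol Relative slack on the no-binding bound (measurement noise can
#'   graze the line).
#' @return The curve, invisibly, as a tibble; aborts with the offending row
#'   number otherwise.
#' @export
validate_titration_curve <- function(curve, tol = 1e-9) {
  required <- c("replicate", "added_ca_mol", "free_ca_mol_per_l", "ph",
                "volume_l", "temperature_k")
  missing <- setdiff(required, names(curve))
  if (length(missing)) {
    abort(paste0("Titration curve is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  curve <- as_tibble(curve)
  grp <- interaction(curve$replicate, curve$ph, drop = TRUE)
  for (rep_id in levels(grp)) {
    cc <- curve[grp == rep_id, ]
    rows <- which(grp == rep_id)
    if (any(diff(cc$added_ca_mol) <= 0)) {
      i <- rows[which(diff(cc$added_ca_mol) <= 0)[1] + 1]
      abort(sprintf("Row %d: added_ca_mol not strictly increasing.", i))
    }
    if (any(diff(cc$volume_l) < 0)) {
      i <- rows[which(diff(cc$volume_l) < 0)[1] + 1]
      abort(sprintf("Row %d: volume_l decreases.", i))
    }
    bad <- cc$free_ca_mol_per_l > cc$added_ca_mol / cc$volume_l * (1 + tol)
    if (any(bad)) {
      abort(sprintf(
        "Row %d: free calcium exceeds the no-binding line added/volume.",
        rows[which(bad)[1]]))
    }
    if (any(cc$free_ca_mol_per_l < 0)) {
      abort(sprintf("Row %d: negative free-calcium concentration.",
                    rows[which(cc$free_ca_mol_per_l < 0)[1]]))
    }
  }
  invisible(curve)
}

# ---------------------------------------------------------------------------
# Direct model: measured bound calcium -> predicted free-calcium activity
# ---------------------------------------------------------------------------

#' Direct-calculation model for free calcium
#'
#' The experimental-value-based model: the measured bound calcium
#' (`added - measured free`) fixes the free phosphate pool; the anion
#' activities follow from the pH speciation, and the free-calcium activity is
#' the exact algebraic solution of the resulting mole balance,
#' \deqn{a_{Ca} = \frac{\gamma_{Ca} n_{added}/V_t}{1 + \gamma_{Ca} S}, \quad
#'       S = \sum_i K_i a_{anion,i} / \gamma_{pair,i}.}
#' Activity coefficients are made self-consistent with the ionic strength of
#' the predicted state by damped fixed-point iteration.
#'
#' Vectorised over dose points (sharing one pH).
#'
#' @param added_ca_mol Added calcium per point, mol.
#' @param free_ca_meas_mol_per_l Measured free-calcium concentration, mol/L.
#' @param total_p_mol Total phosphate in solution, mol.
#' @param ph Fixed pH.
#' @param volume_l Total volume per point, litres.
#' @param k A [binding_constants()] object.
#' @param acid An [acid_constants()] object.
#' @param na_mol,cl_mol Background spectator amounts per point, mol.
#' @param tol,max_iter Fixed-point control on ionic strength.
#'
#' @return A tibble per point: predicted free-calcium activity `a_ca_pred`,
#'   concentration `free_ca_pred_mol_per_l`, the three pair amounts, the
#'   experimental bound amount used, and `ionic_strength`.
#' @export
direct_free_calcium <- function(added_ca_mol, free_ca_meas_mol_per_l,
                                total_p_mol, ph, volume_l, k,
                                acid = acid_constants(),
                                na_mol = 0, cl_mol = 0,
                                tol = 1e-12, max_iter = 300) {
  n <- max(length(added_ca_mol), length(free_ca_meas_mol_per_l),
           length(volume_l), length(na_mol), length(cl_mol))
  added_ca_mol <- rep_len(added_ca_mol, n)
  free_ca_meas_mol_per_l <- rep_len(free_ca_meas_mol_per_l, n)
  volume_l <- rep_len(volume_l, n)
  na_mol <- rep_len(na_mol, n); cl_mol <- rep_len(cl_mol, n)

  n_bound_expt <- added_ca_mol - free_ca_meas_mol_per_l * volume_l
  if (any(n_bound_expt < -1e-12 * pmax(added_ca_mol, 1e-300))) {
    abort("Inconsistent measurement: bound calcium (added - free) is negative.")
  }
  n_bound_expt <- pmax(n_bound_expt, 0)
  p_free <- total_p_mol - n_bound_expt
  if (any(p_free < 0)) {
    abort("Inconsistent measurement: bound calcium exceeds total phosphate.")
  }
  f <- phosphate_fractions_mat(rep_len(ph, 1), acid)

  I <- rep(0, n)
  for (it in seq_len(max_iter)) {
    g1 <- davies_gamma(1, I); g2 <- davies_gamma(2, I); g3 <- davies_gamma(3, I)
    a_h2po4 <- g1 * f[2] * p_free / volume_l
    a_hpo4 <- g2 * f[3] * p_free / volume_l
    a_po4 <- g3 * f[4] * p_free / volume_l
    S <- k$k1 * a_h2po4 / g1 + k$k2 * a_hpo4 / 1 + k$k3 * a_po4 / g1
    a_ca <- g2 * (added_ca_mol / volume_l) / (1 + g2 * S)
    free_pred <- a_ca / g2
    n1 <- k$k1 * a_ca * a_h2po4 / g1 * volume_l
    n2 <- k$k2 * a_ca * a_hpo4 * volume_l
    n3 <- k$k3 * a_ca * a_po4 / g1 * volume_l
    ch <- 10^(-ph) / g1
    coh <- 10^(-(acid$pkw - ph)) / g1
    I_new <- 0.5 * (
      (na_mol + cl_mol) / volume_l + 4 * free_pred +
        (f[2] + 4 * f[3] + 9 * f[4]) * p_free / volume_l +
        (n1 + n3) / volume_l + ch + coh
    )
    if (all(abs(I_new - I) / pmax(I_new, 1e-12) < tol)) {
      I <- I_new
      break
    }
    I <- 0.5 * I + 0.5 * I_new
    if (it == max_iter) {
      abort("direct_free_calcium: ionic-strength loop did not converge.")
    }
  }
  tibble(
    added_ca_mol = added_ca_mol,
    ca_bound_expt_mol = n_bound_expt,
    a_ca_pred = a_ca,
    free_ca_pred_mol_per_l = free_pred,
    n_cah2po4 = n1, n_cahpo4 = n2, n_capo4 = n3,
    ionic_strength = I
  )
}

# ---------------------------------------------------------------------------
# Predictive model: coupled mass-action solve from dosed amounts only
# ---------------------------------------------------------------------------

#' Predictive-calculation model: coupled mass-action solve
#'
#' Solves the three coupled ion-pair relations for the pair amounts
#' (n1, n2, n3) simultaneously at fixed activity coefficients, by damped
#' Newton iteration with an analytic Jacobian. The residual for each pair is
#' \deqn{n_i - c_i (n_{Ca,added} - n_b)(n_{P,total} - n_b), \quad
#'   c_i = \frac{K_i \gamma_{Ca} \gamma_{anion,i} f_i}{\gamma_{pair,i} V_t},}
#' with \eqn{n_b = n_1+n_2+n_3}. The physical root has every amount in
#' \eqn{[0, \min(n_{Ca}, n_P)]}; if the solver leaves that box it restarts
#' from 8 deterministic multi-start points.
#'
#' This routine is an independent formulation of the same equilibrium that
#' [equilibrate()] solves in closed form, and the two are cross-checked in
#' the package's tests.
#'
#' @param n_ca_added Added calcium, mol.
#' @param n_p_total Total phosphate, mol.
#' @param ph Fixed pH.
#' @param volume_l Total volume, litres.
#' @param k A [binding_constants()] object.
#' @param acid An [acid_constants()] object.
#' @param gammas Activity coefficients to use, as a numeric vector
#'   `c(gamma1, gamma2, gamma3)` for charge magnitudes 1-3, or an
#'   [activities()] result from which they are read. If `NULL`, coefficients
#'   are iterated to self-consistency with the solution's own ionic strength
#'   (spectator background via `na_mol`, `cl_mol`).
#' @param na_mol,cl_mol Background spectator amounts (only used when
#'   `gammas = NULL`).
#' @param tol Relative residual tolerance of the Newton solve.
#'
#' @return A one-row tibble: pair amounts `n_cah2po4`, `n_cahpo4`, `n_capo4`,
#'   `ca_bound_mol`, `ca_free_mol`, `free_ca_mol_per_l`, `a_ca`, the gammas
#'   used, and `residual` (max relative residual).
#' @export
predictive_solve <- function(n_ca_added, n_p_total, ph, volume_l, k,
                             acid = acid_constants(), gammas = NULL,
                             na_mol = 0, cl_mol = 0, tol = 1e-12) {
  stopifnot(length(n_ca_added) == 1, length(n_p_total) == 1)
  if (n_ca_added < 0 || n_p_total < 0) abort("Amounts must be non-negative.")
  f <- phosphate_fractions_mat(ph, acid)

  solve_at_gamma <- function(g) {
    g1 <- g[1]; g2 <- g[2]; g3 <- g[3]
    gam_anion <- c(g1, g2, g3)
    gam_pair <- c(g1, 1, g1)
    kk <- c(k$k1, k$k2, k$k3)
    cc <- kk * g2 * gam_anion * f[2:4] / (gam_pair * volume_l)
    lim <- min(n_ca_added, n_p_total)
    if (lim == 0 || sum(cc) == 0) {
      return(list(n = c(0, 0, 0), residual = 0))
    }
    newton <- function(n0) {
      nvec <- n0
      for (it in 1:200) {
        nb <- sum(nvec)
        resid <- nvec - cc * (n_ca_added - nb) * (n_p_total - nb)
        dcommon <- cc * ((n_p_total - nb) + (n_ca_added - nb))
        J <- diag(3) + matrix(dcommon, 3, 3)
        step <- tryCatch(solve(J, resid), error = function(e) NULL)
        if (is.null(step)) return(NULL)
        # damp to stay in the physical box
        lam <- 1
        repeat {
          cand <- nvec - lam * step
          if (all(cand >= 0) && sum(cand) <= lim || lam < 1e-8) break
          lam <- lam / 2
        }
        nvec <- pmax(nvec - lam * step, 0)
        if (sum(nvec) > lim) nvec <- nvec * lim / sum(nvec) * (1 - 1e-12)
        nb <- sum(nvec)
        rel <- abs(nvec - cc * (n_ca_added - nb) * (n_p_total - nb)) /
          pmax(nvec, lim * 1e-14)
        if (max(rel) < tol) return(list(n = nvec, residual = max(rel)))
      }
      NULL
    }
    starts <- c(0.1, 0.01, 0.3, 0.5, 0.7, 0.9, 0.001, 0.99)
    for (s in starts) {
      n0 <- cc / sum(cc) * s * lim
      out <- newton(n0)
      if (!is.null(out) && all(out$n >= 0) && sum(out$n) <= lim) return(out)
    }
    abort(sprintf(
      "predictive_solve: no physical root found (n_Ca = %g, n_P = %g, pH = %g).",
      n_ca_added, n_p_total, ph))
  }

  if (!is.null(gammas)) {
    if (is.data.frame(gammas)) {
      g <- vapply(1:3, function(z) gammas$gamma[match(z, abs(gammas$charge))],
                  numeric(1))
    } else {
      g <- rep_len(as.numeric(gammas), 3)
    }
    sol <- solve_at_gamma(g)
    I <- NA_real_
  } else {
    I <- 0
    g <- davies_gamma(1:3, I)
    for (it in 1:300) {
      sol <- solve_at_gamma(g)
      nb <- sum(sol$n)
      ca_free <- n_ca_added - nb
      p_free <- n_p_total - nb
      g1 <- g[1]
      ch <- 10^(-ph) / g1
      coh <- 10^(-(acid$pkw - ph)) / g1
      I_new <- 0.5 * ((na_mol + cl_mol) / volume_l + 4 * ca_free / volume_l +
                        (f[2] + 4 * f[3] + 9 * f[4]) * p_free / volume_l +
                        (sol$n[1] + sol$n[3]) / volume_l + ch + coh)
      if (abs(I_new - I) / max(I_new, 1e-12) < 1e-10) { I <- I_new; break }
      I <- 0.5 * I + 0.5 * I_new
      g <- davies_gamma(1:3, I)
      if (it == 300) abort("predictive_solve: ionic-strength loop did not converge.")
    }
  }

  nb <- sum(sol$n)
  ca_free <- n_ca_added - nb
  tibble(
    n_cah2po4 = sol$n[1], n_cahpo4 = sol$n[2], n_capo4 = sol$n[3],
    ca_bound_mol = nb, ca_free_mol = ca_free,
    free_ca_mol_per_l = ca_free / volume_l,
    a_ca = g[2] * ca_free / volume_l,
    gamma1 = g[1], gamma2 = g[2], gamma3 = g[3],
    ionic_strength = I, residual = sol$residual
  )
}

# ---------------------------------------------------------------------------
# Curve-level prediction over a dosing schedule
# ---------------------------------------------------------------------------

# Proton content bound in phosphate species + pairs, from an equilibrate row.
# Used for the stoichiometric counter-titrant demand at constant pH.
phosphate_proton_content <- function(eq, acid) {
  f <- phosphate_fractions_mat(eq$ph, acid)
  (3 * f[, 1] + 2 * f[, 2] + 1 * f[, 3]) * eq$p_free_mol +
    2 * eq$n_cah2po4 + 1 * eq$n_cahpo4
}

#' Predict a full titration curve for a dosing protocol
#'
#' Runs the quasi-static equilibrium model over a titrant dosing schedule:
#' at each dose step the added calcium (and chloride, and any acidification
#' of the titrant) is updated, the counter-titrant volume needed to hold the
#' pH is computed from the stoichiometric proton demand, and the solution is
#' re-equilibrated self-consistently. The result is rate-independent: only
#' the total added amounts matter.
#'
#' @param protocol A [titration_protocol()].
#' @param k A [binding_constants()] object.
#' @param acid An [acid_constants()] object.
#' @param n_steps Override for the number of dose steps (defaults to the
#'   protocol's).
#'
#' @return A titration-curve tibble (see [validate_titration_curve()]) with
#'   additional model columns `ca_bound_mol`, `n_cah2po4`, `n_cahpo4`,
#'   `n_capo4`, `ionic_strength`, `na_mol`, `cl_mol`, `total_p_mol`.
#' @export
predict_curve <- function(protocol, k, acid = acid_constants(),
                          n_steps = NULL) {
  p <- protocol
  if (!inherits(p, "titration_protocol")) {
    abort("`protocol` must be a titration_protocol().")
  }
  steps <- if (is.null(n_steps)) p$n_steps else n_steps
  if (steps == 0) {
    return(tibble(replicate = character(), added_ca_mol = numeric(),
                  free_ca_mol_per_l = numeric(), ph = numeric(),
                  volume_l = numeric(), temperature_k = numeric()))
  }
  run_schedule(p, k, acid, n_steps = steps)
}

# Deterministic solution path over the dosing schedule. The only sequential
# coupling between steps is the cumulative counter-titrant (volume and
# Na/Cl); it is tiny relative to the bulk, so the whole schedule is solved
# by a vectorised fixed point: equilibrate all steps, recompute the per-step
# proton demand, update the cumulative counter additions, repeat.
run_schedule <- function(protocol, k, acid, n_steps = NULL) {
  p <- protocol
  steps <- if (is.null(n_steps)) p$n_steps else n_steps
  init <- init_buffer(p, acid)
  n_p <- init$n_p
  ph <- p$target_ph
  dv <- p$dose_step_ml / 1000
  s <- seq_len(steps)
  n_ca <- s * p$titrant_conc * dv
  hcl_step <- if (p$acidified_titrant) p$titrant_hcl_conc * dv else 0
  hcl_cum <- s * hcl_step
  cl_base <- init$cl_mol + 2 * n_ca + hcl_cum
  v_base <- init$volume_l + s * dv
  # first guess: counter neutralises exactly the dosed acid
  na <- init$na_mol + hcl_cum
  cl <- cl_base
  v <- v_base + hcl_cum / p$counter_conc
  eq <- NULL
  for (sweep in 1:40) {
    eq <- eq_core(n_ca, n_p, ph, v, k, acid, na_mol = na, cl_mol = cl)
    ph_content <- phosphate_proton_content(
      list(ph = rep(ph, steps), p_free_mol = eq$p_free,
           n_cah2po4 = eq$n1, n_cahpo4 = eq$n2), acid)
    rel_step <- c(init$proton_content, ph_content[-steps]) - ph_content +
      hcl_step
    na_new <- init$na_mol + cumsum(pmax(rel_step, 0))
    cl_new <- cl_base + cumsum(pmax(-rel_step, 0))
    v_new <- v_base + cumsum(abs(rel_step)) / p$counter_conc
    done <- max(abs(v_new - v)) < 1e-15 * max(v_new) &&
      max(abs(na_new - na)) < 1e-15 * max(na_new)
    na <- na_new; cl <- cl_new; v <- v_new
    if (done) break
  }
  eq <- eq_core(n_ca, n_p, ph, v, k, acid, na_mol = na, cl_mol = cl)
  tibble::new_tibble(list(
    replicate = rep("model", steps), added_ca_mol = n_ca,
    free_ca_mol_per_l = eq$ca_free / v,
    ph = rep(ph, steps), volume_l = v,
    temperature_k = rep(p$temperature_k, steps),
    ca_bound_mol = eq$b,
    n_cah2po4 = eq$n1, n_cahpo4 = eq$n2, n_capo4 = eq$n3,
    ionic_strength = eq$I,
    gamma1 = eq$g1, gamma2 = eq$g2, gamma3 = eq$g3,
    a_ca = eq$g2 * eq$ca_free / v,
    p_free_mol = eq$p_free,
    na_mol = na, cl_mol = cl, total_p_mol = rep(n_p, steps)
  ), nrow = steps)
}

# Initial buffer composition: total phosphate from the recipe, sodium from
# electroneutrality at the target pH (NaH2PO4/Na2HPO4 mix adjusted to pH).
init_buffer <- function(protocol, acid) {
  p <- protocol
  v0 <- p$buffer_mass_g / p$buffer_density_g_ml / 1000
  n_p <- p$buffer_conc * v0
  f <- phosphate_fractions_mat(p$target_ph, acid)
  na <- (f[2] + 2 * f[3] + 3 * f[4]) * n_p
  # H+/OH- correction with a two-pass gamma refresh
  for (i in 1:2) {
    inv <- ion_inventory(c(na = na, h3po4 = f[1] * n_p, h2po4 = f[2] * n_p,
                           hpo4 = f[3] * n_p, po4 = f[4] * n_p),
                         volume_l = v0)
    I <- ionic_strength(inv)
    g1 <- davies_gamma(1, I)
    ch <- 10^(-p$target_ph) / g1
    coh <- 10^(-(acid$pkw - p$target_ph)) / g1
    na <- max((f[2] + 2 * f[3] + 3 * f[4]) * n_p + (coh - ch) * v0, 0)
  }
  eq0 <- eq_core(0, n_p, p$target_ph, v0, binding_constants(0, 0, 0),
                 acid, na_mol = na)
  list(volume_l = v0, na_mol = na, cl_mol = 0, n_p = n_p,
       proton_content = phosphate_proton_content(
         list(ph = p$target_ph, p_free_mol = eq0$p_free,
              n_cah2po4 = eq0$n1, n_cahpo4 = eq0$n2), acid))
}

# ---------------------------------------------------------------------------
# Pre-nucleation regime analysis
# ---------------------------------------------------------------------------

#' Slope of the pre-nucleation titration regime
#'
#' Ordinary least-squares fit of the free-calcium amount against the added
#' calcium amount over an (already truncated) pre-nucleation curve. The slope
#' is the ratio of free to added calcium; 1 means no binding, 0 complete
#' binding.
#'
#' @param curve A titration-curve tibble (single replicate).
#' @return A one-row tibble: `slope`, `intercept`, `se_slope`, `r_squared`,
#'   `n_points`.
#' @export
prenucleation_slope <- function(curve) {
  if (nrow(curve) < 3) abort("Need at least 3 points to fit a slope.")
  x <- curve$added_ca_mol
  y <- curve$free_ca_mol_per_l * curve$volume_l
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact data trips the perfect-fit note
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    se_slope = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n_points = length(x)
  )
}

#' Truncate a titration curve to its pre-nucleation (linear) regime
#'
#' Finds the longest prefix of the curve on which a linear fit of free versus
#' added calcium keeps its root-mean-square residual below `threshold`
#' relative to the mean free-calcium amount. Curves whose nucleation drop is
#' within the data are cut just before it; curves with no linear prefix of at
#' least `window` points signal an empty regime.
#'
#' @param curve A titration-curve tibble (single replicate).
#' @param window Minimum number of points a linear regime must span.
#' @param threshold Relative RMS residual bound for "linear".
#' @return The truncated curve. Aborts with class `"capion_empty_regime"`
#'   when no linear prefix exists.
#' @export
truncate_prenucleation <- function(curve, window = 10, threshold = 0.01) {
  if (nrow(curve) < window + 2) {
    abort(sprintf("Need at least window + 2 = %d points.", window + 2))
  }
  x <- curve$added_ca_mol
  y <- curve$free_ca_mol_per_l * curve$volume_l
  n <- length(x)
  rel_resid <- function(k) {
    fit <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    sqrt(mean(fit$residuals^2)) / max(mean(abs(y[1:k])), 1e-300)
  }
  for (k in rev(seq(window, n))) {
    if (rel_resid(k) < threshold) {
      return(curve[1:k, ])
    }
  }
  abort("No linear pre-nucleation prefix found.",
        class = "capion_empty_regime")
}
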