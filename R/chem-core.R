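# Species bookkeeping: name -> charge. The order is the canonical inventory
# order used throughout the package.
SPECIES_CHARGES <- c(
  na = 1L, cl = -1L, ca_free = 2L,
  h3po4 = 0L, h2po4 = -1L, hpo4 = -2L, po4 = -3L,
  cah2po4 = 1L, cahpo4 = 0L, capo4 = -1L,
  h = 1L, oh = -1L
)

#' Fractional speciation of orthophosphate at a given pH
#'
#' Closed-form triprotic partition of total dissolved phosphate into
#' H3PO4, H2PO4-, HPO4(2-) and PO4(3-) from the three stepwise pKa values.
#' The fractions are mole fractions of total phosphate and sum to one.
#'
#' @param ph pH value(s); each must be finite and in \[0, 14\].
#' @param acid An [acid_constants()] object.
#'
#' @return A tibble with columns `ph`, `f_h3po4`, `f_h2po4`, `f_hpo4`,
#'   `f_po4`, one row per pH.
#' @export
#' @examples
#' phosphate_fractions(c(4.3, 7.0, 11.3))
phosphate_fractions <- function(ph, acid = acid_constants()) {
  if (!inherits(acid, "acid_constants")) abort("`acid` must be acid_constants().")
  if (any(!is.finite(ph))) abort("`ph` must be finite.")
  if (any(ph < 0 | ph > 14)) abort("`ph` must lie in [0, 14].")
  f <- phosphate_fractions_mat(ph, acid)
  tibble(ph = ph,
         f_h3po4 = f[, 1], f_h2po4 = f[, 2],
         f_hpo4 = f[, 3], f_po4 = f[, 4])
}

# matrix version used internally (no validation, columns H3PO4..PO4)
phosphate_fractions_mat <- function(ph, acid) {
  h <- 10^(-ph)
  ka1 <- 10^(-acid$pka1); ka2 <- 10^(-acid$pka2); ka3 <- 10^(-acid$pka3)
  d <- h^3 + h^2 * ka1 + h * ka1 * ka2 + ka1 * ka2 * ka3
  cbind(h^3 / d, h^2 * ka1 / d, h * ka1 * ka2 / d, ka1 * ka2 * ka3 / d)
}

#' Davies activity coefficient
#'
#' Activity coefficient for an ion of charge `z` at molar-basis ionic
#' strength `I`, from the Davies equation
#' \deqn{\log_{10}\gamma = -0.5085\,z^2\left(\frac{\sqrt I}{1+\sqrt I} - 0.3 I\right).}
#' Neutral species get exactly 1.
#'
#' @param charge Integer ionic charge (sign irrelevant).
#' @param ionic_strength Dimensionless (molar-basis) ionic strength, >= 0.
#'
#' @return Activity coefficient(s), recycled over the longer argument.
#' @export
#' @examples
#' davies_gamma(2, 0.02)
#' davies_gamma(0:3, 0.03)
davies_gamma <- function(charge, ionic_strength) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength < 0)) {
    abort("`ionic_strength` must be finite and non-negative.")
  }
  s <- sqrt(ionic_strength)
  10^(-0.5085 * charge^2 * (s / (1 + s) - 0.3 * ionic_strength))
}

#' Build an ion inventory
#'
#' An ion inventory is a tibble of per-species molar amounts and charges for
#' the twelve species the model tracks (Na+, Cl-, free Ca2+, the four
#' phosphate protonation states, the three calcium-phosphate ion pairs, H+
#' and OH-), together with a total solution volume.
#'
#' @param amounts_mol Named numeric vector of molar amounts; names must be a
#'   subset of `names(species_charges())`. Missing species default to zero.
#' @param volume_l Total solution volume in litres (> 0).
#'
#' @return A tibble with columns `species`, `charge`, `amount_mol` and an
#'   attribute `volume_l`.
#' @export
#' @examples
#' inv <- ion_inventory(c(na = 0.02, hpo4 = 0.01), volume_l = 1)
#' ionic_strength(inv)
ion_inventory <- function(amounts_mol = numeric(), volume_l) {
  if (!is.numeric(volume_l) || length(volume_l) != 1 || !is.finite(volume_l) ||
      volume_l <= 0) {
    abort("`volume_l` must be a single positive number.")
  }
  amt <- stats::setNames(numeric(length(SPECIES_CHARGES)), names(SPECIES_CHARGES))
  if (length(amounts_mol)) {
    nm <- names(amounts_mol)
    if (is.null(nm) || !all(nm %in% names(SPECIES_CHARGES))) {
      abort(paste0("Unknown species in `amounts_mol`; allowed: ",
                   paste(names(SPECIES_CHARGES), collapse = ", ")))
    }
    if (any(!is.finite(amounts_mol)) || any(amounts_mol < 0)) {
      abort("Species amounts must be finite and non-negative.")
    }
    amt[nm] <- amounts_mol
  }
  out <- tibble(species = names(SPECIES_CHARGES),
                charge = unname(SPECIES_CHARGES),
                amount_mol = unname(amt))
  attr(out, "volume_l") <- volume_l
  out
}

#' Species charge table
#'
#' @return Named integer vector of elementary charges for the tracked species.
#' @export
species_charges <- function() SPECIES_CHARGES

#' Ionic strength of an ion inventory
#'
#' Molar-basis ionic strength \eqn{I = \tfrac12 \sum_i z_i^2 c_i / c^0} over
#' every charged species in the inventory, including the charged ion pairs;
#' the neutral pair contributes nothing.
#'
#' @param inventory An [ion_inventory()].
#' @return Dimensionless ionic strength.
#' @export
ionic_strength <- function(inventory) {
  v <- attr(inventory, "volume_l")
  if (is.null(v) || v <= 0) abort("Inventory volume must be positive.")
  if (any(inventory$amount_mol < 0)) abort("Species amounts must be non-negative.")
  conc <- inventory$amount_mol / v / C_STANDARD
  0.5 * sum(inventory$charge^2 * conc)
}

#' Activities of all species in an inventory
#'
#' Converts amounts to concentrations, applies Davies activity coefficients
#' by charge at the supplied ionic strength, and returns dimensionless
#' activities \eqn{a_i = \gamma_i c_i / c^0}.
#'
#' @param inventory An [ion_inventory()].
#' @param ionic_strength Dimensionless ionic strength to evaluate the Davies
#'   coefficients at; defaults to the inventory's own ionic strength.
#'
#' @return The inventory tibble with added columns `conc_mol_l`, `gamma`,
#'   `activity`.
#' @export
activities <- function(inventory, ionic_strength = NULL) {
  v <- attr(inventory, "volume_l")
  if (is.null(ionic_strength)) {
    ionic_strength <- ionic_strength(inventory)
  }
  out <- inventory
  out$conc_mol_l <- out$amount_mol / v
  out$gamma <- davies_gamma(out$charge, ionic_strength)
  out$activity <- out$gamma * out$conc_mol_l / C_STANDARD
  attr(out, "volume_l") <- v
  attr(out, "ionic_strength") <- ionic_strength
  out
}

# ---------------------------------------------------------------------------
# Self-consistent equilibration
#
# At fixed pH the three pair equilibria collapse, for given activity
# coefficients, to a single quadratic in the bound-calcium amount b:
#   b = (gCa * S / V) * (Ca_t - b) * (P_t - b),
#   S = K1 f2 + K2 g2 f3 + K3 (g3/g1) f4
# where f are the phosphate fractions of the free phosphate pool (functions
# of pH only on the operational constant basis), and the pair coefficients
# absorb gamma_anion / gamma_pair. Self-consistency in ionic strength is then
# a damped fixed point I -> gamma -> speciation -> I.
# ---------------------------------------------------------------------------

# Vectorised core. All of total_ca, total_p, volume_l, na_mol, cl_mol, ph may
# be vectors (recycled to common length). Returns a list of vectors.
eq_core <- function(total_ca, total_p, ph, volume_l, k, acid,
                    na_mol = 0, cl_mol = 0,
                    damping = 0.5, tol = 1e-10, max_iter = 500) {
  n <- max(length(total_ca), length(total_p), length(ph), length(volume_l),
           length(na_mol), length(cl_mol))
  total_ca <- rep_len(total_ca, n); total_p <- rep_len(total_p, n)
  ph <- rep_len(ph, n); volume_l <- rep_len(volume_l, n)
  na_mol <- rep_len(na_mol, n); cl_mol <- rep_len(cl_mol, n)

  f <- phosphate_fractions_mat(ph, acid)
  h_act <- 10^(-ph)
  oh_act <- 10^(-(acid$pkw - ph))

  iter_step <- function(I) {
    g1 <- davies_gamma(1, I); g2 <- davies_gamma(2, I); g3 <- davies_gamma(3, I)
    # pair charge pattern: +1, 0, -1 -> gamma_pair = g1, 1, g1
    s_coef <- k$k1 * f[, 2] * g1 / g1 +
      k$k2 * f[, 3] * g2 / 1 +
      k$k3 * f[, 4] * g3 / g1
    alpha <- g2 * s_coef / volume_l
    # quadratic alpha b^2 - (alpha (Ca+P) + 1) b + alpha Ca P = 0;
    # the small root in its cancellation-free form
    bcoef <- alpha * (total_ca + total_p) + 1
    disc <- pmax(bcoef^2 - 4 * alpha^2 * total_ca * total_p, 0)
    b <- 2 * alpha * total_ca * total_p / (bcoef + sqrt(disc))
    b <- pmin(pmax(b, 0), pmin(total_ca, total_p))
    ca_free <- total_ca - b
    p_free <- total_p - b
    a_ca <- g2 * ca_free / volume_l
    # pair amounts n_i = K_i a_Ca a_anion_i / gamma_pair_i * V
    a_h2po4 <- g1 * f[, 2] * p_free / volume_l
    a_hpo4 <- g2 * f[, 3] * p_free / volume_l
    a_po4 <- g3 * f[, 4] * p_free / volume_l
    n1 <- k$k1 * a_ca * a_h2po4 / g1 * volume_l
    n2 <- k$k2 * a_ca * a_hpo4 / 1 * volume_l
    n3 <- k$k3 * a_ca * a_po4 / g1 * volume_l
    # ionic strength over all charged species
    ch <- h_act / g1
    coh <- oh_act / g1
    I_new <- 0.5 * (
      na_mol / volume_l + cl_mol / volume_l +
        4 * ca_free / volume_l +
        (f[, 2] + 4 * f[, 3] + 9 * f[, 4]) * p_free / volume_l +
        n1 / volume_l + n3 / volume_l +
        ch + coh
    )
    list(I = I_new, b = b, ca_free = ca_free, p_free = p_free,
         n1 = n1, n2 = n2, n3 = n3,
         g1 = g1, g2 = g2, g3 = g3, ch = ch, coh = coh)
  }

  # initial I at gamma = 1 speciation
  I <- iter_step(rep(0, n))$I
  st <- NULL
  converged <- rep(FALSE, n)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    st <- iter_step(I)
    dI <- abs(st$I - I) / pmax(st$I, 1e-12)
    converged <- dI < tol
    I <- damping * I + (1 - damping) * st$I
    if (all(converged)) break
  }
  if (!all(converged)) {
    abort(sprintf(
      "Equilibration did not converge in %d iterations (max |dI|/I = %.3g, last I = %.6g).",
      max_iter, max(abs(st$I - I) / pmax(st$I, 1e-12)), I[which.max(abs(st$I - I))]))
  }
  # one final evaluation at the converged I so outputs match gamma(I)
  st <- iter_step(I)
  st$I <- I
  st$iterations <- it
  st$ph <- ph; st$volume_l <- volume_l
  st$total_ca <- total_ca; st$total_p <- total_p
  st$na_mol <- na_mol; st$cl_mol <- cl_mol
  st
}

#' Equilibrate a calcium-phosphate solution at fixed pH
#'
#' Solves the coupled mass-action system for the three 1:1 calcium-phosphate
#' ion pairs at fixed pH, self-consistently in ionic strength: speciation is
#' computed with Davies activity coefficients, the coefficients are
#' recomputed from the resulting ionic strength, and the loop is damped and
#' iterated to a relative ionic-strength tolerance of 1e-10. Mass balances on
#' total calcium and total phosphate hold to solver precision.
#'
#' All of `total_ca_mol`, `total_p_mol`, `ph`, `volume_l`, `na_mol` and
#' `cl_mol` may be vectors (recycled); one equilibrium is solved per row.
#'
#' @param total_ca_mol Total (added) calcium, mol.
#' @param total_p_mol Total phosphate, mol.
#' @param ph Fixed pH of the solution.
#' @param k A [binding_constants()] object.
#' @param acid An [acid_constants()] object.
#' @param volume_l Total solution volume, litres.
#' @param na_mol,cl_mol Background sodium and chloride amounts, mol (spectator
#'   ions; they only enter the ionic strength).
#' @param background Optionally, an [ion_inventory()] whose `na`/`cl` rows and
#'   volume are used instead of `na_mol`/`cl_mol`/`volume_l`.
#' @param damping Damping factor on the ionic-strength update (0 = none).
#' @param tol Relative convergence tolerance on ionic strength.
#' @param max_iter Iteration cap; exceeded caps raise a convergence error
#'   reporting the last ionic strength.
#'
#' @return A tibble, one row per condition, with the inputs plus
#'   `ionic_strength`, activity coefficients `gamma1`-`gamma3`, free and
#'   bound calcium (`ca_free_mol`, `ca_bound_mol`), free phosphate
#'   (`p_free_mol`), the three pair amounts (`n_cah2po4`, `n_cahpo4`,
#'   `n_capo4`), the free-calcium activity `a_ca`, and `iterations`.
#' @export
#' @examples
#' equilibrate(1e-4, 5e-4, ph = 8.3, k = binding_preset("revised_25C"),
#'             volume_l = 0.05, na_mol = 8e-4)
equilibrate <- function(total_ca_mol, total_p_mol, ph,
                        k, acid = acid_constants(), volume_l,
                        na_mol = 0, cl_mol = 0, background = NULL,
                        damping = 0.5, tol = 1e-10, max_iter = 500) {
  if (!inherits(k, "binding_constants")) abort("`k` must be binding_constants().")
  if (!inherits(acid, "acid_constants")) abort("`acid` must be acid_constants().")
  if (!is.null(background)) {
    volume_l <- attr(background, "volume_l")
    na_mol <- background$amount_mol[background$species == "na"]
    cl_mol <- background$amount_mol[background$species == "cl"]
  }
  if (any(total_ca_mol < 0) || any(total_p_mol < 0)) {
    abort("Total amounts must be non-negative.")
  }
  if (any(volume_l <= 0)) abort("`volume_l` must be positive.")
  st <- eq_core(total_ca_mol, total_p_mol, ph, volume_l, k, acid,
                na_mol = na_mol, cl_mol = cl_mol,
                damping = damping, tol = tol, max_iter = max_iter)
  tibble(
    total_ca_mol = st$total_ca, total_p_mol = st$total_p,
    ph = st$ph, volume_l = st$volume_l,
    na_mol = st$na_mol, cl_mol = st$cl_mol,
    ionic_strength = st$I,
    gamma1 = st$g1, gamma2 = st$g2, gamma3 = st$g3,
    ca_free_mol = st$ca_free, ca_bound_mol = st$b, p_free_mol = st$p_free,
    n_cah2po4 = st$n1, n_cahpo4 = st$n2, n_capo4 = st$n3,
    a_ca = st$g2 * st$ca_free / st$volume_l,
    iterations = st$iterations
  )
}

#' Full speciation snapshot for a single equilibrated condition
#'
#' Runs [equilibrate()] for one condition and expands the result into a full
#' [ion_inventory()] with per-species concentrations, Davies coefficients and
#' activities.
#'
#' @inheritParams equilibrate
#' @return A list of class `speciation_state` with elements `inventory`
#'   (an activity-annotated inventory tibble), `ionic_strength`, `ph`,
#'   and `summary` (the one-row [equilibrate()] tibble).
#' @export
speciation_state <- function(total_ca_mol, total_p_mol, ph, k,
                             acid = acid_constants(), volume_l,
                             na_mol = 0, cl_mol = 0, ...) {
  stopifnot(length(total_ca_mol) == 1, length(total_p_mol) == 1,
            length(ph) == 1, length(volume_l) == 1)
  eq <- equilibrate(total_ca_mol, total_p_mol, ph, k, acid, volume_l,
                    na_mol = na_mol, cl_mol = cl_mol, ...)
  f <- phosphate_fractions_mat(ph, acid)
  g1 <- eq$gamma1
  inv <- ion_inventory(c(
    na = na_mol, cl = cl_mol, ca_free = eq$ca_free_mol,
    h3po4 = f[1] * eq$p_free_mol, h2po4 = f[2] * eq$p_free_mol,
    hpo4 = f[3] * eq$p_free_mol, po4 = f[4] * eq$p_free_mol,
    cah2po4 = eq$n_cah2po4, cahpo4 = eq$n_cahpo4, capo4 = eq$n_capo4,
    h = 10^(-ph) / g1 * volume_l, oh = 10^(-(acid$pkw - ph)) / g1 * volume_l
  ), volume_l = volume_l)
  structure(
    list(inventory = activities(inv, eq$ionic_strength),
         ionic_strength = eq$ionic_strength, ph = ph, summary = eq),
    class = "speciation_state"
  )
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("<speciation_state> pH %.2f, I = %.4g, bound Ca = %.3g mol\n",
              x$ph, x$ionic_strength, x$summary$ca_bound_mol))
  print(x$inventory)
  invisible(x)
}
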