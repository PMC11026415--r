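# ---------------------------------------------------------------------------
# Standard thermodynamics of ion pairing from equilibrium constants
# ---------------------------------------------------------------------------

#' Standard Gibbs energy of association
#'
#' \eqn{\Delta G^0 = -R T \ln K}, in kJ/mol, with R = 8.314 J/K/mol.
#'
#' @param k Equilibrium constant(s), dimensionless, > 0.
#' @param temperature Absolute temperature, kelvin.
#' @return Standard Gibbs energy, kJ/mol.
#' @export
#' @examples
#' delta_g0(470, 298.15)
delta_g0 <- function(k, temperature = 298.15) {
  if (any(k <= 0)) abort("`k` must be positive.")
  if (any(temperature <= 0)) abort("`temperature` must be positive (kelvin).")
  -R_GAS * temperature * log(k) / 1000
}

#' Standard enthalpy from two-temperature van't Hoff analysis
#'
#' \eqn{\Delta H^0 = R \ln(K_b/K_a) / (1/T_a - 1/T_b)}, in kJ/mol. Equal
#' constants at the two temperatures give exactly zero.
#'
#' @param k_a,k_b Equilibrium constants at `t_a` and `t_b`.
#' @param t_a,t_b The two temperatures, kelvin (must differ).
#' @return Standard enthalpy, kJ/mol.
#' @export
#' @examples
#' vant_hoff_dh0(470, 298.15, 480, 310.15)
vant_hoff_dh0 <- function(k_a, t_a, k_b, t_b) {
  if (any(t_a == t_b)) abort("The two temperatures must differ.")
  if (any(c(k_a, k_b) <= 0)) abort("Equilibrium constants must be positive.")
  R_GAS * log(k_b / k_a) / (1 / t_a - 1 / t_b) / 1000
}

#' Standard entropy from Gibbs energy and enthalpy
#'
#' \eqn{\Delta S^0 = 1000 (\Delta H^0 - \Delta G^0) / T}, in J/K/mol.
#'
#' @param dg0,dh0 Standard Gibbs energy and enthalpy, kJ/mol.
#' @param temperature Absolute temperature, kelvin.
#' @return Standard entropy, J/K/mol.
#' @export
#' @examples
#' entropy0(-3.7, 0, 298.15)
entropy0 <- function(dg0, dh0, temperature = 298.15) {
  if (any(temperature <= 0)) abort("`temperature` must be positive (kelvin).")
  1000 * (dh0 - dg0) / temperature
}

#' Bundle a consistent (dG0, dH0, dS0) triple
#'
#' @param dg0,dh0 Standard Gibbs energy and enthalpy, kJ/mol.
#' @param t_ref Reference temperature, kelvin.
#' @return A one-row tibble with `dg0_kj_mol`, `dh0_kj_mol`, `ds0_j_k_mol`,
#'   `t_ref_k`; the Gibbs identity holds by construction.
#' @export
thermo_triple <- function(dg0, dh0, t_ref = 298.15) {
  tibble(dg0_kj_mol = dg0, dh0_kj_mol = dh0,
         ds0_j_k_mol = entropy0(dg0, dh0, t_ref), t_ref_k = t_ref)
}

#' Linear fit of Gibbs energy against temperature
#'
#' Least-squares fit of \eqn{\Delta G(T) = \Delta H - T \Delta S}; the
#' intercept is the enthalpy (kJ/mol) and minus the slope the entropy
#' (converted to J/K/mol). With exactly two points this reproduces the
#' two-temperature van't Hoff composition exactly.
#'
#' @param data A data frame with columns `temperature_k` and `dg0_kj_mol`
#'   (at least two distinct temperatures).
#' @return A one-row tibble: `dh0_kj_mol`, `ds0_j_k_mol`, `sigma_dh0`,
#'   `sigma_ds0` (standard errors, `NA` with two points).
#' @export
#' @examples
#' fit_gibbs_line(data.frame(temperature_k = c(298.15, 310.15),
#'                           dg0_kj_mol = c(-26.8, -28.8)))
fit_gibbs_line <- function(data) {
  if (length(unique(data$temperature_k)) < 2) {
    abort("Need at least two distinct temperatures.")
  }
  fit <- stats::lm(dg0_kj_mol ~ temperature_k, data = data)
  cf <- stats::coef(fit)
  se <- if (nrow(data) > 2) {
    suppressWarnings(summary(fit))$coefficients[, 2]  # exact lines are fine
  } else {
    c(NA, NA)
  }
  tibble(dh0_kj_mol = unname(cf[1]),
         ds0_j_k_mol = -unname(cf[2]) * 1000,
         sigma_dh0 = unname(se[1]),
         sigma_ds0 = unname(se[2]) * 1000)
}

#' Full thermodynamic table from two-temperature association constants
#'
#' Builds the per-ion-pair standard thermodynamic quantities from the
#' association constants at two temperatures: \eqn{\Delta G^0} at the
#' reference (lower) temperature, \eqn{\Delta H^0} by two-point van't Hoff,
#' and \eqn{\Delta S^0} from the Gibbs identity.
#'
#' @param k_ref A [binding_constants()] at the reference temperature.
#' @param k_alt A [binding_constants()] at the second temperature.
#' @return A tibble with one row per ion pair (`pair`, `k_ref`, `k_alt`,
#'   `dg0_kj_mol`, `dh0_kj_mol`, `ds0_j_k_mol`, `t_ref_k`).
#' @export
#' @examples
#' thermo_table(binding_preset("revised_25C"), binding_preset("revised_37C"))
thermo_table <- function(k_ref, k_alt) {
  stopifnot(inherits(k_ref, "binding_constants"),
            inherits(k_alt, "binding_constants"))
  t1 <- k_ref$temperature; t2 <- k_alt$temperature
  kr <- c(k_ref$k1, k_ref$k2, k_ref$k3)
  ka <- c(k_alt$k1, k_alt$k2, k_alt$k3)
  dg <- delta_g0(kr, t1)
  dh <- vant_hoff_dh0(kr, t1, ka, t2)
  tibble(
    pair = c("[CaH2PO4]+", "[CaHPO4]0", "[CaPO4]-"),
    k_ref = kr, k_alt = ka,
    dg0_kj_mol = dg, dh0_kj_mol = dh,
    ds0_j_k_mol = entropy0(dg, dh, t1),
    t_ref_k = t1
  )
}
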