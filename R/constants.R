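#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Gas constant, J/K/mol
R_GAS <- 8.314

# Standard concentration c0 = 1 M; activities are made dimensionless by
# dividing molar concentrations by this value.
C_STANDARD <- 1

#' Acid dissociation constants of phosphoric acid
#'
#' Bundles the three stepwise pKa values of H3PO4 together with the
#' temperature they refer to. The values are operational (mixed) constants as
#' read by a calibrated pH electrode at the working ionic strength
#' (~0.015-0.03): the proton enters as an activity, the phosphate species as
#' concentrations. The defaults are the values determined by half-equivalence
#' titration in the matched electrode setup (pKa1 = 2.58, pKa2 = 6.98) and
#' the literature value for the inaccessible third step (pKa3 = 12.32).
#'
#' @param pka1,pka2,pka3 Stepwise pKa values (dimensionless). Must be finite
#'   and strictly increasing.
#' @param temperature Absolute temperature in kelvin.
#' @param pkw Ion product of water on the same operational basis; used for
#'   the hydroxide contribution to charge balances.
#'
#' @return An object of class `acid_constants`.
#' @export
#' @examples
#' acid_constants()
#' acid_constants(pka2 = 7.00)
acid_constants <- function(pka1 = 2.58, pka2 = 6.98, pka3 = 12.32,
                           temperature = 298.15, pkw = 14) {
  vals <- c(pka1, pka2, pka3, temperature, pkw)
  if (any(!is.finite(vals))) {
    abort("All acid constants and the temperature must be finite.")
  }
  if (!(pka1 < pka2 && pka2 < pka3)) {
    abort("pKa values must satisfy pka1 < pka2 < pka3.")
  }
  if (temperature <= 0) abort("`temperature` must be positive (kelvin).")
  structure(
    list(pka1 = pka1, pka2 = pka2, pka3 = pka3,
         temperature = temperature, pkw = pkw),
    class = "acid_constants"
  )
}

#' @export
print.acid_constants <- function(x, ...) {
  cat(sprintf("<acid_constants> pKa = %.2f / %.2f / %.2f at %.2f K\n",
              x$pka1, x$pka2, x$pka3, x$temperature))
  invisible(x)
}

#' Ion association constants for the calcium-phosphate ion pairs
#'
#' The three activity-based (dimensionless, c0 = 1 M) association constants
#' for \verb{Ca2+ + H2PO4- <-> [CaH2PO4]+} (K1),
#' \verb{Ca2+ + HPO4(2-) <-> [CaHPO4]0} (K2) and
#' \verb{Ca2+ + PO4(3-) <-> [CaPO4]-} (K3), at a stated temperature.
#'
#' @param k1,k2,k3 Association constants, all strictly positive and finite.
#' @param temperature Absolute temperature in kelvin.
#'
#' @return An object of class `binding_constants`.
#' @seealso [binding_preset()] for the revised and legacy literature sets.
#' @export
#' @examples
#' binding_constants(4.5, 470, 50000)
binding_constants <- function(k1, k2, k3, temperature = 298.15) {
  vals <- c(k1, k2, k3)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("Association constants must be finite and non-negative.")
  }
  if (temperature <= 0) abort("`temperature` must be positive (kelvin).")
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, temperature = temperature),
    class = "binding_constants"
  )
}

#' @export
print.binding_constants <- function(x, ...) {
  cat(sprintf("<binding_constants> K1 = %g, K2 = %g, K3 = %g at %.2f K\n",
              x$k1, x$k2, x$k3, x$temperature))
  invisible(x)
}

#' Named presets for calcium-phosphate association constants
#'
#' Three presets are shipped:
#' \describe{
#'   \item{`"revised_25C"`}{The titration-derived set K1 = 4.5, K2 = 470,
#'     K3 = 50,000 at 298.15 K.}
#'   \item{`"revised_37C"`}{The near-physiological set K1 = 4.5, K2 = 480,
#'     K3 = 69,500 at 310.15 K.}
#'   \item{`"legacy_25C"`}{A reconstruction of the historical constants in
#'     which calcium-phosphate binding was strongly overestimated: K1 and K2
#'     as in the revised set, and K3 two orders of magnitude above the
#'     revised value (the size of the historical overestimate; the implied
#'     Gibbs-energy gap between the second and third association, 23 kJ/mol,
#'     is close to the 21.4 kJ/mol the older literature reports). This
#'     preset is a synthetic reconstruction, not a verbatim literature
#'     table.}
#' }
#'
#' @param name One of `"revised_25C"`, `"revised_37C"`, `"legacy_25C"`.
#' @return A [binding_constants()] object.
#' @export
#' @examples
#' binding_preset("revised_25C")
#' binding_preset("legacy_25C")
binding_preset <- function(name = c("revised_25C", "revised_37C", "legacy_25C")) {
  name <- match.arg(name)
  switch(name,
    revised_25C = binding_constants(4.5, 470, 50000, temperature = 298.15),
    revised_37C = binding_constants(4.5, 480, 69500, temperature = 310.15),
    # K3 overestimated by two orders of magnitude in the historical tables
    legacy_25C = binding_constants(4.5, 470, 100 * 50000, temperature = 298.15)
  )
}
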