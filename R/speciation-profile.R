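# ---------------------------------------------------------------------------
# Ion-pair speciation diagrams and bound-calcium fractions across pH
# ---------------------------------------------------------------------------

#' Ion-pair speciation profile across pH
#'
#' Equilibrates the solution at each pH of a grid and reports the mole
#' fraction of each of the three calcium-phosphate ion pairs, normalised to
#' the total amount of ion pairs at that pH, together with the bound-calcium
#' fraction of total calcium. Even where the absolute pair concentrations
#' are tiny (low pH), the mole fractions describe which pair dominates.
#'
#' @param k A [binding_constants()] object.
#' @param acid An [acid_constants()] object.
#' @param total_ca_mol_l,total_p_mol_l Total calcium and phosphate,
#'   mol/L. The defaults (0.05 mM Ca / 1 mM P) sit in the dilute regime
#'   where the crossover pH values have converged; at the titration's own
#'   10 mM phosphate the higher ionic strength shifts the crossovers up by
#'   roughly 0.2 pH units.
#' @param ph_grid pH grid, within \[2, 12\].
#' @param na_mol_l Background sodium, mol/L; defaults to the amount
#'   neutralising the phosphate at each pH (buffer electroneutrality).
#'
#' @return A tibble of class `speciation_profile`: `ph`, pair mole fractions
#'   `x_cah2po4`, `x_cahpo4`, `x_capo4`, `bound_ca_fraction`,
#'   `free_ca_fraction`, and the underlying pair amounts.
#' @export
#' @examples
#' prof <- pair_speciation(binding_preset("revised_25C"), ph_grid = seq(2, 12, 0.5))
#' head(prof)
pair_speciation <- function(k, acid = acid_constants(),
                            total_ca_mol_l = 5e-5, total_p_mol_l = 1e-3,
                            ph_grid = seq(2, 12, by = 0.1),
                            na_mol_l = NULL) {
  if (any(ph_grid < 2 | ph_grid > 12)) abort("`ph_grid` must lie in [2, 12].")
  if (total_ca_mol_l <= 0 || total_p_mol_l <= 0) {
    abort("Totals must be positive.")
  }
  v <- 1  # per-litre basis
  if (is.null(na_mol_l)) {
    f <- phosphate_fractions_mat(ph_grid, acid)
    na_mol_l <- (f[, 2] + 2 * f[, 3] + 3 * f[, 4]) * total_p_mol_l
  }
  eq <- equilibrate(total_ca_mol_l, total_p_mol_l, ph_grid, k, acid,
                    volume_l = v, na_mol = na_mol_l,
                    cl_mol = 2 * total_ca_mol_l)
  pairs_total <- eq$n_cah2po4 + eq$n_cahpo4 + eq$n_capo4
  safe <- pmax(pairs_total, 1e-300)
  out <- tibble(
    ph = ph_grid,
    x_cah2po4 = eq$n_cah2po4 / safe,
    x_cahpo4 = eq$n_cahpo4 / safe,
    x_capo4 = eq$n_capo4 / safe,
    bound_ca_fraction = eq$ca_bound_mol / total_ca_mol_l,
    free_ca_fraction = eq$ca_free_mol / total_ca_mol_l,
    n_cah2po4 = eq$n_cah2po4, n_cahpo4 = eq$n_cahpo4, n_capo4 = eq$n_capo4,
    ionic_strength = eq$ionic_strength
  )
  class(out) <- c("speciation_profile", class(out))
  attr(out, "constants") <- k
  out
}

#' Bound-calcium fraction across pH
#'
#' Convenience wrapper around [pair_speciation()] returning only the pH grid
#' and the bound/free calcium fractions.
#'
#' The defaults here are the titration's own conditions (0.5 mM Ca /
#' 10 mM P).
#'
#' @inheritParams pair_speciation
#' @return A tibble: `ph`, `bound_ca_fraction`, `free_ca_fraction`.
#' @export
bound_fraction <- function(k, acid = acid_constants(),
                           total_ca_mol_l = 5e-4, total_p_mol_l = 0.010,
                           na_mol_l = NULL,
                           ph_grid = seq(2, 12, by = 0.1)) {
  prof <- pair_speciation(k, acid, total_ca_mol_l, total_p_mol_l, ph_grid,
                          na_mol_l = na_mol_l)
  tibble(ph = prof$ph,
         bound_ca_fraction = prof$bound_ca_fraction,
         free_ca_fraction = prof$free_ca_fraction)
}

#' Dominance crossover pH values of a speciation profile
#'
#' Locates (by linear interpolation on the grid) the pH values at which the
#' majority ion pair changes.
#'
#' @param profile A `speciation_profile` from [pair_speciation()].
#' @return A tibble with `from`, `to`, `ph_crossover`.
#' @export
speciation_crossovers <- function(profile) {
  pairs <- c("x_cah2po4", "x_cahpo4", "x_capo4")
  lab <- c("[CaH2PO4]+", "[CaHPO4]0", "[CaPO4]-")
  dom <- pairs[max.col(as.matrix(profile[pairs]))]
  ch <- which(dom[-1] != dom[-length(dom)])
  if (!length(ch)) {
    return(tibble(from = character(), to = character(),
                  ph_crossover = numeric()))
  }
  rows <- lapply(ch, function(i) {
    p1 <- dom[i]; p2 <- dom[i + 1]
    # root of x_p1 - x_p2 between grid points i and i+1
    d1 <- profile[[p1]][i] - profile[[p2]][i]
    d2 <- profile[[p1]][i + 1] - profile[[p2]][i + 1]
    w <- if (d1 == d2) 0.5 else d1 / (d1 - d2)
    tibble(from = lab[match(p1, pairs)], to = lab[match(p2, pairs)],
           ph_crossover = profile$ph[i] + w * (profile$ph[i + 1] - profile$ph[i]))
  })
  dplyr::bind_rows(rows)
}
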