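# ---------------------------------------------------------------------------
# ggplot2 figures
# ---------------------------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   geom_abline theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Speciation diagram of the calcium-phosphate ion pairs
#'
#' Mole fraction of each ion pair (of total ion pairs) against pH.
#'
#' @param object A `speciation_profile` from [pair_speciation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot speciation_profile
#' @export
autoplot.speciation_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("ph", "x_cah2po4", "x_cahpo4", "x_capo4")],
    -"ph", names_to = "pair", values_to = "mole_fraction")
  long$pair <- factor(long$pair,
                      levels = c("x_cah2po4", "x_cahpo4", "x_capo4"),
                      labels = c("[CaH2PO4]+", "[CaHPO4]0", "[CaPO4]-"))
  ggplot(long, aes(.data$ph, .data$mole_fraction, colour = .data$pair)) +
    geom_line(linewidth = 0.8) +
    labs(x = "pH", y = "Mole fraction of total ion pairs", colour = NULL) +
    theme_minimal()
}

#' Plot titration curves against the no-binding line
#'
#' Free-calcium concentration against added calcium, one line per
#' replicate/pH, with the dashed no-binding line (free = added / volume).
#'
#' @param curves A titration-curve tibble.
#' @return A ggplot.
#' @export
plot_titration_curves <- function(curves) {
  curves <- as_tibble(curves)
  curves$group <- interaction(curves$replicate, curves$ph, drop = TRUE)
  curves$no_binding <- curves$added_ca_mol / curves$volume_l
  ggplot(curves, aes(.data$added_ca_mol)) +
    geom_line(aes(y = .data$no_binding), linetype = "dashed",
              colour = "grey50") +
    geom_line(aes(y = .data$free_ca_mol_per_l, colour = factor(.data$ph),
                  group = .data$group)) +
    labs(x = "Added calcium (mol)", y = "Free calcium (mol/L)",
         colour = "pH") +
    theme_minimal()
}

#' Plot the bound-calcium fraction across pH for several constant sets
#'
#' @param ... Named [binding_constants()] objects (names label the lines).
#' @param acid An [acid_constants()] object.
#' @param ph_grid pH grid.
#' @return A ggplot.
#' @export
plot_bound_fraction <- function(..., acid = acid_constants(),
                                ph_grid = seq(2, 12, by = 0.1)) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  long <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    bf <- bound_fraction(sets[[nm]], acid, ph_grid = ph_grid)
    bf$constants <- nm
    bf
  }))
  ggplot(long, aes(.data$ph, .data$bound_ca_fraction,
                   colour = .data$constants)) +
    geom_line(linewidth = 0.8) +
    labs(x = "pH", y = "Fraction of calcium bound", colour = NULL) +
    theme_minimal()
}
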