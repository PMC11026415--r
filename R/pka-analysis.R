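# ---------------------------------------------------------------------------
# pKa extraction from acid-base titration curves
# ---------------------------------------------------------------------------

# Local-quadratic (Savitzky-Golay-style) derivative of y with respect to x on
# a sliding window. Works on non-uniform spacing; width must be odd >= 3.
local_quadratic_derivative <- function(x, y, width = 5) {
  n <- length(x)
  if (width %% 2 == 0) width <- width + 1
  hw <- (width - 1) / 2
  d <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    xs <- x[lo:hi] - x[i]
    ys <- y[lo:hi]
    if (length(xs) >= 3) {
      cf <- stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients
      d[i] <- cf[2]
    } else {
      d[i] <- (ys[length(ys)] - ys[1]) / (xs[length(xs)] - xs[1])
    }
  }
  d
}

#' Find equivalence points of an acid-base titration curve
#'
#' Smooths the derivative dpH/dV with a local-quadratic (Savitzky-Golay
#' style) filter and returns the volumes of the `n_expected` largest local
#' maxima, in volume order. For 0.01 M phosphoric acid only the first two
#' equivalence points are detectable; the third is buried in the water
#' equilibrium.
#'
#' @param curve A tibble with columns `volume_ml` (added base, strictly
#'   increasing) and `ph`, as produced by [simulate_acid_titration()].
#' @param n_expected Number of equivalence points to return (1 or 2).
#' @param width Smoothing window width (points) for the derivative.
#'
#' @return Numeric vector of equivalence volumes (mL), in volume order.
#' @export
find_equivalence_points <- function(curve, n_expected = 2, width = 5) {
  if (nrow(curve) < 10) abort("Need at least 10 titration points.")
  if (!n_expected %in% c(1L, 2L)) abort("`n_expected` must be 1 or 2.")
  v <- curve$volume_ml; ph <- curve$ph
  if (any(diff(v) <= 0)) abort("`volume_ml` must be strictly increasing.")
  d <- local_quadratic_derivative(v, ph, width)
  # interior local maxima of the smoothed derivative
  idx <- which(diff(sign(diff(d))) == -2) + 1
  if (length(idx) < n_expected) {
    abort(sprintf("Detected only %d equivalence point(s), expected %d.",
                  length(idx), n_expected))
  }
  top <- idx[order(d[idx], decreasing = TRUE)][seq_len(n_expected)]
  # refine each maximum by a quadratic through its three neighbours
  refine <- function(i) {
    if (i <= 1 || i >= length(v)) return(v[i])
    xs <- v[(i - 1):(i + 1)]; ys <- d[(i - 1):(i + 1)]
    cf <- stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients
    if (cf[3] >= 0) return(v[i])
    vv <- -cf[2] / (2 * cf[3])
    if (vv >= xs[1] && vv <= xs[3]) vv else v[i]
  }
  sort(vapply(top, refine, numeric(1)))
}

#' pKa values from half-equivalence points
#'
#' Reads the pH at half of each successive equivalence interval (0 to V1,
#' V1 to V2, ...) by monotone piecewise-linear interpolation in volume. At
#' the half-equivalence point of each step the pH equals the corresponding
#' operational pKa — provided the acid step is weak relative to its
#' concentration. For the first step of 0.01 M phosphoric acid that proviso
#' fails: a non-negligible fraction of the acid is dissociated on its own,
#' so at half the equivalence volume the conjugate ratio is not 1:1. When
#' the curve carries its recipe (attributes `acid_mol`, `base_conc`,
#' `acid_volume_ml`, as written by [simulate_acid_titration()]) and
#' `correct_strong_acid = TRUE`, the degree of neutralisation is recomputed
#' from the charge balance (Na+ from the base plus free H+ minus OH-) and
#' the Henderson-Hasselbalch ratio correction is applied; the correction is
#' negligible for the second step.
#'
#' @param curve A tibble with columns `volume_ml` and `ph` (and optionally
#'   `ionic_strength`).
#' @param equivalence_volumes_ml Equivalence volumes from
#'   [find_equivalence_points()], in increasing order.
#' @param correct_strong_acid Apply the free-proton charge-balance
#'   correction when the recipe is available.
#' @return Numeric vector of pKa estimates, one per equivalence point.
#' @export
pka_from_half_equivalence <- function(curve, equivalence_volumes_ml,
                                      correct_strong_acid = TRUE) {
  v_eq <- sort(equivalence_volumes_ml)
  half <- (c(0, v_eq[-length(v_eq)]) + v_eq) / 2
  if (any(half < min(curve$volume_ml)) || any(half > max(curve$volume_ml))) {
    abort("A half-equivalence volume lies outside the data range.")
  }
  ph_half <- stats::approx(curve$volume_ml, curve$ph, xout = half,
                           ties = "ordered")$y
  acid_mol <- attr(curve, "acid_mol")
  base_conc <- attr(curve, "base_conc")
  v0_ml <- attr(curve, "acid_volume_ml")
  if (!correct_strong_acid || is.null(acid_mol) || is.null(base_conc) ||
      is.null(v0_ml)) {
    return(ph_half)
  }
  co_acid <- attr(curve, "co_acid_conc") %||% 0
  dil <- isTRUE(attr(curve, "compensate_dilution"))
  I_half <- if ("ionic_strength" %in% names(curve)) {
    stats::approx(curve$volume_ml, curve$ionic_strength, xout = half,
                  ties = "ordered")$y
  } else {
    rep(0, length(half))
  }
  pka <- numeric(length(half))
  for (j in seq_along(half)) {
    vb <- half[j] / 1000
    v <- v0_ml / 1000 + vb + if (dil) vb else 0
    n_acid <- acid_mol + if (dil) co_acid * vb else 0
    g1 <- davies_gamma(1, I_half[j])
    c_h <- 10^(-ph_half[j]) / g1
    c_oh <- 10^(ph_half[j] - 14) / g1
    # mean protons removed per phosphate, from the charge balance
    x <- (base_conc * vb / v + c_h - c_oh) / (n_acid / v)
    x <- min(max(x, j - 1 + 1e-9), j - 1e-9)
    pka[j] <- ph_half[j] + log10((j - x) / (x - (j - 1)))
  }
  pka
}

#' One-call pKa estimation from an acid titration curve
#'
#' Convenience wrapper: detect equivalence points, then read the pKa values
#' at the half-equivalence volumes.
#'
#' @inheritParams find_equivalence_points
#' @return A tibble with `step`, `v_equivalence_ml`, `pka`.
#' @export
#' @examples
#' curve <- simulate_acid_titration(n_steps = 250)
#' estimate_pka(curve)
estimate_pka <- function(curve, n_expected = 2, width = 5) {
  v_eq <- find_equivalence_points(curve, n_expected, width)
  pka <- pka_from_half_equivalence(curve, v_eq)
  tibble(step = seq_along(v_eq), v_equivalence_ml = v_eq, pka = pka)
}
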