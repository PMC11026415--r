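# ---------------------------------------------------------------------------
# K1 from the low-pH curve, and the global multi-pH fit for K1-K3
# ---------------------------------------------------------------------------

# Approximate spectator background (Na, Cl) for measured curves, from the
# protocol recipe: initial buffer sodium, chloride from the CaCl2 titrant,
# and the acid spike neutralised by NaOH counter-titration. The residual
# counter demand from speciation shifts is small and ignored here; the model
# engines recompute it exactly when predicting whole curves.
reconstruct_background <- function(curve, protocol, acid) {
  init <- init_buffer(protocol, acid)
  v_titrant <- curve$added_ca_mol / protocol$titrant_conc
  hcl <- if (protocol$acidified_titrant) {
    protocol$titrant_hcl_conc * v_titrant
  } else {
    0
  }
  list(na_mol = init$na_mol + hcl,
       cl_mol = init$cl_mol + 2 * curve$added_ca_mol + hcl,
       n_p = init$n_p)
}

#' Direct determination of K1 from a low-pH titration curve
#'
#' At pH around 4.3, H2PO4- dominates the phosphate speciation, so all bound
#' calcium can be attributed to the \verb{[CaH2PO4]+} pair and K1 follows
#' point-by-point from the law of mass action,
#' \eqn{K_1 = a_{pair} / (a_{Ca} a_{H2PO4})}, with the bound amount taken
#' from `added - measured free`. Points with non-positive bound amounts are
#' skipped with a warning.
#'
#' @param curve A single-replicate, pre-nucleation titration-curve tibble at
#'   pH <= 5.
#' @param acid An [acid_constants()] object.
#' @param protocol The [titration_protocol()] describing the recipe (total
#'   phosphate and background electrolyte).
#'
#' @return A one-row tibble: `k1` (mean over points), `k1_sd`, `n_points`,
#'   `n_skipped`.
#' @export
fit_k1_direct <- function(curve, acid = acid_constants(),
                          protocol = titration_protocol(target_ph = 4.3)) {
  ph <- curve$ph[1]
  if (ph > 5) abort("Direct K1 determination requires pH <= 5.")
  bg <- reconstruct_background(curve, protocol, acid)
  n_bound <- curve$added_ca_mol - curve$free_ca_mol_per_l * curve$volume_l
  keep <- n_bound > 0
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warn(sprintf("Skipping %d point(s) with non-positive bound calcium.",
                 n_skipped))
  }
  if (!any(keep)) abort("No usable points: all bound amounts non-positive.")
  f <- phosphate_fractions_mat(ph, acid)
  v <- curve$volume_l[keep]
  nb <- n_bound[keep]
  p_free <- bg$n_p - nb
  free_c <- curve$free_ca_mol_per_l[keep]
  # self-consistent ionic strength of the measured state
  I <- rep(0.02, sum(keep))
  for (it in 1:200) {
    g1 <- davies_gamma(1, I); g2 <- davies_gamma(2, I); g3 <- davies_gamma(3, I)
    ch <- 10^(-ph) / g1
    coh <- 10^(-(acid$pkw - ph)) / g1
    I_new <- 0.5 * ((bg$na_mol[keep] + bg$cl_mol[keep]) / v + 4 * free_c +
                      (f[2] + 4 * f[3] + 9 * f[4]) * p_free / v +
                      nb / v + ch + coh)  # pair taken as charge +1 here
    if (all(abs(I_new - I) / pmax(I_new, 1e-12) < 1e-12)) { I <- I_new; break }
    I <- (I + I_new) / 2
  }
  a_ca <- g2 * free_c
  a_h2po4 <- g1 * f[2] * p_free / v
  a_pair <- g1 * nb / v
  k1_points <- a_pair / (a_ca * a_h2po4)
  tibble(k1 = mean(k1_points),
         k1_sd = stats::sd(k1_points),
         n_points = sum(keep), n_skipped = n_skipped)
}

#' Global least-squares fit of the association constants
#'
#' Minimises the summed squared residuals between measured and modelled
#' free-calcium concentrations over all points of all curves, across pH
#' values. The constants are optimised in log space (they span five orders
#' of magnitude) with three deterministic starts around `init`. By default
#' K1 is fixed to its direct low-pH determination when a curve at pH <= 5 is
#' present, mirroring the direct law-of-mass-action route; otherwise K1 is
#' fitted (or fixed via `fix_k1`).
#'
#' @param curves A titration-curve tibble (multiple replicates/pH values;
#'   column `ph` groups curves). Curves must span at least 2 pH values and
#'   be pre-truncated to the pre-nucleation regime.
#' @param model `"predictive"` (coupled mass-action solve from dosed amounts,
#'   the default) or `"direct"` (measured-bound-based model).
#' @param acid An [acid_constants()] object.
#' @param init A [binding_constants()] object with starting values.
#' @param protocol The [titration_protocol()] describing the shared recipe
#'   (pH is taken per curve group).
#' @param fix_k1 Optional fixed K1 value; overrides the automatic direct
#'   determination. `NA` forces K1 to be fitted.
#' @param weights `"none"` (default, unweighted SSE) or `"inverse_variance"`
#'   (per-curve inverse-variance weights).
#' @param n_starts Number of deterministic optimiser starts (1-3), spaced
#'   +-0.5 log units around `init`.
#' @param reltol Relative convergence tolerance of the optimiser.
#'
#' @return An object of class `capion_fit`: estimates as
#'   [binding_constants()], per-curve RMS residuals, the objective value,
#'   model tag, and convergence information. Use [tidy()] / [glance()] to
#'   extract tabular summaries, and [binding_error_bounds()] for
#'   tolerance-scan error bounds.
#' @export
fit_binding_constants <- function(curves,
                                  model = c("predictive", "direct"),
                                  acid = acid_constants(),
                                  init = binding_constants(5, 500, 5e4),
                                  protocol = titration_protocol(),
                                  fix_k1 = NULL,
                                  weights = c("none", "inverse_variance"),
                                  n_starts = 3, reltol = 1e-10) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  validate_titration_curve(curves, tol = Inf)
  ph_values <- sort(unique(curves$ph))
  if (length(ph_values) < 2) abort("Need curves spanning at least 2 pH values.")

  # K1 handling: direct determination from a low-pH curve when available
  k1_source <- "fitted"
  low <- curves[curves$ph <= 5, ]
  if (is.null(fix_k1) && nrow(low) > 0) {
    k1s <- vapply(split(low, low$replicate), function(cc) {
      fit_k1_direct(cc, acid,
                    protocol_at_ph(protocol, cc$ph[1]))$k1
    }, numeric(1))
    fix_k1 <- mean(k1s)
    k1_source <- "direct_low_ph"
  } else if (!is.null(fix_k1) && !is.na(fix_k1)) {
    k1_source <- "fixed"
  } else {
    fix_k1 <- NULL
  }
  if (max(ph_values) < 9) {
    warn(paste("No curve above pH 9: K3 is weakly identifiable",
               "(PO4(3-) signal is negligible); expect wide bounds."))
  }

  fit_ph <- ph_values[ph_values > 5 | length(ph_values) == sum(ph_values <= 5)]
  fit_curves <- curves[curves$ph %in% fit_ph, ]
  groups <- split(fit_curves, fit_curves$ph)
  dose_mol <- protocol$titrant_conc * protocol$dose_step_ml / 1000
  wt <- lapply(groups, function(g) {
    if (weights == "inverse_variance") {
      v <- stats::var(g$free_ca_mol_per_l)
      rep(1 / max(v, 1e-300), nrow(g))
    } else {
      rep(1, nrow(g))
    }
  })

  model_group <- function(g, k) {
    ph <- g$ph[1]
    idx <- as.integer(round(g$added_ca_mol / dose_mol))
    prot <- protocol_at_ph(protocol, ph)
    pc <- predict_curve(prot, k, acid, n_steps = max(idx))
    if (model == "predictive") {
      pc$free_ca_mol_per_l[idx]
    } else {
      bg <- reconstruct_background(g, prot, acid)
      direct_free_calcium(g$added_ca_mol, g$free_ca_mol_per_l,
                          bg$n_p, ph, g$volume_l, k, acid,
                          na_mol = bg$na_mol,
                          cl_mol = bg$cl_mol)$free_ca_pred_mol_per_l
    }
  }

  make_k <- function(par) {
    if (is.null(fix_k1)) {
      binding_constants(exp(par[1]), exp(par[2]), exp(par[3]),
                        protocol$temperature_k)
    } else {
      binding_constants(fix_k1, exp(par[1]), exp(par[2]),
                        protocol$temperature_k)
    }
  }
  objective <- function(par) {
    k <- make_k(par)
    tot <- 0
    for (i in seq_along(groups)) {
      pred <- model_group(groups[[i]], k)
      tot <- tot + sum(wt[[i]] * (pred - groups[[i]]$free_ca_mol_per_l)^2)
    }
    tot
  }

  par0 <- if (is.null(fix_k1)) log(c(init$k1, init$k2, init$k3)) else
    log(c(init$k2, init$k3))
  best <- NULL
  for (off in c(0, 0.5, -0.5)[seq_len(n_starts)]) {
    o <- stats::optim(par0 + off, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  k_hat <- make_k(best$par)

  per_curve <- dplyr::bind_rows(lapply(groups, function(g) {
    pred <- model_group(g, k_hat)
    g$pred <- pred
    dplyr::summarise(
      dplyr::group_by(g, .data$ph, .data$replicate),
      rms_resid_mol_per_l = sqrt(mean((.data$pred - .data$free_ca_mol_per_l)^2)),
      rms_rel_resid = sqrt(mean(((.data$pred - .data$free_ca_mol_per_l) /
                                   pmax(.data$free_ca_mol_per_l, 1e-300))^2)),
      n_points = dplyr::n(), .groups = "drop")
  }))

  structure(
    list(estimates = k_hat, k1_source = k1_source,
         model = model, sse = best$value,
         convergence = best$convergence,
         per_curve = per_curve,
         acid = acid, protocol = protocol,
         n_points = nrow(fit_curves),
         ph_values = ph_values,
         bounds = NULL),
    class = "capion_fit"
  )
}

# protocol copy with a different target pH
protocol_at_ph <- function(protocol, ph) {
  p <- unclass(protocol)
  p$target_ph <- ph
  structure(p, class = "titration_protocol")
}

#' @export
print.capion_fit <- function(x, ...) {
  k <- x$estimates
  cat(sprintf("<capion_fit> %s model, K1 = %.3g (%s), K2 = %.4g, K3 = %.5g\n",
              x$model, k$k1, x$k1_source, k$k2, k$k3))
  cat(sprintf("  SSE = %.4g over %d points at pH {%s}\n", x$sse, x$n_points,
              paste(format(x$ph_values), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy capion_fit
#' @export
#' @rdname fit_binding_constants
#' @param x A `capion_fit` object.
#' @param ... Unused.
tidy.capion_fit <- function(x, ...) {
  k <- x$estimates
  out <- tibble(
    term = c("K1", "K2", "K3"),
    estimate = c(k$k1, k$k2, k$k3),
    source = c(x$k1_source, "fitted", "fitted")
  )
  if (!is.null(x$bounds)) {
    out <- dplyr::left_join(out, x$bounds, by = "term")
  }
  out
}

#' @method glance capion_fit
#' @export
#' @rdname fit_binding_constants
glance.capion_fit <- function(x, ...) {
  tibble(sse = x$sse, n_points = x$n_points,
         n_curves = nrow(x$per_curve),
         n_ph = length(x$ph_values),
         model = x$model, convergence = x$convergence)
}

#' Tolerance-scan error bounds for fitted association constants
#'
#' For each constant in turn, scans a log-spaced grid around the best-fit
#' value (the others held fixed) and reports the interval within which the
#' worst per-curve RMS relative deviation between model and measurement
#' stays below `tolerance`. The default tolerance of 5% reflects the typical
#' between-replicate reproducibility of such titrations. Intervals that run
#' into the grid edge are flagged one-sided.
#'
#' @param fit A `capion_fit` from [fit_binding_constants()].
#' @param curves The curves the fit was run on.
#' @param tolerance Worst per-curve RMS relative deviation defining the
#'   acceptable-agreement range.
#' @param span Half-width of the scan grid in log10 units.
#' @param n_grid Number of grid points per side.
#'
#' @return The fit object with a `bounds` tibble attached (`term`, `lower`,
#'   `upper`, `half_width`, `one_sided`); also returned via `tidy()`.
#' @export
binding_error_bounds <- function(fit, curves, tolerance = 0.05,
                                 span = 1, n_grid = 17) {
  stopifnot(inherits(fit, "capion_fit"))
  validate_titration_curve(curves, tol = Inf)
  fit_ph <- fit$ph_values[fit$ph_values > 5 |
                            length(fit$ph_values) == sum(fit$ph_values <= 5)]
  groups <- split(curves[curves$ph %in% fit_ph, ],
                  curves$ph[curves$ph %in% fit_ph])
  dose_mol <- fit$protocol$titrant_conc * fit$protocol$dose_step_ml / 1000

  worst_dev <- function(k) {
    mx <- 0
    for (g in groups) {
      idx <- as.integer(round(g$added_ca_mol / dose_mol))
      pc <- predict_curve(protocol_at_ph(fit$protocol, g$ph[1]), k, fit$acid,
                          n_steps = max(idx))
      pred <- pc$free_ca_mol_per_l[idx]
      for (rep_id in unique(g$replicate)) {
        sel <- g$replicate == rep_id
        dev <- sqrt(mean(((pred[sel] - g$free_ca_mol_per_l[sel]) /
                            pmax(g$free_ca_mol_per_l[sel], 1e-300))^2))
        mx <- max(mx, dev)
      }
    }
    mx
  }

  k_best <- fit$estimates
  terms <- c("K1", "K2", "K3")
  rows <- vector("list", 3)
  for (i in 1:3) {
    kv <- c(k_best$k1, k_best$k2, k_best$k3)
    grid <- kv[i] * 10^seq(-span, span, length.out = 2 * n_grid + 1)
    ok <- vapply(grid, function(val) {
      kv2 <- kv; kv2[i] <- val
      worst_dev(binding_constants(kv2[1], kv2[2], kv2[3],
                                  k_best$temperature)) <= tolerance
    }, logical(1))
    centre <- n_grid + 1
    if (!ok[centre]) {
      rows[[i]] <- tibble(term = terms[i], lower = NA_real_, upper = NA_real_,
                          half_width = NA_real_, one_sided = NA)
      next
    }
    lo <- centre; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- centre; while (hi < length(grid) && ok[hi + 1]) hi <- hi + 1
    rows[[i]] <- tibble(
      term = terms[i], lower = grid[lo], upper = grid[hi],
      half_width = (grid[hi] - grid[lo]) / 2,
      one_sided = lo == 1 || hi == length(grid)
    )
  }
  fit$bounds <- dplyr::bind_rows(rows)
  fit
}
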