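# ---------------------------------------------------------------------------
# CSV dialect, run configuration, and reports
# ---------------------------------------------------------------------------

TITRATION_COLUMNS <- c("replicate", "added_ca_mol", "free_ca_mol_per_l",
                       "ph", "volume_l", "temperature_k")

#' Read titration curves from CSV
#'
#' Reads the package's titration CSV dialect: a header with at least the
#' columns `replicate, added_ca_mol, free_ca_mol_per_l, ph, volume_l,
#' temperature_k` (units fixed in the names: mol, mol/L, L, K; decimal
#' point, not comma). Curves are validated on load; violations are reported
#' with the offending row number.
#'
#' @param path Path to a CSV file.
#' @return A validated titration-curve tibble (replicates stacked, grouped
#'   by the `replicate` column).
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(TITRATION_COLUMNS, names(df))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  num <- setdiff(TITRATION_COLUMNS, "replicate")
  for (nm in num) {
    if (!is.numeric(df[[nm]])) {
      abort(sprintf("Column `%s` must be numeric.", nm))
    }
  }
  df$replicate <- as.character(df$replicate)
  validate_titration_curve(df)
  as_tibble(df)
}

#' Write titration curves to CSV
#'
#' @param curve A titration-curve tibble.
#' @param path Output path.
#' @param digits Significant digits to keep (default full precision).
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path, digits = 17) {
  validate_titration_curve(curve, tol = Inf)
  out <- curve[intersect(c(TITRATION_COLUMNS,
                           setdiff(names(curve), TITRATION_COLUMNS)),
                         names(curve))]
  readr::write_csv(out, path)
  invisible(path)
}

#' Split a multi-replicate curve table into a list of single curves
#'
#' @param curves A titration-curve tibble.
#' @return A named list of single-replicate tibbles.
#' @export
split_replicates <- function(curves) {
  split(curves, curves$replicate)
}

#' Read a run configuration
#'
#' Reads a YAML run configuration with optional sections `protocol` (fields
#' of [titration_protocol()]), `acid` (fields of [acid_constants()]),
#' `constants` (either `preset:` naming a [binding_preset()], or explicit
#' `k1/k2/k3/temperature`), `artifact` (fields of [artifact_model()]),
#' `fit` (options for [fit_binding_constants()]), `noise_cv`, and `seed`.
#' Unknown fields raise an error before any computation.
#'
#' @param path Path to a YAML file.
#' @return A list of class `capion_config` with fully-constructed component
#'   objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("protocol", "acid", "constants", "artifact", "fit",
             "noise_cv", "seed", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  build <- function(fields, ctor) {
    if (is.null(fields)) return(ctor())
    do.call(ctor, fields)
  }
  constants <- if (is.null(raw$constants)) {
    binding_preset("revised_25C")
  } else if (!is.null(raw$constants$preset)) {
    binding_preset(raw$constants$preset)
  } else {
    do.call(binding_constants, raw$constants)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  proto_fields <- raw$protocol
  if (!is.null(proto_fields) && is.null(proto_fields$seed)) {
    proto_fields$seed <- seed
  }
  structure(list(
    protocol = build(proto_fields, titration_protocol),
    acid = build(raw$acid, acid_constants),
    constants = constants,
    artifact = build(raw$artifact, artifact_model),
    fit = raw$fit,
    noise_cv = if (is.null(raw$noise_cv)) 0.01 else raw$noise_cv,
    seed = seed,
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir
  ), class = "capion_config")
}

#' Write a generation manifest alongside simulated data
#'
#' Records every protocol parameter, the generator constants, the artifact
#' settings, the noise level and the seed, so a simulated dataset can be
#' regenerated exactly.
#'
#' @param path Output YAML path.
#' @param protocol,k,acid,artifact,noise_cv Generation inputs.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, protocol, k, acid, artifact,
                           noise_cv) {
  yaml::write_yaml(list(
    protocol = unclass(protocol),
    constants = unclass(k),
    acid = unclass(acid),
    artifact = unclass(artifact),
    noise_cv = noise_cv,
    package_version = as.character(utils::packageVersion("capion"))
  ), path)
  invisible(path)
}
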