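#' Read or write a cohort configuration as a declarative YAML file
#'
#' The on-disk schema is a flat key-value YAML document with exactly the
#' fields of [cohort_config()]; `planted_effects` is a mapping from
#' feature name to log-hazard coefficient. Reading validates through the
#' constructor, so a round trip reproduces the configuration exactly.
#'
#' @param path YAML file path.
#' @return `read_cohort_config()` a `cohort_config`;
#'   `write_cohort_config()` the path, invisibly.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- numeric(0)
  if (!is.null(y$planted_effects) && length(y$planted_effects))
    eff <- unlist(y$planted_effects)
  cohort_config(
    n_patients = y$n_patients,
    volume_shape = unlist(y$volume_shape),
    voxel_spacing_mm = unlist(y$voxel_spacing_mm),
    lesion_radius_range_mm = unlist(y$lesion_radius_range_mm),
    texture_correlation_lengths = unlist(y$texture_correlation_lengths),
    n_mutation_genes = y$n_mutation_genes,
    n_expression_genes = y$n_expression_genes,
    n_proteins = y$n_proteins,
    planted_effects = eff,
    baseline_hazard = y$baseline_hazard,
    censoring_rate = y$censoring_rate,
    seed = y$seed)
}

#' @param config a `cohort_config`.
#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- unclass(config)
  y$planted_effects <- as.list(y$planted_effects)
  yaml::write_yaml(y, path)
  invisible(path)
}
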