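#' Configuration for a synthetic multi-omic survival cohort
#'
#' Bundles every dial of the generator: cohort size, lesion geometry and
#' texture, omic block sizes, planted log-hazard effects, baseline hazard
#' and censoring. Defaults emulate a 200-patient glioblastoma-like study
#' with 32^3-voxel volumes at 1 mm spacing, lesions of 6-10 mm radius,
#' texture correlation lengths between 1 and 6 mm, 100 mutation genes,
#' 500 expression genes, the routine 6-protein IHC panel, 20% censoring
#' and a baseline hazard of 1/400 per day (median survival around one
#' year under the null).
#'
#' @param n_patients cohort size (>= 2).
#' @param volume_shape voxel grid triple.
#' @param voxel_spacing_mm positive spacing triple.
#' @param lesion_radius_range_mm min/max lesion radius in mm.
#' @param texture_correlation_lengths either a length-2 range (sampled
#'   per patient) or a length-`n_patients` vector of correlation lengths
#'   in mm.
#' @param n_mutation_genes binary mutation genes (default 100).
#' @param n_expression_genes expression genes (default 500).
#' @param n_proteins IHC proteins on the 0-3 ordinal score scale
#'   (default 6).
#' @param planted_effects named numeric vector: feature column name ->
#'   log-hazard coefficient per standard deviation.
#' @param baseline_hazard event rate per day.
#' @param censoring_rate target censored fraction in `[0, 1)`.
#' @param seed master integer seed; all randomness derives from it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 200L,
                          volume_shape = c(32L, 32L, 32L),
                          voxel_spacing_mm = c(1, 1, 1),
                          lesion_radius_range_mm = c(6, 10),
                          texture_correlation_lengths = c(1, 6),
                          n_mutation_genes = 100L,
                          n_expression_genes = 500L,
                          n_proteins = 6L,
                          planted_effects = numeric(0),
                          baseline_hazard = 1 / 400,
                          censoring_rate = 0.2,
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("n_patients must be at least 2")
  if (any(voxel_spacing_mm <= 0)) stop("voxel spacing must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (length(lesion_radius_range_mm) != 2L ||
      lesion_radius_range_mm[1] > lesion_radius_range_mm[2])
    stop("lesion_radius_range_mm must be an increasing pair")
  if (!length(texture_correlation_lengths) %in% c(2L, n_patients))
    stop("texture_correlation_lengths must be a range or per-patient vector")
  if (length(planted_effects) &&
      (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects)))))
    stop("planted_effects must be a named numeric vector")
  structure(list(
    n_patients = n_patients,
    volume_shape = as.integer(volume_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
    texture_correlation_lengths = as.numeric(texture_correlation_lengths),
    n_mutation_genes = as.integer(n_mutation_genes),
    n_expression_genes = as.integer(n_expression_genes),
    n_proteins = as.integer(n_proteins),
    planted_effects = planted_effects,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)), class = "cohort_config")
}

protein_panel_names <- function(k) {
  panel <- c("ki67", "egfr", "pten", "cd44", "p53", "vimentin")
  if (k <= length(panel)) panel[seq_len(k)]
  else c(panel, sprintf("protein%02d", seq_len(k - length(panel))))
}

#' Generate a complete synthetic study
#'
#' Draws, per patient, a textured lesion (volume + mask), extracts its
#' 45-feature radiomic vector, and simulates clinical covariates (age,
#' sex, KPS, therapy type), a binary gene-mutation block, an expression
#' block and an IHC protein block. Overall survival follows a
#' proportional-hazards model over the standardized feature table with
#' the configured planted effects, plus independent exponential
#' censoring. If `out_dir` is given the dataset is written to disk
#' (NIfTI volumes/masks, CSV tables, JSON manifest with the seed and a
#' config hash). Bit-identical for a given config.
#'
#' @param config a `cohort_config`.
#' @param out_dir optional output directory; created if missing.
#' @param write_volumes write NIfTI volumes/masks when `out_dir` is set
#'   (default TRUE).
#' @return (invisibly when writing) list with `clinical`, `radiomics`,
#'   `mutations`, `expression`, `proteins` data.frames, the standardized
#'   `feature_table` used for the hazard model, per-patient `volumes`
#'   and `masks`, and the `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL, write_volumes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  radii <- stats::runif(n, config$lesion_radius_range_mm[1],
                        config$lesion_radius_range_mm[2])
  tcl <- config$texture_correlation_lengths
  scales <- if (length(tcl) == 2L) stats::runif(n, tcl[1], tcl[2]) else tcl

  # clinical covariates, drawn to resemble an adult GBM cohort
  age <- round(pmin(pmax(stats::rnorm(n, 61, 12), 18), 85))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  kps <- sample(seq(40, 100, 10), n, replace = TRUE,
                prob = c(.03, .07, .10, .20, .25, .25, .10))
  therapy <- sample(c("RT+TMZ", "RT", "none"), n, replace = TRUE,
                    prob = c(.70, .20, .10))

  mut_rates <- stats::runif(config$n_mutation_genes, 0.02, 0.4)
  mutations <- vapply(mut_rates, function(r) stats::rbinom(n, 1L, r),
                      integer(n))
  colnames(mutations) <- sprintf("gene%03d", seq_len(config$n_mutation_genes))
  expression <- matrix(stats::rnorm(n * config$n_expression_genes),
                       n, config$n_expression_genes)
  colnames(expression) <- sprintf("tx%04d", seq_len(config$n_expression_genes))
  proteins <- vapply(seq_len(config$n_proteins), function(k)
    sample(0:3, n, replace = TRUE, prob = c(.25, .30, .30, .15)),
    integer(n))
  colnames(proteins) <- protein_panel_names(config$n_proteins)

  # lesions + radiomic features, one derived seed per patient
  volumes <- vector("list", n)
  masks <- vector("list", n)
  radiomics <- matrix(NA_real_, n, 45,
                      dimnames = list(NULL, radiomic_feature_names()))
  for (k in seq_len(n)) {
    ls <- generate_lesion(config$volume_shape, config$voxel_spacing_mm,
                          radius_mm = radii[k], texture_scale_mm = scales[k],
                          seed = (config$seed %% 100000L) * 10007L + k)
    volumes[[k]] <- ls$volume
    masks[[k]] <- ls$mask
    radiomics[k, ] <- extract_all(normalize_intensity(ls$volume), ls$mask)
  }

  # standardized feature table spanning all blocks; hazards are log-linear
  # in these z-scores
  clin_num <- cbind(age = age, kps = kps,
                    sex_male = as.integer(sex == "M"),
                    therapy_rt_tmz = as.integer(therapy == "RT+TMZ"),
                    therapy_rt = as.integer(therapy == "RT"))
  raw <- cbind(radiomics, clin_num,
               `colnames<-`(mutations, paste0("mut_", colnames(mutations))),
               `colnames<-`(expression, paste0("expr_", colnames(expression))),
               `colnames<-`(proteins, paste0("prot_", colnames(proteins))))
  z <- scale(raw)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- as.data.frame(z)

  eff <- config$planted_effects
  if (length(eff)) {
    bad <- setdiff(names(eff), colnames(z))
    if (length(bad))
      stop("planted_effects name features the generator does not produce: ",
           paste(bad, collapse = ", "))
  }
  surv <- generate_survival(z, eff, baseline = config$baseline_hazard,
                            censoring_rate = config$censoring_rate,
                            seed = (config$seed %% 100000L) * 10007L + n + 1L)

  clinical <- data.frame(patient_id = ids, age = age, sex = sex, kps = kps,
                         therapy_type = therapy,
                         os_days = surv$os_days, event = surv$event)
  out <- list(
    clinical = clinical,
    radiomics = data.frame(patient_id = ids, radiomics),
    mutations = data.frame(patient_id = ids, mutations),
    expression = data.frame(patient_id = ids, expression),
    proteins = data.frame(patient_id = ids, proteins),
    feature_table = z,
    volumes = volumes,
    masks = masks,
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f)
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    wr(out$clinical, "clinical.csv")
    wr(out$radiomics, "features.csv")
    wr(out$mutations, "mutations.csv")
    wr(out$expression, "expression.csv")
    wr(out$proteins, "proteins.csv")
    if (write_volumes) {
      for (k in seq_len(n)) {
        write_volume(volumes[[k]],
                     file.path(out_dir, sprintf("vol_%s.nii.gz", ids[k])))
        write_volume(masks[[k]],
                     file.path(out_dir, sprintf("mask_%s.nii.gz", ids[k])))
      }
    }
    manifest <- list(seed = config$seed,
                     config = unclass(config),
                     config_hash = rlang::hash(unclass(config)),
                     n_patients = n)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
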