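#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_experiment()], [simulate_annotation()] and
#' [simulate_coverage()]. Defaults emulate a 5-strain RNAi study:
#' 5 wild-isolate strains x 3 treatments (empty-vector control, par-1
#' RNAi, pos-1 RNAi) x 3 biological replicates, with roughly a third of
#' genes differentially expressed between strains, a twentieth carrying
#' strain-by-treatment interactions, and a small tail of genes
#' structurally unexpressed ("off") in one or more strains.
#'
#' @param n_genes number of genes to simulate.
#' @param strains character vector of strain labels; the first is taken
#'   as the reference unless `reference_strain` says otherwise.
#' @param reference_strain label of the reference strain.
#' @param treatments character vector of treatment labels; the first is
#'   the control unless `control_treatment` says otherwise.
#' @param control_treatment label of the control treatment.
#' @param n_replicates biological replicates per strain x treatment cell.
#' @param baseline_mean_log2,baseline_sd_log2 log2-normal parameters of
#'   the per-gene baseline expected count.
#' @param dispersion_alpha NB dispersion (variance = mu + alpha * mu^2);
#'   a scalar, a length-`n_genes` vector, or a function of `n` returning
#'   per-gene values.
#' @param frac_strain_de fraction of genes with a strain effect.
#' @param frac_interaction fraction with a strain:treatment interaction.
#' @param frac_treatment_de fraction with a treatment main effect.
#' @param frac_off fraction structurally unexpressed in >= 1 strain;
#'   off genes are drawn from the strain-DE genes.
#' @param frac_missing_cov,frac_low_cov fractions of genes whose DNA
#'   coverage is zero (missing) or below 25% of the strain median (low)
#'   in at least one non-reference strain.
#' @param effect_size_log2 |beta| (log2) planted for DE genes.
#' @param off_min_mean floor on the baseline mean of off genes, so that
#'   their expression in non-off strains is unambiguous.
#' @param library_size_spread fold-range of per-sample depth factors
#'   (drawn log-uniformly within it).
#' @param coverage_depth mean per-base DNA depth of an adequate gene.
#' @param coverage_noise_sd lognormal sd of coverage noise; 0 = exact.
#' @param annotation_overlap_frac fraction of genes given duplicated /
#'   overlapping exon records (multi-transcript mimicry).
#' @param seed integer seed; identical configs give identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       strains = c("N2", "CB4856", "JU1088", "EG4348", "QX1211"),
                       reference_strain = strains[1],
                       treatments = c("control", "par1", "pos1"),
                       control_treatment = treatments[1],
                       n_replicates = 3,
                       baseline_mean_log2 = 6,
                       baseline_sd_log2 = 2,
                       dispersion_alpha = 0.05,
                       frac_strain_de = 0.34,
                       frac_interaction = 0.05,
                       frac_treatment_de = 0.10,
                       frac_off = 0.026,
                       frac_missing_cov = 0.015,
                       frac_low_cov = 0.025,
                       effect_size_log2 = 2,
                       off_min_mean = 200,
                       library_size_spread = 3,
                       coverage_depth = 30,
                       coverage_noise_sd = 0.15,
                       annotation_overlap_frac = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, strains = strains,
    reference_strain = reference_strain,
    treatments = treatments, control_treatment = control_treatment,
    n_replicates = n_replicates,
    baseline_mean_log2 = baseline_mean_log2,
    baseline_sd_log2 = baseline_sd_log2,
    dispersion_alpha = dispersion_alpha,
    frac_strain_de = frac_strain_de,
    frac_interaction = frac_interaction,
    frac_treatment_de = frac_treatment_de,
    frac_off = frac_off,
    frac_missing_cov = frac_missing_cov,
    frac_low_cov = frac_low_cov,
    effect_size_log2 = effect_size_log2,
    off_min_mean = off_min_mean,
    library_size_spread = library_size_spread,
    coverage_depth = coverage_depth,
    coverage_noise_sd = coverage_noise_sd,
    annotation_overlap_frac = annotation_overlap_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_genes) || length(cfg$n_genes) != 1 ||
      cfg$n_genes < 0 || cfg$n_genes != round(cfg$n_genes)) {
    stop("invalid 'n_genes': must be a single nonnegative integer")
  }
  if (length(cfg$strains) < 1 || anyDuplicated(cfg$strains)) {
    stop("invalid 'strains': need >= 1 unique strain label")
  }
  if (length(cfg$treatments) < 1 || anyDuplicated(cfg$treatments)) {
    stop("invalid 'treatments': need >= 1 unique treatment label")
  }
  if (!cfg$reference_strain %in% cfg$strains || length(cfg$reference_strain) != 1) {
    stop("invalid 'reference_strain': must be exactly one of 'strains'")
  }
  if (!cfg$control_treatment %in% cfg$treatments || length(cfg$control_treatment) != 1) {
    stop("invalid 'control_treatment': must be exactly one of 'treatments'")
  }
  if (cfg$n_replicates < 1) stop("invalid 'n_replicates': must be >= 1")
  for (f in c("frac_strain_de", "frac_interaction", "frac_treatment_de",
              "frac_off", "frac_missing_cov", "frac_low_cov")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("invalid '%s': must be a proportion in [0, 1]", f))
    }
  }
  if (cfg$frac_off > cfg$frac_strain_de) {
    stop("invalid 'frac_off': must be <= 'frac_strain_de' (off genes are a subset of strain-DE genes)")
  }
  if (cfg$frac_missing_cov + cfg$frac_low_cov > 1) {
    stop("invalid 'frac_missing_cov'/'frac_low_cov': fractions sum above 1")
  }
  if (!is.function(cfg$dispersion_alpha) &&
      (any(cfg$dispersion_alpha < 0) || !is.numeric(cfg$dispersion_alpha))) {
    stop("invalid 'dispersion_alpha': must be nonnegative")
  }
  if (cfg$effect_size_log2 <= 0) stop("invalid 'effect_size_log2': must be positive")
  if (cfg$library_size_spread < 1) stop("invalid 'library_size_spread': must be >= 1")
  invisible(cfg)
}

#' Construct a sample design table
#'
#' @param sample data.frame-compatible vectors of sample id, strain,
#'   treatment and replicate.
#' @param reference_strain,control_treatment declared reference levels.
#' @return data.frame with class `sample_design` and reference levels
#'   stored as attributes; strain and treatment are factors with the
#'   reference level first.
#' @export
sample_design <- function(sample, strain, treatment, replicate,
                          reference_strain, control_treatment) {
  d <- data.frame(sample = as.character(sample),
                  strain = as.character(strain),
                  treatment = as.character(treatment),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample)) stop("duplicated sample ids in design")
  if (!reference_strain %in% d$strain) {
    stop("reference strain '", reference_strain, "' absent from design")
  }
  if (!control_treatment %in% d$treatment) {
    stop("control treatment '", control_treatment, "' absent from design")
  }
  d$strain <- stats::relevel(factor(d$strain), ref = reference_strain)
  d$treatment <- stats::relevel(factor(d$treatment), ref = control_treatment)
  attr(d, "reference_strain") <- reference_strain
  attr(d, "control_treatment") <- control_treatment
  class(d) <- c("sample_design", "data.frame")
  d
}

reference_strain <- function(design) attr(design, "reference_strain")
control_treatment <- function(design) attr(design, "control_treatment")
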