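#' Simulate a multi-strain RNAi expression experiment
#'
#' Draws a gene x sample count matrix from the negative binomial model
#' the downstream tests assume: for gene i and sample j,
#' counts ~ NB(mean = s_j * q_ij, variance = mu + alpha * mu^2), where
#' log2 q_ij is assembled from a per-gene baseline, a strain effect
#' (beta1), a treatment effect (beta2) and a strain:treatment
#' interaction (beta3), and s_j is a per-sample depth factor drawn
#' log-uniformly within `library_size_spread`. Genes planted as "off" in
#' a strain have expected count exactly 0 in every sample of that
#' strain (structural zeros). Every planted signal is recorded in the
#' returned ground truth.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, dimnames set.}
#'     \item{design}{[sample_design()] data.frame.}
#'     \item{truth}{list of planted parameters: `mu` baseline means,
#'       `alpha` dispersions, `beta1` (genes x strains, log2),
#'       `beta2` (genes x treatments, log2), `beta3` (genes x
#'       strain:treatment cells, log2), `off` logical genes x strains,
#'       `coverage_class` character genes x strains, `size_factors`,
#'       and index vectors of planted DE / interaction / off genes.}
#'   }
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  strains <- config$strains
  treatments <- config$treatments
  S <- length(strains)
  Tt <- length(treatments)
  reps <- config$n_replicates

  grid <- expand.grid(replicate = seq_len(reps), treatment = treatments,
                      strain = strains, stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "treatment", "replicate")]
  sample_ids <- paste(grid$strain, grid$treatment, grid$replicate, sep = "_")
  design <- sample_design(sample_ids, grid$strain, grid$treatment,
                          grid$replicate, config$reference_strain,
                          config$control_treatment)
  m <- nrow(design)

  gene_ids <- if (n > 0) sprintf("gene%05d", seq_len(n)) else character(0)
  cellnames <- as.vector(outer(strains, treatments, paste, sep = ":"))

  empty_mat <- function(cols) {
    matrix(0, nrow = n, ncol = length(cols), dimnames = list(gene_ids, cols))
  }
  truth <- list(
    mu = stats::setNames(numeric(n), gene_ids),
    alpha = stats::setNames(numeric(n), gene_ids),
    beta1 = empty_mat(strains),
    beta2 = empty_mat(treatments),
    beta3 = empty_mat(cellnames),
    off = matrix(FALSE, n, length(strains), dimnames = list(gene_ids, strains)),
    coverage_class = matrix("adequate", n, length(strains),
                            dimnames = list(gene_ids, strains)),
    de_genes = character(0), interaction_genes = character(0),
    treatment_de_genes = character(0), off_genes = character(0)
  )

  if (n == 0) {
    counts <- matrix(0L, 0, m, dimnames = list(gene_ids, design$sample))
    truth$size_factors <- stats::setNames(rep(1, m), design$sample)
    return(list(counts = counts, design = design, truth = truth))
  }

  truth$mu <- stats::setNames(2^stats::rnorm(n, config$baseline_mean_log2,
                                             config$baseline_sd_log2), gene_ids)
  a <- config$dispersion_alpha
  truth$alpha <- stats::setNames(
    if (is.function(a)) a(n) else rep_len(a, n), gene_ids)

  nonref <- setdiff(strains, config$reference_strain)
  noncontrol <- setdiff(treatments, config$control_treatment)
  es <- config$effect_size_log2

  # strain-DE genes: each non-reference strain affected w.p. 1/2, >= 1
  n_de <- round(config$frac_strain_de * n)
  de_idx <- sort(sample.int(n, n_de))
  truth$de_genes <- gene_ids[de_idx]
  if (n_de > 0 && length(nonref) > 0) {
    for (i in de_idx) {
      hit <- stats::runif(length(nonref)) < 0.5
      if (!any(hit)) hit[sample.int(length(nonref), 1)] <- TRUE
      truth$beta1[i, nonref[hit]] <- es * sample(c(-1, 1), sum(hit), replace = TRUE)
    }
  }

  # treatment main effects (within-strain RNAi responses)
  n_tr <- round(config$frac_treatment_de * n)
  if (n_tr > 0 && length(noncontrol) > 0) {
    tr_idx <- sort(sample.int(n, n_tr))
    truth$treatment_de_genes <- gene_ids[tr_idx]
    for (i in tr_idx) {
      hit <- stats::runif(length(noncontrol)) < 0.5
      if (!any(hit)) hit[sample.int(length(noncontrol), 1)] <- TRUE
      truth$beta2[i, noncontrol[hit]] <- es * sample(c(-1, 1), sum(hit), replace = TRUE)
    }
  }

  # strain:treatment interactions on non-reference, non-control cells
  n_int <- round(config$frac_interaction * n)
  if (n_int > 0 && length(nonref) > 0 && length(noncontrol) > 0) {
    int_idx <- sort(sample.int(n, n_int))
    truth$interaction_genes <- gene_ids[int_idx]
    cells <- as.vector(outer(nonref, noncontrol, paste, sep = ":"))
    for (i in int_idx) {
      hit <- stats::runif(length(cells)) < 0.5
      if (!any(hit)) hit[sample.int(length(cells), 1)] <- TRUE
      truth$beta3[i, cells[hit]] <- es * sample(c(-1, 1), sum(hit), replace = TRUE)
    }
  }

  # off genes: subset of strain-DE genes, structural zeros in 1..S-1 strains
  n_off <- round(config$frac_off * n)
  if (n_off > 0 && S >= 2) {
    n_off <- min(n_off, n_de)
    off_idx <- sort(sample(de_idx, n_off))
    truth$off_genes <- gene_ids[off_idx]
    # counts of silent strains skewed toward 1 (most off genes are off in
    # a single strain)
    kprob <- c(0.60, 0.26, 0.12, 0.02)[seq_len(S - 1)]
    kprob <- kprob / sum(kprob)
    for (i in off_idx) {
      k <- sample.int(S - 1, 1, prob = kprob)
      truth$off[i, sample(strains, k)] <- TRUE
      truth$mu[i] <- max(truth$mu[i], config$off_min_mean)
    }
  }

  # coverage classes: missing / low planted in one random non-reference
  # strain per selected gene (the reference maps to itself)
  n_miss <- round(config$frac_missing_cov * n)
  n_low <- round(config$frac_low_cov * n)
  if ((n_miss + n_low) > 0 && length(nonref) > 0) {
    pick <- sample.int(n, n_miss + n_low)
    for (j in seq_along(pick)) {
      s <- sample(nonref, 1)
      truth$coverage_class[pick[j], s] <-
        if (j <= n_miss) "missing" else "low"
    }
  }

  s_j <- exp(stats::runif(m, -log(config$library_size_spread) / 2,
                          log(config$library_size_spread) / 2))
  truth$size_factors <- stats::setNames(s_j, design$sample)

  strain_j <- as.character(design$strain)
  treat_j <- as.character(design$treatment)
  cell_j <- paste(strain_j, treat_j, sep = ":")
  log2q <- log2(truth$mu) +
    truth$beta1[, strain_j, drop = FALSE] +
    truth$beta2[, treat_j, drop = FALSE] +
    truth$beta3[, cell_j, drop = FALSE]
  mu_mat <- 2^log2q * rep(s_j, each = n)
  off_mask <- truth$off[, strain_j, drop = FALSE]
  mu_mat[off_mask] <- 0

  # alpha = 0 is drawn as NB with a very large size (Poisson limit)
  size_vec <- rep(1 / pmax(truth$alpha, 1e-12), times = m)
  y <- stats::rnbinom(n * m, mu = as.vector(mu_mat), size = size_vec)
  counts <- matrix(as.integer(y), n, m,
                   dimnames = list(gene_ids, design$sample))
  list(counts = counts, design = design, truth = truth)
}
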