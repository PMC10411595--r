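#' Union of pairwise strain-vs-strain DE genes (control samples)
#'
#' Runs a Wald test between every pair of strains on control-condition
#' samples (2-level NB GLM per gene) and returns the union, over all
#' pairs, of genes with adjusted p below the threshold. With 5 strains
#' all 10 pairs are tested. No fold-change threshold is applied.
#'
#' @param counts gene x sample matrix of control samples (or the full
#'   matrix; non-control samples are dropped).
#' @param design [sample_design()] matching `counts` columns.
#' @param sf size factors (computed on the control subset when NULL).
#' @param alpha per-gene dispersions reused for every pair; estimated
#'   per pair when NULL.
#' @param fdr adjusted-p threshold (default 0.1).
#' @return character vector of gene ids in the union; attribute
#'   `pair_sets` is a named list of per-pair significant gene sets and
#'   `pairs_skipped` lists pairs dropped for want of replicates.
#' @export
pairwise_de_union <- function(counts, design, sf = NULL, alpha = NULL,
                              fdr = 0.1) {
  ctrl <- control_treatment(design)
  keep <- design$treatment == ctrl
  if (!is.null(sf)) sf <- sf[keep]
  if (!is.null(alpha) && length(alpha) > 1) {
    alpha <- rep_len(alpha, nrow(counts))
  }
  design <- design[keep, , drop = FALSE]
  counts <- counts[, keep, drop = FALSE]
  strains <- levels(droplevels(design$strain))
  if (length(strains) < 2) stop("need >= 2 strains with control samples")
  if (is.null(sf)) sf <- size_factors(counts)
  pair_sets <- list()
  skipped <- character(0)
  for (i in seq_len(length(strains) - 1)) {
    for (j in (i + 1):length(strains)) {
      s1 <- strains[i]
      s2 <- strains[j]
      sel <- design$strain %in% c(s1, s2)
      if (sum(design$strain == s1) < 2 || sum(design$strain == s2) < 2) {
        warning(sprintf("pair %s-%s skipped: < 2 control replicates", s1, s2))
        skipped <- c(skipped, paste(s1, s2, sep = "-"))
        next
      }
      dsub <- design[sel, , drop = FALSE]
      dsub$strain <- stats::relevel(droplevels(dsub$strain), ref = s1)
      csub <- counts[, sel, drop = FALSE]
      sfsub <- sf[sel]
      X <- stats::model.matrix(~strain, data = as.data.frame(dsub))
      a <- if (is.null(alpha)) {
        estimate_dispersion(csub, dsub, sfsub, formula = ~strain)$alpha
      } else rep_len(alpha, nrow(csub))
      p <- rep(NA_real_, nrow(csub))
      for (g in seq_len(nrow(csub))) {
        f <- fit_nb_glm(csub[g, ], X, sfsub, a[g])
        if (!f$degenerate && !is.na(f$loglik) && is.finite(f$se_log2[2]) &&
            f$se_log2[2] > 0) {
          p[g] <- 2 * stats::pnorm(-abs(f$coef_log2[2] / f$se_log2[2]))
        }
      }
      padj <- bh_adjust(p)
      pair_sets[[paste(s1, s2, sep = "-")]] <-
        rownames(csub)[!is.na(padj) & padj < fdr]
    }
  }
  out <- sort(unique(unlist(pair_sets)))
  attr(out, "pair_sets") <- pair_sets
  attr(out, "pairs_skipped") <- skipped
  out
}

#' Strains with exactly zero expression per gene
#'
#' A strain is reported for a gene iff every sample of that strain --
#' all treatments, all replicates -- has a count of exactly 0
#' (equivalently, zero mean expression). A single nonzero count in any
#' sample of the strain disqualifies it.
#'
#' @param counts gene x sample matrix covering all treatments.
#' @param design [sample_design()].
#' @return logical matrix, genes x strains; TRUE = zero in every
#'   sample of that strain.
#' @export
zero_expression_strains <- function(counts, design) {
  strains <- levels(design$strain)
  out <- sapply(strains, function(s) {
    rowSums(counts[, design$strain == s, drop = FALSE] > 0) == 0
  })
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), strains))
  out
}

#' Call off genes and resolve them against DNA coverage
#'
#' The off-gene set is the intersection of (a) genes differentially
#' expressed between at least one strain pair and (b) genes with zero
#' expression in at least one -- but not every -- strain. Each off
#' (gene, strain) is then categorized from that strain's DNA coverage
#' class: adequate coverage means the gene is truly unexpressed
#' ("truly_off"); zero raw coverage means the gene is putatively
#' missing from the strain's genome ("missing_genome"); low coverage
#' leaves the call uncertain ("uncertain_low_coverage").
#'
#' @param pairwise_union gene ids from [pairwise_de_union()].
#' @param zero_sets logical genes x strains matrix from
#'   [zero_expression_strains()].
#' @param coverage data.frame from [classify_coverage()] (gene_id,
#'   strain, cov_class); genes absent from it are categorized
#'   uncertain_low_coverage and reported in the `missing_from_coverage`
#'   attribute.
#' @return list:
#'   \describe{
#'     \item{records}{data.frame gene_id, strain, category -- one row
#'       per off (gene, strain).}
#'     \item{off_strains}{named list, per off gene, of its silent
#'       strains.}
#'     \item{per_strain_summary}{data.frame strain, truly_off,
#'       missing_genome, uncertain_low_coverage, total.}
#'     \item{n_off_strain_counts}{table of genes off in exactly
#'       1, 2, ... strains.}
#'   }
#' @export
call_off_genes <- function(pairwise_union, zero_sets, coverage) {
  strains <- colnames(zero_sets)
  n_zero <- rowSums(zero_sets)
  off_genes <- intersect(pairwise_union,
                         rownames(zero_sets)[n_zero >= 1 &
                                             n_zero < length(strains)])
  cov_key <- paste(coverage$gene_id, coverage$strain, sep = "\r")
  cov_class <- stats::setNames(coverage$cov_class, cov_key)
  recs <- list()
  off_strains <- list()
  absent <- character(0)
  for (g in off_genes) {
    ss <- strains[zero_sets[g, ]]
    off_strains[[g]] <- ss
    cls <- cov_class[paste(g, ss, sep = "\r")]
    if (any(is.na(cls))) absent <- c(absent, g)
    cat_ <- ifelse(is.na(cls), "uncertain_low_coverage",
                   c(adequate = "truly_off", missing = "missing_genome",
                     low = "uncertain_low_coverage")[cls])
    recs[[g]] <- data.frame(gene_id = g, strain = ss,
                            category = unname(cat_),
                            stringsAsFactors = FALSE)
  }
  records <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(gene_id = character(0), strain = character(0),
               category = character(0))
  rownames(records) <- NULL
  cats <- c("truly_off", "missing_genome", "uncertain_low_coverage")
  per_strain <- do.call(rbind, lapply(strains, function(s) {
    r <- records[records$strain == s, , drop = FALSE]
    cnt <- table(factor(r$category, levels = cats))
    data.frame(strain = s, truly_off = as.integer(cnt["truly_off"]),
               missing_genome = as.integer(cnt["missing_genome"]),
               uncertain_low_coverage =
                 as.integer(cnt["uncertain_low_coverage"]),
               total = nrow(r), stringsAsFactors = FALSE)
  }))
  res <- list(records = records, off_strains = off_strains,
              per_strain_summary = per_strain,
              n_off_strain_counts = table(lengths(off_strains)))
  attr(res, "missing_from_coverage") <- unique(absent)
  res
}

#' Flag off genes responsive to RNAi in an expressing strain
#'
#' An off gene is RNAi-responsive when it has a significant
#' within-strain RNAi contrast call (up or down) in at least one strain
#' that is NOT among its silent strains, for either RNAi treatment.
#'
#' @param off the result of [call_off_genes()].
#' @param contrasts data.frame binding [wald_contrast()] results for
#'   every (strain, treatment) pair (needs gene_id, strain, treatment,
#'   call).
#' @return data.frame gene_id, rnai_responsive, qualifying -- the
#'   qualifying column is a semicolon-joined list of
#'   strain:treatment:direction triples.
#' @export
rnai_responsive_off <- function(off, contrasts) {
  genes <- names(off$off_strains)
  hits <- contrasts[contrasts$call %in% c("up", "down"), , drop = FALSE]
  out <- lapply(genes, function(g) {
    h <- hits[hits$gene_id == g &
              !(hits$strain %in% off$off_strains[[g]]), , drop = FALSE]
    data.frame(gene_id = g, rnai_responsive = nrow(h) > 0,
               qualifying = paste(
                 sprintf("%s:%s:%s", h$strain, h$treatment, h$call),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(gene_id = character(0), rnai_responsive = logical(0),
               qualifying = character(0))
  rownames(res) <- NULL
  res
}
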