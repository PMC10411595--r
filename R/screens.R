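#' Drop genes with low total counts
#'
#' Retains exactly the genes whose counts summed over all samples reach
#' the threshold (a gene summing 9 is removed at the default of 10; a
#' gene summing 10 is kept). Gene order is preserved.
#'
#' @param counts gene x sample matrix.
#' @param threshold minimum summed count (default 10).
#' @return the filtered matrix.
#' @export
filter_low_counts <- function(counts, threshold = 10) {
  stopifnot(threshold >= 0)
  counts[rowSums(counts) >= threshold, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (genes with strictly positive counts in every sample) of that
#' sample's count divided by the gene's geometric mean across samples.
#' Multiplying every sample's counts by the same constant leaves all
#' size factors unchanged; zero-containing genes never enter the
#' reference set.
#'
#' @param counts gene x sample matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; size factors are ",
         "undefined. Simulate deeper libraries or pre-filter samples.")
  }
  lc <- log(counts[ref, , drop = FALSE])
  lgeo <- rowMeans(lc)
  sf <- apply(lc, 2, function(x) exp(stats::median(x - lgeo)))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjustment with optional independent filtering
#'
#' Step-up BH adjustment with monotonicity enforcement. With
#' `independent_filtering = TRUE`, a base-mean threshold is chosen over
#' a quantile grid to maximize the number of rejections at the given
#' FDR; genes below the chosen threshold receive no adjusted p-value
#' (NA).
#'
#' @param pvals raw p-values (NA allowed; kept NA).
#' @param base_means per-gene mean of normalized counts (required when
#'   filtering).
#' @param independent_filtering logical.
#' @param fdr target FDR used to pick the filtering threshold.
#' @param quantiles candidate base-mean quantiles.
#' @return numeric vector of adjusted p-values (NA where filtered).
#' @export
bh_adjust <- function(pvals, base_means = NULL,
                      independent_filtering = FALSE, fdr = 0.1,
                      quantiles = seq(0, 0.95, by = 0.05)) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values outside [0, 1]")
  adj_sub <- function(keep) {
    out <- rep(NA_real_, length(pvals))
    idx <- which(keep & ok)
    out[idx] <- stats::p.adjust(pvals[idx], method = "BH")
    out
  }
  if (!independent_filtering) return(adj_sub(rep(TRUE, length(pvals))))
  if (is.null(base_means)) {
    stop("base_means required when independent_filtering = TRUE")
  }
  best <- NULL
  best_rej <- -1L
  for (q in quantiles) {
    thr <- stats::quantile(base_means, q, na.rm = TRUE)
    cand <- adj_sub(base_means >= thr)
    rej <- sum(cand < fdr, na.rm = TRUE)
    if (rej > best_rej) {
      best_rej <- rej
      best <- cand
    }
  }
  best
}

#' Shrink log fold changes toward zero
#'
#' Posterior mean under a zero-centered normal prior on the true log2
#' fold change: shrunk = raw * tau^2 / (tau^2 + se^2). The prior scale
#' tau is estimated by marginal maximum likelihood across genes
#' (raw ~ N(0, tau^2 + se^2)) unless supplied. |shrunk| <= |raw|, and
#' shrunk -> raw as se -> 0.
#'
#' @param raw raw log2 fold changes.
#' @param se their standard errors (log2 scale).
#' @param prior_sd optional fixed prior sd; estimated when NULL.
#' @return list: `shrunk` (NA where se is nonfinite), `prior_sd`.
#' @export
shrink_lfc <- function(raw, se, prior_sd = NULL) {
  ok <- is.finite(raw) & is.finite(se) & se > 0
  if (is.null(prior_sd)) {
    if (!any(ok)) {
      prior_sd <- 0
    } else {
      nll <- function(lt) {
        -sum(stats::dnorm(raw[ok], 0, sqrt(exp(lt)^2 + se[ok]^2), log = TRUE))
      }
      opt <- stats::optimize(nll, c(log(1e-4), log(100)))
      prior_sd <- exp(opt$minimum)
      if (nll(log(1e-4)) <= opt$objective) prior_sd <- 0
    }
  }
  shrunk <- rep(NA_real_, length(raw))
  shrunk[ok] <- raw[ok] * prior_sd^2 / (prior_sd^2 + se[ok]^2)
  list(shrunk = shrunk, prior_sd = prior_sd)
}

#' Likelihood-ratio screen of nested NB models
#'
#' Fits the full and reduced NB GLM per gene with a shared per-gene
#' dispersion (estimated once under the full design unless supplied)
#' and tests 2 * (ll_full - ll_reduced) against the chi-squared
#' distribution with df equal to the difference in model ranks. Used
#' with full = ~ strain vs reduced = ~ 1 on control samples for the
#' strain screen, and full = ~ strain * treatment vs reduced =
#' ~ strain + treatment for the interaction screen.
#'
#' @param counts gene x sample matrix.
#' @param design [sample_design()] for the same samples.
#' @param full,reduced model formulas on design columns; reduced must
#'   be nested in full.
#' @param sf size factors (computed from `counts` when NULL).
#' @param alpha per-gene dispersion vector or scalar; estimated under
#'   the full design when NULL.
#' @param fdr FDR for independent filtering.
#' @param independent_filtering passed to [bh_adjust()].
#' @return data.frame: gene_id, baseMean, stat, df, pvalue, padj.
#' @export
lrt_screen <- function(counts, design, full, reduced, sf = NULL,
                       alpha = NULL, fdr = 0.1,
                       independent_filtering = FALSE) {
  if (is.null(sf)) sf <- size_factors(counts)
  Xf <- design_matrix(design, full)
  Xr <- design_matrix(design, reduced)
  rf <- qr(Xf)$rank
  rr <- qr(Xr)$rank
  if (qr(cbind(Xf, Xr))$rank > rf) {
    stop("reduced model is not nested in the full model")
  }
  df <- rf - rr
  if (is.null(alpha)) {
    alpha <- estimate_dispersion(counts, design, sf, formula = full)$alpha
  }
  alpha <- rep_len(alpha, nrow(counts))
  n <- nrow(counts)
  stat <- numeric(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    ff <- fit_nb_glm(y, Xf, sf, alpha[i])
    fr <- fit_nb_glm(y, Xr, sf, alpha[i])
    stat[i] <- if (is.na(ff$loglik) || is.na(fr$loglik)) NA_real_ else
      max(0, 2 * (ff$loglik - fr$loglik))
  }
  pvalue <- if (df == 0) rep(1, n) else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  padj <- bh_adjust(pvalue, base_mean, independent_filtering, fdr)
  data.frame(gene_id = rownames(counts), baseMean = base_mean,
             stat = stat, df = df, pvalue = pvalue, padj = padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-strain treatment-vs-control Wald contrast
#'
#' Restricts to one strain's samples, fits the NB GLM ~ treatment, and
#' tests the requested treatment coefficient against the control with a
#' two-sided Wald test. Fold changes are shrunk with [shrink_lfc()] and
#' a gene is called up (down) when the shrunken fold change exceeds
#' +(-) the fold-change threshold and the adjusted p-value is below
#' `fdr`.
#'
#' @param counts gene x sample matrix (all samples; subsetting is
#'   internal).
#' @param design [sample_design()].
#' @param strain,treatment the contrast cell; compared against the
#'   design's control treatment within `strain`.
#' @param sf size factors for all samples (computed when NULL).
#' @param alpha per-gene dispersions (estimated on the strain subset
#'   under ~ treatment when NULL).
#' @param fdr significance threshold on the adjusted p (default 0.1).
#' @param fc_threshold linear fold-change threshold (default 1.5, i.e.
#'   |shrunken log2 FC| > log2(1.5)).
#' @param shrink logical; apply fold-change shrinkage (default TRUE;
#'   when FALSE calls use the raw fold change).
#' @param independent_filtering passed to [bh_adjust()].
#' @return data.frame: gene_id, strain, treatment, baseMean, lfc_raw,
#'   lfc_shrunk, se, pvalue, padj, call.
#' @export
wald_contrast <- function(counts, design, strain, treatment, sf = NULL,
                          alpha = NULL, fdr = 0.1, fc_threshold = 1.5,
                          shrink = TRUE, independent_filtering = FALSE) {
  ctrl <- control_treatment(design)
  for (tr in c(treatment, ctrl)) {
    if (!any(design$strain == strain & design$treatment == tr)) {
      stop(sprintf("no samples in cell (strain %s, treatment %s)",
                   strain, tr))
    }
  }
  if (is.null(sf)) sf <- size_factors(counts)
  keep <- design$strain == strain
  dsub <- design[keep, , drop = FALSE]
  dsub$treatment <- droplevels(dsub$treatment)
  csub <- counts[, keep, drop = FALSE]
  sfsub <- sf[keep]
  X <- stats::model.matrix(~treatment, data = as.data.frame(dsub))
  coef_name <- paste0("treatment", treatment)
  if (!coef_name %in% colnames(X)) {
    stop("treatment level not found in design matrix: ", treatment)
  }
  if (is.null(alpha)) {
    alpha <- estimate_dispersion(csub, dsub, sfsub,
                                 formula = ~treatment)$alpha
  }
  alpha <- rep_len(alpha, nrow(csub))
  n <- nrow(csub)
  lfc <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- fit_nb_glm(csub[i, ], X, sfsub, alpha[i])
    if (!f$degenerate && !is.na(f$loglik)) {
      lfc[i] <- f$coef_log2[coef_name]
      se[i] <- f$se_log2[which(colnames(X) == coef_name)]
    }
  }
  z <- lfc / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  sh <- shrink_lfc(lfc, se)
  eff <- if (shrink) sh$shrunk else lfc
  base_mean <- rowMeans(sweep(csub, 2, sfsub, "/"))
  padj <- bh_adjust(pvalue, base_mean, independent_filtering, fdr)
  lt <- log2(fc_threshold)
  call <- rep("ns", n)
  sig <- !is.na(padj) & padj < fdr & !is.na(eff)
  call[sig & eff > lt] <- "up"
  call[sig & eff < -lt] <- "down"
  data.frame(gene_id = rownames(csub), strain = strain,
             treatment = treatment, baseMean = base_mean,
             lfc_raw = lfc, lfc_shrunk = sh$shrunk, se = se,
             pvalue = pvalue, padj = padj, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA of variance-stabilized expression
#'
#' Applies the stabilizing transform log2(count / size factor + 1),
#' selects the genes with the highest cross-sample variance, centers
#' each gene, and computes principal components by singular value
#' decomposition.
#'
#' @param counts gene x sample matrix.
#' @param sf size factors (computed when NULL).
#' @param n_top number of most-variable genes to use (default 500).
#' @param n_pcs number of components to return.
#' @return list: `scores` (samples x n_pcs), `var_explained` (fraction
#'   per returned PC, nonincreasing), `genes` (the genes used).
#' @export
vst_pca <- function(counts, sf = NULL, n_top = 500, n_pcs = 3) {
  if (ncol(counts) < 2) stop("need at least 2 samples for PCA")
  if (n_top > nrow(counts)) {
    stop("n_top (", n_top, ") exceeds the gene count (", nrow(counts), ")")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, "/") + 1)
  v <- apply(x, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  xc <- x[top, , drop = FALSE] - rowMeans(x[top, , drop = FALSE])
  sv <- svd(t(xc))
  n_pcs <- min(n_pcs, length(sv$d))
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(scores) <- colnames(counts)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  tot <- sum(sv$d^2)
  ve <- if (tot > 0) sv$d[seq_len(n_pcs)]^2 / tot else rep(0, n_pcs)
  list(scores = scores, var_explained = ve,
       genes = rownames(counts)[top])
}
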