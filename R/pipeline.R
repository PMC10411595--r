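#' Validate pipeline inputs
#'
#' Checks agreement between the count matrix, sample sheet, annotation
#' and depth tables and reports problems without stopping. Errors are
#' conditions that would make the analysis wrong (duplicate gene ids,
#' negative counts, unmatched samples); warnings flag fragile but
#' workable designs (cells with < 3 replicates, chromosomes in the
#' annotation absent from a depth file).
#'
#' @param counts gene x sample matrix.
#' @param design [sample_design()].
#' @param annotation optional exon table.
#' @param depth optional named list of per-strain depth tables.
#' @return data.frame with columns level ("error"/"warning") and
#'   message; zero rows when everything checks out.
#' @export
validate_inputs <- function(counts, design, annotation = NULL,
                            depth = NULL) {
  issues <- list()
  note <- function(level, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dups <- unique(rownames(counts)[duplicated(rownames(counts))])
    note("error", paste("duplicated gene id(s):",
                        paste(utils::head(dups, 5), collapse = ", ")))
  }
  if (any(counts < 0)) note("error", "negative counts present")
  unmatched <- setdiff(colnames(counts), design$sample)
  if (length(unmatched) > 0) {
    note("error", paste("count columns missing from sample sheet:",
                        paste(unmatched, collapse = ", ")))
  }
  unmatched2 <- setdiff(design$sample, colnames(counts))
  if (length(unmatched2) > 0) {
    note("error", paste("sample-sheet rows missing from counts:",
                        paste(unmatched2, collapse = ", ")))
  }
  cells <- table(design$strain, design$treatment)
  low <- which(cells < 3 & cells > 0, arr.ind = TRUE)
  if (nrow(low) > 0) {
    for (r in seq_len(nrow(low))) {
      note("warning", sprintf("cell (%s, %s) has %d replicate(s)",
                              rownames(cells)[low[r, 1]],
                              colnames(cells)[low[r, 2]],
                              cells[low[r, 1], low[r, 2]]))
    }
  }
  if (!is.null(annotation) && !is.null(depth)) {
    ann_chr <- unique(annotation$chrom)
    for (s in names(depth)) {
      miss <- setdiff(ann_chr, unique(depth[[s]]$chrom))
      if (length(miss) > 0) {
        note("warning", sprintf(
          "depth for strain %s lacks chromosome(s): %s", s,
          paste(miss, collapse = ", ")))
      }
    }
  }
  if (length(issues) == 0) {
    return(data.frame(level = character(0), message = character(0)))
  }
  do.call(rbind, issues)
}

#' Run the full multi-strain RNAi analysis
#'
#' Orchestrates all stages on either a synthetic bundle (generated from
#' a [sim_config()]) or user-supplied tables: low-count filter, size
#' factors, strain LRT on control samples (~ strain vs ~ 1),
#' strain-by-treatment interaction LRT (~ strain * treatment vs
#' ~ strain + treatment), per-strain RNAi Wald contrasts with
#' fold-change shrinkage, variance-stabilized PCA, exon merging, DNA
#' coverage classification, off-gene calling with the
#' truly-off / missing-genome / uncertain trichotomy, and the overlap
#' enrichment of DE genes with poorly covered genes. Every stage's
#' table is written to `outdir` as TSV; the summary percentages in the
#' manifest are recomputed from the written tables.
#'
#' @param config list with either `synthetic` (a [sim_config()]) or
#'   paths `counts`, `sample_sheet`, `gtf`, `depth` (named vector of
#'   per-strain depth files); optional `strain_alias` named vector
#'   mapping expression-strain labels to coverage-strain labels;
#'   thresholds `low_count` (10), `fdr` (0.1), `fc_threshold` (1.5),
#'   `cov_low` (0.25); flags `independent_filtering` (TRUE for LRT
#'   screens), `shrink` (TRUE); `outdir`.
#' @param quiet suppress progress messages.
#' @return invisible list of all stage results plus the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  outdir <- config$outdir %||% stop("config$outdir is required")
  low_count <- config$low_count %||% 10
  fdr <- config$fdr %||% 0.1
  fc_threshold <- config$fc_threshold %||% 1.5
  cov_low <- config$cov_low %||% 0.25
  indep <- config$independent_filtering %||% TRUE
  shrink <- config$shrink %||% TRUE
  alias <- config$strain_alias

  truth <- NULL
  if (!is.null(config$synthetic)) {
    scfg <- config$synthetic
    say("simulating experiment (", scfg$n_genes, " genes)")
    sim <- simulate_experiment(scfg)
    counts <- sim$counts
    design <- sim$design
    truth <- sim$truth
    annotation <- simulate_annotation(scfg)
    depth <- simulate_coverage(annotation, truth, scfg)
  } else {
    counts <- read_counts_tsv(config$counts)
    if (nrow(counts) == 0 || ncol(counts) == 0) {
      stop("empty count matrix; nothing to analyze")
    }
    design <- read_sample_sheet(config$sample_sheet,
                                config$reference_strain,
                                config$control_treatment)
    annotation <- read_gtf_exons(config$gtf)
    depth <- lapply(config$depth, read_depth_bed)
  }
  if (nrow(counts) == 0) stop("empty count matrix; nothing to analyze")
  # align column order to the sample sheet
  val <- validate_inputs(counts, design, annotation, depth)
  if (any(val$level == "error")) {
    stop("input validation failed:\n  ",
         paste(val$message[val$level == "error"], collapse = "\n  "))
  }
  counts <- counts[, design$sample, drop = FALSE]

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n_in <- nrow(counts)
  filt <- filter_low_counts(counts, low_count)
  stopifnot(n_in == nrow(filt) + (n_in - nrow(filt)))
  say("filter: ", nrow(filt), " of ", n_in, " genes retained")
  sf <- size_factors(filt)

  ctrl <- control_treatment(design)
  is_ctrl <- design$treatment == ctrl
  dctrl <- design[is_ctrl, , drop = FALSE]
  cctrl <- filt[, is_ctrl, drop = FALSE]
  sfctrl <- sf[is_ctrl]

  say("strain LRT on control samples")
  strain_lrt <- lrt_screen(cctrl, dctrl, ~strain, ~1, sf = sfctrl,
                           fdr = fdr, independent_filtering = indep)
  write_tsv(strain_lrt, file.path(outdir, "strain_lrt.tsv"))

  say("strain x treatment interaction LRT")
  inter_lrt <- lrt_screen(filt, design, ~ strain * treatment,
                          ~ strain + treatment, sf = sf, fdr = fdr,
                          independent_filtering = indep)
  write_tsv(inter_lrt, file.path(outdir, "interaction_lrt.tsv"))

  say("within-strain RNAi contrasts")
  strains <- levels(design$strain)
  rnai <- setdiff(levels(design$treatment), ctrl)
  contrasts <- do.call(rbind, lapply(strains, function(s) {
    do.call(rbind, lapply(rnai, function(tr) {
      wald_contrast(filt, design, s, tr, sf = sf, fdr = fdr,
                    fc_threshold = fc_threshold, shrink = shrink)
    }))
  }))
  write_tsv(contrasts, file.path(outdir, "contrasts.tsv"))

  say("variance-stabilized PCA")
  pca <- vst_pca(filt, sf, n_top = min(500, nrow(filt)))
  write_tsv(data.frame(sample = rownames(pca$scores), pca$scores),
            file.path(outdir, "pca.tsv"))

  say("coverage screen")
  merged <- merge_exons(annotation)
  merged_used <- merged[merged$gene_id %in% rownames(filt), , drop = FALSE]
  write_tsv(merged_used, file.path(outdir, "merged_exons.bed"))
  cov_strain_of <- function(s) if (!is.null(alias) && s %in% names(alias))
    alias[[s]] else s
  raw_cov <- lapply(strains, function(s) {
    gene_coverage(merged_used, depth[[cov_strain_of(s)]])
  })
  names(raw_cov) <- strains
  cov_tbl <- classify_coverage(raw_cov, low_threshold = cov_low)
  write_tsv(cov_tbl, file.path(outdir, "coverage.tsv"))

  say("off genes")
  pw <- pairwise_de_union(filt, design, sf = sf, fdr = fdr)
  zeros <- zero_expression_strains(filt, design)
  off <- call_off_genes(pw, zeros, cov_tbl)
  write_tsv(off$records, file.path(outdir, "off_genes.tsv"))
  write_tsv(off$per_strain_summary,
            file.path(outdir, "off_gene_summary.tsv"))
  resp <- rnai_responsive_off(off, contrasts)
  write_tsv(resp, file.path(outdir, "off_rnai_responsive.tsv"))

  say("enrichment of DE genes among poorly covered genes")
  # recomputed from the written tables so report and tables agree
  slrt <- utils::read.delim(file.path(outdir, "strain_lrt.tsv"))
  covt <- utils::read.delim(file.path(outdir, "coverage.tsv"))
  de_genes <- slrt$gene_id[!is.na(slrt$padj) & slrt$padj < fdr]
  poor <- unique(covt$gene_id[covt$cov_class %in% c("missing", "low")])
  universe <- slrt$gene_id
  ov <- summarize_overlap(N = length(universe), K = length(de_genes),
                          n = length(intersect(poor, universe)),
                          k = length(intersect(de_genes, poor)))
  enr <- data.frame(
    N = length(universe), K = length(de_genes),
    n = length(intersect(poor, universe)),
    k = length(intersect(de_genes, poor)),
    p = ov$enrichment$p, log10_p = ov$enrichment$log10_p,
    expected = ov$enrichment$expected,
    fold_enrichment = ov$enrichment$fold_enrichment,
    pct_poor_that_are_de = round_pct(ov$pct_B_in_A, 1),
    pct_all_that_are_de = round_pct(ov$pct_A_in_universe, 1),
    pct_de_that_are_poor = round_pct(ov$pct_A_in_B, 1))
  write_tsv(enr, file.path(outdir, "enrichment.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("strainexpr")),
    config = config[setdiff(names(config), "synthetic")],
    synthetic = !is.null(truth),
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
    n_genes_in = n_in,
    n_genes_filtered = n_in - nrow(filt),
    n_genes_analyzed = nrow(filt),
    n_samples = ncol(filt),
    n_strain_de = sum(!is.na(strain_lrt$padj) & strain_lrt$padj < fdr),
    n_interaction = sum(!is.na(inter_lrt$padj) & inter_lrt$padj < fdr),
    n_off_genes = length(off$off_strains),
    frac_strain_de = round(mean(!is.na(strain_lrt$padj) &
                                strain_lrt$padj < fdr), 4),
    enrichment = as.list(enr))
  if (!is.null(truth)) {
    planted_off <- truth$off_genes
    called_off <- names(off$off_strains)
    manifest$off_recovery <- list(
      planted = length(planted_off), called = length(called_off),
      sensitivity = if (length(planted_off) > 0)
        mean(planted_off %in% called_off) else NA,
      precision = if (length(called_off) > 0)
        mean(called_off %in% planted_off) else NA)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  say("done; outputs in ", outdir)
  invisible(list(counts = filt, design = design, truth = truth,
                 size_factors = sf, strain_lrt = strain_lrt,
                 interaction_lrt = inter_lrt, contrasts = contrasts,
                 pca = pca, merged_exons = merged_used,
                 coverage = cov_tbl, off = off, responsive = resp,
                 enrichment = enr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
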