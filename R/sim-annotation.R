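#' Simulate a gene annotation with multi-transcript exon records
#'
#' Lays the configured genes end to end along one synthetic chromosome,
#' giving each gene 1 to 5 exons. A configurable fraction of genes get a
#' second transcript whose exon records duplicate and partially overlap
#' the first transcript's, to exercise per-gene exon merging.
#' Coordinates follow the 1-based inclusive GTF convention.
#'
#' @param config a [sim_config()] object.
#' @param overlap_frac fraction of genes given duplicated/overlapping
#'   exon records; defaults to `config$annotation_overlap_frac`.
#' @param max_exons maximum exons per gene (uniform on 1..max_exons).
#' @return data.frame with columns gene_id, transcript_id, chrom,
#'   start, end, strand; attribute `chrom_lengths` is a named vector of
#'   chromosome lengths.
#' @export
simulate_annotation <- function(config, overlap_frac = config$annotation_overlap_frac,
                                max_exons = 5) {
  validate_sim_config(config)
  set.seed(config$seed + 1000L)
  n <- config$n_genes
  chrom <- "chrS"
  if (n == 0) {
    ann <- data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    attr(ann, "chrom_lengths") <- c(chrS = 1000L)
    return(ann)
  }
  gene_ids <- sprintf("gene%05d", seq_len(n))
  rows <- vector("list", n)
  pos <- 1L
  dup <- stats::runif(n) < overlap_frac
  for (i in seq_len(n)) {
    n_ex <- sample.int(max_exons, 1)
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(50:200, n_ex - 1, replace = TRUE) else integer(0)
    start <- pos + sample(200:1000, 1)
    starts <- start + cumsum(c(0L, ex_len[-n_ex] + gaps))
    ends <- starts + ex_len - 1L
    strand <- sample(c("+", "-"), 1)
    df <- data.frame(gene_id = gene_ids[i],
                     transcript_id = paste0(gene_ids[i], ".t1"),
                     chrom = chrom, start = starts, end = ends,
                     strand = strand, stringsAsFactors = FALSE)
    if (dup[i]) {
      # second transcript: duplicate of exon 1 plus an overlapping,
      # shifted copy straddling exon 1's right edge
      shift <- max(1L, ex_len[1] %/% 2)
      df2 <- data.frame(gene_id = gene_ids[i],
                        transcript_id = paste0(gene_ids[i], ".t2"),
                        chrom = chrom,
                        start = c(starts[1], starts[1] + shift),
                        end = c(ends[1], ends[1] + shift),
                        strand = strand, stringsAsFactors = FALSE)
      df <- rbind(df, df2)
    }
    rows[[i]] <- df
    pos <- max(df$end)
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  attr(ann, "chrom_lengths") <-
    stats::setNames(as.integer(max(ann$end) + 500L), chrom)
  ann
}

#' Simulate per-strain DNA depth tracks over merged exons
#'
#' Emits one BED-style depth table per strain (chrom, start, end,
#' mean_depth; 0-based half-open intervals over the merged exons of
#' each gene). Genes whose planted coverage class is "missing" in a
#' strain get depth exactly 0 over all of their exons; "low" genes get
#' depth scaled so that their median-normalized gene-level coverage
#' falls strictly inside (0, 0.25); "adequate" genes fluctuate around
#' the strain-level depth.
#'
#' @param annotation as from [simulate_annotation()].
#' @param truth ground-truth list from [simulate_experiment()] (needs
#'   `coverage_class`).
#' @param config a [sim_config()] object.
#' @return named list (one element per strain) of depth data.frames.
#' @export
simulate_coverage <- function(annotation, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2000L)
  genes <- rownames(truth$coverage_class)
  missing_ann <- setdiff(genes, unique(annotation$gene_id))
  if (length(missing_ann) > 0) {
    stop("gene(s) in ground truth absent from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  }
  merged <- merge_exons(annotation)
  merged <- merged[merged$gene_id %in% genes, , drop = FALSE]
  depth0 <- config$coverage_depth
  sdlog <- config$coverage_noise_sd

  out <- stats::setNames(vector("list", ncol(truth$coverage_class)),
                         colnames(truth$coverage_class))
  for (s in colnames(truth$coverage_class)) {
    cls <- truth$coverage_class[, s]
    gene_depth <- stats::setNames(
      depth0 * exp(stats::rnorm(length(genes), 0, sdlog)), genes)
    gene_depth[cls == "missing"] <- 0
    # provisional strain median (low genes still at adequate depth)
    med <- stats::median(gene_depth)
    low <- names(cls)[cls == "low"]
    gene_depth[low] <- stats::runif(length(low), 0.02, 0.18) * med
    ex_depth <- gene_depth[merged$gene_id] *
      exp(stats::rnorm(nrow(merged), 0, sdlog))
    ex_depth[gene_depth[merged$gene_id] == 0] <- 0
    out[[s]] <- data.frame(chrom = merged$chrom, start = merged$start,
                           end = merged$end,
                           mean_depth = round(ex_depth, 4),
                           stringsAsFactors = FALSE)
  }
  out
}
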