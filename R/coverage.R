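#' Merge exon records into per-gene nonoverlapping intervals
#'
#' Collapses all exon records of each gene (across transcripts) into an
#' ordered set of disjoint intervals: duplicates are dropped and
#' overlapping or book-ended exons are coalesced. Input coordinates are
#' 1-based inclusive (GTF convention); output coordinates are 0-based
#' half-open (BED convention), i.e. a GTF exon [s, e] becomes
#' [s - 1, e).
#'
#' @param annotation data.frame with columns gene_id, chrom, start, end
#'   (1-based inclusive) and optionally strand / transcript_id.
#' @return data.frame with columns gene_id, chrom, start, end (0-based
#'   half-open), width; sorted by gene then start.
#' @export
merge_exons <- function(annotation) {
  req <- c("gene_id", "chrom", "start", "end")
  if (!all(req %in% names(annotation))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(annotation) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      width = integer(0)))
  }
  bad <- which(annotation$start > annotation$end)
  if (length(bad) > 0) {
    b <- bad[1]
    stop(sprintf("inverted exon interval for gene %s: [%d, %d]",
                 annotation$gene_id[b], annotation$start[b],
                 annotation$end[b]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end))
  by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(gr, annotation$gene_id))
  flat <- unlist(by_gene, use.names = TRUE)
  out <- data.frame(
    gene_id = names(flat),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(flat),
    width = GenomicRanges::width(flat),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene mean DNA coverage over merged exons
#'
#' Computes, for each gene, the length-weighted mean depth over its
#' merged exons: sum(depth * overlap_length) / sum(merged length).
#' Depth records partially overlapping a merged exon are intersected;
#' any merged base with no depth record is an error (no silent
#' zero-fill).
#'
#' @param merged merged exon table from [merge_exons()] (0-based
#'   half-open).
#' @param depth data.frame of depth records: either BED-style
#'   (chrom, start, end, mean_depth; 0-based half-open) or per-base
#'   (chrom, pos, depth; pos 0-based).
#' @return named numeric vector of per-gene raw coverage.
#' @export
gene_coverage <- function(merged, depth) {
  if (all(c("pos", "depth") %in% names(depth))) {
    depth <- data.frame(chrom = depth$chrom, start = depth$pos,
                        end = depth$pos + 1L, mean_depth = depth$depth)
  }
  req <- c("chrom", "start", "end", "mean_depth")
  if (!all(req %in% names(depth))) {
    stop("depth must have columns chrom,start,end,mean_depth or chrom,pos,depth")
  }
  if (nrow(merged) == 0) return(stats::setNames(numeric(0), character(0)))
  # to 1-based inclusive for IRanges arithmetic
  mg <- GenomicRanges::GRanges(merged$chrom,
                               IRanges::IRanges(merged$start + 1L, merged$end))
  dg <- GenomicRanges::GRanges(depth$chrom,
                               IRanges::IRanges(depth$start + 1L, depth$end))
  ov <- GenomicRanges::findOverlaps(mg, dg)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  inter_w <- GenomicRanges::width(
    GenomicRanges::pintersect(mg[qh], dg[sh]))
  covered <- tapply(inter_w, factor(qh, levels = seq_len(nrow(merged))),
                    sum, default = 0)
  gap <- which(covered < merged$width)
  if (length(gap) > 0) {
    g <- gap[1]
    stop(sprintf(
      "no depth record covers %d base(s) of merged exon %s:%d-%d (gene %s)",
      merged$width[g] - covered[g], merged$chrom[g], merged$start[g],
      merged$end[g], merged$gene_id[g]))
  }
  wsum <- tapply(inter_w * depth$mean_depth[sh],
                 factor(qh, levels = seq_len(nrow(merged))), sum, default = 0)
  num <- tapply(as.numeric(wsum), merged$gene_id, sum)
  den <- tapply(as.numeric(merged$width), merged$gene_id, sum)
  res <- num / den
  stats::setNames(as.numeric(res), names(res))
}

#' Classify per-gene coverage within strains
#'
#' Median-normalizes raw coverage within each strain (median taken over
#' all genes, zeros included) and assigns one class per (gene, strain):
#' "missing" iff raw coverage is exactly 0; "low" iff raw > 0 and the
#' normalized coverage is strictly below 0.25; "adequate" otherwise
#' (normalized coverage of exactly 0.25 is adequate).
#'
#' @param coverage data.frame with columns gene_id, strain, raw_cov, or
#'   a named list of per-strain raw coverage vectors as from
#'   [gene_coverage()].
#' @param low_threshold normalized-coverage cutoff for "low" (strict).
#' @return data.frame gene_id, strain, raw_cov, norm_cov, cov_class.
#' @export
classify_coverage <- function(coverage, low_threshold = 0.25) {
  if (is.list(coverage) && !is.data.frame(coverage)) {
    coverage <- do.call(rbind, lapply(names(coverage), function(s) {
      data.frame(gene_id = names(coverage[[s]]), strain = s,
                 raw_cov = as.numeric(coverage[[s]]),
                 stringsAsFactors = FALSE)
    }))
  }
  req <- c("gene_id", "strain", "raw_cov")
  if (!all(req %in% names(coverage))) {
    stop("coverage must have columns: ", paste(req, collapse = ", "))
  }
  if (any(coverage$raw_cov < 0)) stop("negative raw coverage")
  out <- lapply(split(coverage, coverage$strain), function(d) {
    med <- stats::median(d$raw_cov)
    if (med <= 0) {
      stop("degenerate coverage median (<= 0) in strain ", d$strain[1])
    }
    d$norm_cov <- d$raw_cov / med
    d$cov_class <- ifelse(d$raw_cov == 0, "missing",
                          ifelse(d$norm_cov < low_threshold, "low",
                                 "adequate"))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
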