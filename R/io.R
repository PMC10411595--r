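#' Read and write the pipeline's standard tables
#'
#' Counts are stored as TSV with a `gene_id` column followed by one
#' column per sample; the sample sheet has columns sample, strain,
#' treatment, replicate; depth tracks are BED-style TSVs (chrom, start,
#' end, mean_depth; 0-based half-open); annotations are standard
#' 9-column GTF with exon features carrying gene_id and transcript_id
#' attributes.
#'
#' @name strainexpr-io
NULL

#' @param counts gene x sample matrix.
#' @param path output file.
#' @rdname strainexpr-io
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname strainexpr-io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("counts TSV lacks a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @param design [sample_design()] data.frame.
#' @rdname strainexpr-io
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.table(as.data.frame(design)[, c("sample", "strain",
                                               "treatment", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @param reference_strain,control_treatment declared reference levels
#'   (defaults: first strain / a treatment named "control" if present,
#'   else the first).
#' @rdname strainexpr-io
#' @export
read_sample_sheet <- function(path, reference_strain = NULL,
                              control_treatment = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "strain", "treatment", "replicate")
  if (!all(req %in% names(df))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(reference_strain)) reference_strain <- df$strain[1]
  if (is.null(control_treatment)) {
    control_treatment <- if ("control" %in% df$treatment) "control" else
      df$treatment[1]
  }
  sample_design(df$sample, df$strain, df$treatment, df$replicate,
                reference_strain, control_treatment)
}

#' @param annotation exon table from [simulate_annotation()].
#' @rdname strainexpr-io
#' @export
write_gtf <- function(annotation, path) {
  lines <- sprintf(
    '%s\tstrainexpr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    annotation$chrom, annotation$start, annotation$end,
    annotation$strand, annotation$gene_id, annotation$transcript_id)
  writeLines(lines, path)
}

#' @rdname strainexpr-io
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(gene_id = gr$gene_id,
             transcript_id = if ("transcript_id" %in%
                                 names(S4Vectors::mcols(gr)))
               gr$transcript_id else NA_character_,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @param depth BED-style depth data.frame.
#' @rdname strainexpr-io
#' @export
write_depth_bed <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname strainexpr-io
#' @export
read_depth_bed <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "mean_depth") %in% names(df)) &&
      !all(c("chrom", "pos", "depth") %in% names(df))) {
    stop("depth file must have columns chrom,start,end,mean_depth ",
         "or chrom,pos,depth")
  }
  df
}

#' @param x any data.frame.
#' @rdname strainexpr-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
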