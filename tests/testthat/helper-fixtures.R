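# Small fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

# a tiny two-strain, two-treatment design with r replicates per cell
tiny_design <- function(strains = c("A", "B"), treatments = c("ctrl", "rnai"),
                        r = 3) {
  g <- expand.grid(replicate = seq_len(r), treatment = treatments,
                   strain = strains, stringsAsFactors = FALSE)
  sample_design(paste(g$strain, g$treatment, g$replicate, sep = "_"),
                g$strain, g$treatment, g$replicate,
                reference_strain = strains[1],
                control_treatment = treatments[1])
}

# deterministic counts matrix with dimnames
counts_matrix <- function(x, genes = NULL, samples = NULL) {
  m <- as.matrix(x)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH: for each p_i the smallest m * t / #{p <= t} over
# candidate thresholds t in {p_j : p_j >= p_i}, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  sapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / sapply(cand, function(t) sum(p <= t))))
  })
}

# brute-force hypergeometric upper tail by enumerating all n-subsets
# of a universe of size N containing a fixed K-subset
hyper_oracle <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}

# per-base union oracle for exon merging (1-based inclusive input)
merge_oracle_length <- function(starts, ends) {
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}
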