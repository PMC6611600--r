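# In-code fixture builders shared across test files.

make_samples <- function(n = 3) {
  data.frame(
    sample_id = c(sprintf("wt%d", 1:n), sprintf("het%d", 1:n)),
    group = factor(rep(c("WT", "HET"), each = n), levels = c("WT", "HET")),
    litter = rep(sprintf("litter%d", 1:n), 2),
    stringsAsFactors = FALSE)
}

# Junction table straight from a count matrix (columns = samples).
make_jt <- function(counts, starts, ends, strand = "+", chrom = "chr1",
                    annotated = TRUE) {
  keys <- junction_key(chrom, starts, ends, strand)
  rownames(counts) <- keys
  structure(list(
    junctions = data.frame(key = keys, chrom = chrom, intron_start = starts,
                           intron_end = ends, strand = strand,
                           annotated = annotated, stringsAsFactors = FALSE),
    counts = counts), class = "junction_table")
}

# A minimal annotation: one gene, three exons in one transcript, plus an
# optional second transcript that skips the middle exon.
make_cassette_annotation <- function(with_skip_transcript = FALSE) {
  rows <- data.frame(
    feature = c("gene", rep("exon", 3)),
    gene_id = "geneA",
    transcript_id = c(".", rep("geneA.t1", 3)),
    chrom = "chr1",
    start = c(1L, 1L, 201L, 401L),
    end = c(600L, 100L, 300L, 600L),
    strand = "+", stringsAsFactors = FALSE)
  if (with_skip_transcript) {
    rows <- rbind(rows, data.frame(
      feature = "exon", gene_id = "geneA",
      transcript_id = "geneA.t2", chrom = "chr1",
      start = c(1L, 401L), end = c(100L, 600L), strand = "+",
      stringsAsFactors = FALSE))
  }
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Welch t statistic for the permutation oracle (independent of the
# package's vectorised implementation).
welch_t_stat <- function(x, y) {
  (mean(y) - mean(x)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Brute-force two-sided permutation p-value over all group relabelings.
perm_p_value <- function(x, y) {
  vals <- c(x, y)
  idx <- utils::combn(length(vals), length(x))
  obs <- abs(welch_t_stat(x, y))
  ts <- apply(idx, 2, function(i) abs(welch_t_stat(vals[i], vals[-i])))
  mean(ts >= obs - 1e-12)
}

# Run the anchor-set -> usage -> test chain on a bare junction table.
usage_test <- function(jt, samples, config = analysis_config()) {
  anchors <- build_anchor_sets(jt$junctions)
  usage <- compute_usage(jt, anchors)
  test_differential_usage(usage, samples, config)
}
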