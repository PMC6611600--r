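#' Analysis configuration
#'
#' Bundles the thresholds of the junction-usage analysis. Defaults encode
#' the study's rules: a gene is expressed if its raw count mean is at least
#' `gene_count_mean_min` in both genotype groups; a junction is retained if
#' its mean unique-read count is at least `junction_mean_min` in at least
#' one group; a junction is differentially used if its two-group t-test p
#' is below `p_cutoff` AND the absolute usage difference is at least
#' `usage_delta_min`; the FDR re-analysis applies Benjamini-Hochberg at
#' `fdr_alpha`. The DE-table rule classifies genes up when padj <
#' `de_padj_max` and fold change >= `de_fc_up`, down when padj <
#' `de_padj_max` and fold change <= `de_fc_down`.
#'
#' @param gene_count_mean_min minimum group-mean raw gene count (default 100)
#' @param junction_mean_min minimum group-mean junction count (default 10)
#' @param p_cutoff per-junction p-value threshold (default 0.05)
#' @param usage_delta_min minimum absolute usage difference, a fraction in
#'   (0, 1] (default 0.20)
#' @param fdr_alpha Benjamini-Hochberg level (default 0.05)
#' @param de_padj_max,de_fc_up,de_fc_down DE-table thresholds
#'   (defaults 0.05, 1.5, 0.67)
#' @param t_test `"welch"` (default) or `"student"` two-sample t flavour
#' @return a list of class `analysis_config`
#' @export
analysis_config <- function(gene_count_mean_min = 100,
                            junction_mean_min = 10,
                            p_cutoff = 0.05,
                            usage_delta_min = 0.20,
                            fdr_alpha = 0.05,
                            de_padj_max = 0.05,
                            de_fc_up = 1.5,
                            de_fc_down = 0.67,
                            t_test = c("welch", "student")) {
  t_test <- match.arg(t_test)
  cfg <- list(gene_count_mean_min = gene_count_mean_min,
              junction_mean_min = junction_mean_min,
              p_cutoff = p_cutoff,
              usage_delta_min = usage_delta_min,
              fdr_alpha = fdr_alpha,
              de_padj_max = de_padj_max,
              de_fc_up = de_fc_up,
              de_fc_down = de_fc_down,
              t_test = t_test)
  num <- vapply(cfg[1:8], as.numeric, numeric(1))
  if (any(num <= 0)) stop("all thresholds must be positive")
  if (cfg$usage_delta_min > 1) stop("usage_delta_min must lie in (0, 1]")
  structure(cfg, class = "analysis_config")
}

group_masks <- function(samples) {
  if (!all(c("WT", "HET") %in% as.character(samples$group))) {
    stop("both groups (WT and HET) need at least one sample")
  }
  list(WT = as.character(samples$group) == "WT",
       HET = as.character(samples$group) == "HET")
}

#' Select expressed genes
#'
#' A gene is expressed when the arithmetic mean of its raw counts is at
#' least the configured threshold in the WT group AND in the HET group
#' (boundary inclusive).
#'
#' @param gene_counts numeric matrix, genes x samples, of raw counts
#' @param samples sample sheet ([read_sample_sheet()] format); column order
#'   of `gene_counts` must match `samples$sample_id`
#' @param config an [analysis_config()]
#' @return character vector of expressed gene ids
#' @export
filter_expressed_genes <- function(gene_counts, samples,
                                   config = analysis_config()) {
  stopifnot(ncol(gene_counts) == nrow(samples))
  g <- group_masks(samples)
  wt_mean <- rowMeans(gene_counts[, g$WT, drop = FALSE])
  het_mean <- rowMeans(gene_counts[, g$HET, drop = FALSE])
  rownames(gene_counts)[wt_mean >= config$gene_count_mean_min &
                        het_mean >= config$gene_count_mean_min]
}

#' Assign junctions to genes
#'
#' A junction belongs to a gene when both of its intron ends lie within the
#' gene's span. A junction spanning several (overlapping) genes is assigned
#' to all of them.
#'
#' @param junctions data.frame with `key`, `chrom`, `intron_start`,
#'   `intron_end` (the `junctions` slot of a [junction_table()])
#' @param annotation an `annotation` object
#' @return data.frame with columns `key`, `gene_id`
#' @export
assign_junctions_to_genes <- function(junctions, annotation) {
  genes <- annotation$genes
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- junctions$chrom == genes$chrom[i] &
      junctions$intron_start >= genes$start[i] &
      junctions$intron_end <= genes$end[i]
    if (!any(hit)) return(NULL)
    data.frame(key = junctions$key[hit], gene_id = genes$gene_id[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(key = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Sum junction counts per gene
#'
#' Convenience proxy for gene-level counts when only junction tables are
#' available: per gene and sample, the sum of unique-read counts over the
#' junctions assigned to the gene.
#'
#' @param jt a `junction_table`
#' @param assignment output of [assign_junctions_to_genes()]
#' @return numeric matrix, genes x samples
#' @export
gene_junction_counts <- function(jt, assignment) {
  genes <- unique(assignment$gene_id)
  m <- matrix(0, nrow = length(genes), ncol = ncol(jt$counts),
              dimnames = list(genes, colnames(jt$counts)))
  for (g in genes) {
    keys <- assignment$key[assignment$gene_id == g]
    m[g, ] <- colSums(jt$counts[keys, , drop = FALSE])
  }
  m
}

#' Filter junctions by group-mean count
#'
#' A junction is retained when its mean unique-read count is at least the
#' configured threshold in the WT group OR in the HET group (boundary
#' inclusive). The input is expected to be restricted to junctions on
#' expressed genes already.
#'
#' @param jt a `junction_table` (possibly subset)
#' @param samples sample sheet; must match the columns of `jt$counts`
#' @param config an [analysis_config()]
#' @return character vector of retained junction keys
#' @export
filter_junctions <- function(jt, samples, config = analysis_config()) {
  stopifnot(ncol(jt$counts) == nrow(samples))
  g <- group_masks(samples)
  wt_mean <- rowMeans(jt$counts[, g$WT, drop = FALSE])
  het_mean <- rowMeans(jt$counts[, g$HET, drop = FALSE])
  rownames(jt$counts)[wt_mean >= config$junction_mean_min |
                      het_mean >= config$junction_mean_min]
}

#' Subset a junction table by key
#'
#' @param jt a `junction_table`
#' @param keys junction keys to keep
#' @return a `junction_table` restricted to `keys`
#' @export
subset_junctions <- function(jt, keys) {
  keep <- jt$junctions$key %in% keys
  structure(list(junctions = jt$junctions[keep, , drop = FALSE],
                 counts = jt$counts[jt$junctions$key[keep], , drop = FALSE]),
            class = "junction_table")
}

#' Build anchor sets of junctions
#'
#' An anchor set is the competition group over which junction usage is
#' defined: all junctions sharing a common start coordinate
#' (`shared_start`) or, conversely, a common end coordinate (`shared_end`).
#' Every junction belongs to exactly one shared-start set and exactly one
#' shared-end set; singleton sets are produced but flagged untestable
#' (their usage is identically 1).
#'
#' @param junctions data.frame with `key`, `chrom`, `intron_start`,
#'   `intron_end`, `strand`
#' @return data.frame with one row per (junction, side): columns `key`,
#'   `side` (`shared_start`/`shared_end`), `anchor_id`, `set_size`,
#'   `testable` (set_size > 1)
#' @export
build_anchor_sets <- function(junctions) {
  if (nrow(junctions) == 0L) {
    return(data.frame(key = character(0), side = character(0),
                      anchor_id = character(0), set_size = integer(0),
                      testable = logical(0), stringsAsFactors = FALSE))
  }
  stopifnot(!anyDuplicated(junctions$key))
  one_side <- function(side, coord) {
    anchor <- sprintf("%s:%s@%d:%s", junctions$chrom, side, coord,
                      junctions$strand)
    size <- as.integer(table(anchor)[anchor])
    data.frame(key = junctions$key, side = side, anchor_id = anchor,
               set_size = size, testable = size > 1L,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side("shared_start", junctions$intron_start),
               one_side("shared_end", junctions$intron_end))
  rownames(out) <- NULL
  out
}

#' Compute per-sample junction usage
#'
#' Within one anchor set and sample, a junction's usage is its unique-read
#' count divided by the summed counts of all junctions in the set. When the
#' set total is zero for a sample the usage is undefined (NA) for every
#' member in that sample, never fabricated as 0/0.
#'
#' @param jt a `junction_table` restricted to the junctions under test
#' @param anchors output of [build_anchor_sets()] on `jt$junctions`
#' @return numeric matrix, rows indexed by `paste(key, side)` aligned with
#'   `anchors`, columns = samples; attribute `anchors` carries the anchor
#'   data.frame
#' @export
compute_usage <- function(jt, anchors) {
  counts <- jt$counts[anchors$key, , drop = FALSE]
  totals <- rowsum(counts, anchors$anchor_id, reorder = FALSE)
  denom <- totals[anchors$anchor_id, , drop = FALSE]
  usage <- counts / denom
  usage[denom == 0] <- NA_real_
  rownames(usage) <- paste(anchors$key, anchors$side)
  attr(usage, "anchors") <- anchors
  usage
}

# Vectorised two-sample t (Welch or Student). Returns p-values with the
# deterministic degenerate-case policy: zero variance in both groups with
# unequal means -> p 0; with equal means -> p 1; both flagged.
two_group_t <- function(x_mat, wt, het, flavor = "welch") {
  nx <- rowSums(!is.na(x_mat[, wt, drop = FALSE]))
  ny <- rowSums(!is.na(x_mat[, het, drop = FALSE]))
  mx <- rowMeans(x_mat[, wt, drop = FALSE], na.rm = TRUE)
  my <- rowMeans(x_mat[, het, drop = FALSE], na.rm = TRUE)
  vx <- apply(x_mat[, wt, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  vy <- apply(x_mat[, het, drop = FALSE], 1L, stats::var, na.rm = TRUE)
  if (flavor == "welch") {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  }
  tstat <- (my - mx) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.na(vx) & !is.na(vy) & vx == 0 & vy == 0
  p[degenerate & mx != my] <- 0
  p[degenerate & mx == my] <- 1
  list(p = p, delta = my - mx, mean_wt = mx, mean_het = my,
       n_wt = nx, n_het = ny, degenerate = degenerate)
}

#' Test differential junction usage between groups
#'
#' For each (junction, anchor side) pair a two-sided two-sample t-test
#' (Welch by default) compares per-sample usages between WT and HET.
#' A pair is testable only when both groups have at least two samples with
#' defined usage; otherwise it is reported untested with a reason code.
#' Significance applies the dual rule: p below `p_cutoff` AND an absolute
#' usage difference of at least `usage_delta_min`. Benjamini-Hochberg
#' adjusted p-values over all tested pairs are included for the FDR
#' re-analysis (`significant_fdr`: adjusted p <= `fdr_alpha`).
#'
#' @param usage usage matrix from [compute_usage()]
#' @param samples sample sheet matching the columns of `usage`
#' @param config an [analysis_config()]
#' @return data.frame with one row per (junction, side): usage group means,
#'   `delta` (HET - WT), `p_value`, `p_adjusted`, `significant`,
#'   `significant_fdr`, `tested`, `reason`, `degenerate`
#' @export
test_differential_usage <- function(usage, samples,
                                    config = analysis_config()) {
  anchors <- attr(usage, "anchors")
  g <- group_masks(samples)
  tt <- two_group_t(usage, g$WT, g$HET, config$t_test)
  res <- data.frame(key = anchors$key, side = anchors$side,
                    anchor_id = anchors$anchor_id,
                    set_size = anchors$set_size,
                    mean_wt = tt$mean_wt, mean_het = tt$mean_het,
                    delta = tt$delta,
                    p_value = tt$p, stringsAsFactors = FALSE)
  res$degenerate <- tt$degenerate
  res$tested <- anchors$testable & tt$n_wt >= 2L & tt$n_het >= 2L
  res$reason <- ifelse(res$tested, "",
                       ifelse(!anchors$testable, "singleton_set",
                              "fewer_than_2_defined_per_group"))
  res$p_value[!res$tested] <- NA_real_
  res$p_adjusted <- NA_real_
  res$p_adjusted[res$tested] <- apply_fdr(res$p_value[res$tested],
                                          config$fdr_alpha)$p_adjusted
  res$significant <- res$tested & !is.na(res$p_value) &
    res$p_value < config$p_cutoff & abs(res$delta) >= config$usage_delta_min
  res$significant_fdr <- res$tested & !is.na(res$p_adjusted) &
    res$p_adjusted <= config$fdr_alpha &
    abs(res$delta) >= config$usage_delta_min
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values; a hypothesis is significant when its adjusted
#' p-value is at most `alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @param alpha FDR level (default 0.05)
#' @return list with `p_adjusted` and logical `significant`
#' @export
apply_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}

#' Full differential-usage pipeline
#'
#' Wires the analysis end to end: junction-to-gene assignment, expressed
#' gene selection (gene counts approximated by summed junction counts when
#' `gene_counts` is not supplied), junction count filter, anchor sets,
#' usage, and the two-group test.
#'
#' @param jt a `junction_table`
#' @param annotation an `annotation` object
#' @param samples sample sheet matching the columns of `jt$counts`
#' @param config an [analysis_config()]
#' @param gene_counts optional genes x samples matrix of raw gene counts;
#'   when NULL, junction-sum proxies are used
#' @return the [test_differential_usage()] data.frame, with attributes
#'   `expressed_genes` and `kept_junctions`
#' @export
splice_usage_pipeline <- function(jt, annotation, samples,
                                  config = analysis_config(),
                                  gene_counts = NULL) {
  stopifnot(identical(colnames(jt$counts), samples$sample_id))
  assignment <- assign_junctions_to_genes(jt$junctions, annotation)
  if (is.null(gene_counts)) {
    gene_counts <- gene_junction_counts(jt, assignment)
  }
  expressed <- filter_expressed_genes(gene_counts, samples, config)
  keys_on_expressed <- unique(assignment$key[assignment$gene_id %in%
                                             expressed])
  jt_expr <- subset_junctions(jt, keys_on_expressed)
  kept <- filter_junctions(jt_expr, samples, config)
  jt_kept <- subset_junctions(jt_expr, kept)
  anchors <- build_anchor_sets(jt_kept$junctions)
  usage <- compute_usage(jt_kept, anchors)
  res <- test_differential_usage(usage, samples, config)
  attr(res, "expressed_genes") <- expressed
  attr(res, "kept_junctions") <- kept
  res
}

#' Percent spliced-in of a cassette exon
#'
#' For a cassette exon with two inclusion junctions (upstream exon to
#' cassette, cassette to downstream exon) and one skipping junction
#' (upstream to downstream exon), the inclusion level per sample is
#' Psi = (I/2) / ((I/2) + S), where I is the summed read count of the two
#' inclusion junctions and S the skipping junction's count. The halving of
#' I compensates for the inclusion isoform contributing two junctions where
#' the skipping isoform contributes one. Psi is 1 when S = 0 and I > 0, and
#' undefined when I = S = 0 (such samples are excluded from the group
#' summary with a warning).
#'
#' @param jt a `junction_table`
#' @param event list with junction keys `inclusion1`, `inclusion2`, `skip`
#' @param samples sample sheet matching the columns of `jt$counts`
#' @return object of class `psi_result`: list with `per_sample` data.frame
#'   (sample_id, group, I, S, psi) and `by_group` data.frame (group, n,
#'   mean_psi, sd_psi)
#' @export
compute_psi <- function(jt, event, samples) {
  need <- c(event$inclusion1, event$inclusion2, event$skip)
  missing <- setdiff(need, rownames(jt$counts))
  if (length(missing) > 0L) {
    stop("event junction(s) absent from the junction table: ",
         paste(missing, collapse = ", "))
  }
  I <- jt$counts[event$inclusion1, ] + jt$counts[event$inclusion2, ]
  S <- jt$counts[event$skip, ]
  psi <- ifelse(I + S > 0, (I / 2) / ((I / 2) + S), NA_real_)
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           I = as.numeric(I[samples$sample_id]),
                           S = as.numeric(S[samples$sample_id]),
                           psi = as.numeric(psi[samples$sample_id]),
                           stringsAsFactors = FALSE)
  if (anyNA(per_sample$psi)) {
    warning("Psi undefined (I = S = 0) for sample(s): ",
            paste(per_sample$sample_id[is.na(per_sample$psi)],
                  collapse = ", "), "; excluded from group summary")
  }
  by_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                    function(d) {
    ok <- !is.na(d$psi)
    data.frame(group = d$group[1L], n = sum(ok),
               mean_psi = if (any(ok)) mean(d$psi[ok]) else NA_real_,
               sd_psi = if (sum(ok) > 1L) stats::sd(d$psi[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  structure(list(per_sample = per_sample, by_group = by_group),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat("Cassette-exon inclusion (Psi = (I/2)/((I/2)+S))\n")
  print(x$per_sample, row.names = FALSE)
  cat("\nGroup summary:\n")
  print(x$by_group, row.names = FALSE)
  invisible(x)
}

#' Per-sample unannotated-junction percentage
#'
#' For each sample, among the junctions detected in that sample (unique
#' count > 0) on expressed genes, the percentage absent from the
#' annotation's junction set, followed by a two-group t-test comparing WT
#' and HET. A sample with zero detected junctions has an undefined
#' percentage and is excluded with a warning. Internally fractions are
#' used; percentages appear only in the returned table.
#'
#' @param jt a `junction_table` already restricted to expressed genes
#' @param annotation an `annotation` object supplying the annotated set
#' @param samples sample sheet matching the columns of `jt$counts`
#' @param config an [analysis_config()] (for the t-test flavour)
#' @return list with `per_sample` data.frame (sample_id, group,
#'   n_junctions, n_unannotated, percent_unannotated), `group_means`
#'   (percent scale), `p_value`, and `degenerate` flag
#' @export
unannotated_junction_percentage <- function(jt, annotation, samples,
                                            config = analysis_config()) {
  annotated_keys <- unique(annotation$junctions$key)
  detected <- jt$counts > 0
  n_j <- colSums(detected)
  unann <- !(rownames(jt$counts) %in% annotated_keys)
  n_u <- colSums(detected & unann)
  frac <- ifelse(n_j > 0, n_u / n_j, NA_real_)
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           n_junctions = as.integer(n_j[samples$sample_id]),
                           n_unannotated = as.integer(n_u[samples$sample_id]),
                           percent_unannotated =
                             100 * as.numeric(frac[samples$sample_id]),
                           stringsAsFactors = FALSE)
  if (anyNA(per_sample$percent_unannotated)) {
    warning("no detected junctions for sample(s): ",
            paste(per_sample$sample_id[is.na(per_sample$percent_unannotated)],
                  collapse = ", "), "; excluded from the comparison")
  }
  fr <- matrix(per_sample$percent_unannotated / 100, nrow = 1,
               dimnames = list("frac", per_sample$sample_id))
  g <- group_masks(samples)
  tt <- two_group_t(fr, g$WT, g$HET, config$t_test)
  gm <- c(WT = 100 * tt$mean_wt, HET = 100 * tt$mean_het)
  list(per_sample = per_sample, group_means = gm,
       p_value = unname(tt$p), degenerate = unname(tt$degenerate))
}

#' Classify a differential-expression table
#'
#' Applies the threshold rule to a (gene, fold_change, p_adjusted) table:
#' up-regulated when padj < `de_padj_max` and fold change >= `de_fc_up`;
#' down-regulated when padj < `de_padj_max` and fold change <= `de_fc_down`;
#' everything else unclassified.
#'
#' @param de data.frame with columns `gene`, `fold_change`, `p_adjusted`
#' @param config an [analysis_config()]
#' @return list with character vectors `up` and `down`, and the input with
#'   a `class` column (`up`/`down`/`unclassified`)
#' @export
filter_de_table <- function(de, config = analysis_config()) {
  stopifnot(all(c("gene", "fold_change", "p_adjusted") %in% names(de)))
  if (any(de$fold_change <= 0)) {
    stop("fold changes must be positive")
  }
  sig <- de$p_adjusted < config$de_padj_max
  cls <- ifelse(sig & de$fold_change >= config$de_fc_up, "up",
                ifelse(sig & de$fold_change <= config$de_fc_down, "down",
                       "unclassified"))
  de$class <- cls
  list(up = de$gene[cls == "up"], down = de$gene[cls == "down"], table = de)
}
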