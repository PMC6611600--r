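test_that("expressed-gene filter requires the mean in both groups, boundary inclusive", {
  samples <- make_samples(3)
  gc <- rbind(
    gA = c(150, 150, 150, 90, 90, 90),    # HET mean below threshold
    gB = c(100, 100, 100, 100, 100, 100), # exactly at the boundary
    gC = c(0, 0, 0, 0, 0, 0),
    gD = c(500, 400, 300, 120, 110, 130))
  colnames(gc) <- samples$sample_id
  kept <- filter_expressed_genes(gc, samples)
  expect_setequal(kept, c("gB", "gD"))
  expect_equal(filter_expressed_genes(gc * 0, samples), character(0))
  expect_error(filter_expressed_genes(gc[, 1:3], samples[1:3, ]),
               "both groups")
})

test_that("junction filter requires the mean in at least one group, boundary inclusive", {
  samples <- make_samples(3)
  counts <- rbind(c(12, 12, 12, 3, 3, 3),      # kept via WT
                  c(9.9, 9.9, 9.9, 9.9, 9.9, 9.9),  # dropped
                  c(4, 4, 4, 10, 10, 10))      # kept via HET boundary
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 501L, 901L),
                ends = c(200L, 600L, 1000L))
  kept <- filter_junctions(jt, samples)
  expect_setequal(kept, jt$junctions$key[c(1, 3)])
})

test_that("anchor sets partition junctions by shared start and shared end", {
  expect_equal(nrow(build_anchor_sets(empty_jt <- data.frame(
    key = character(0), chrom = character(0), intron_start = integer(0),
    intron_end = integer(0), strand = character(0)))), 0L)

  # cassette exon: up-inclusion 101-200, skip 101-400, down-inclusion 301-400
  j <- data.frame(key = c("A", "SKIP", "B"), chrom = "chr1",
                  intron_start = c(101L, 101L, 301L),
                  intron_end = c(200L, 400L, 400L), strand = "+",
                  stringsAsFactors = FALSE)
  a <- build_anchor_sets(j)
  # every junction appears once per side
  expect_equal(sum(a$side == "shared_start"), 3L)
  expect_equal(sum(a$side == "shared_end"), 3L)
  ss <- a[a$side == "shared_start", ]
  expect_equal(ss$anchor_id[ss$key == "SKIP"], ss$anchor_id[ss$key == "A"])
  se <- a[a$side == "shared_end", ]
  expect_equal(se$anchor_id[se$key == "SKIP"], se$anchor_id[se$key == "B"])
  # the inclusion junctions do not share anchors with each other
  expect_false(ss$anchor_id[ss$key == "A"] == ss$anchor_id[ss$key == "B"])
  expect_equal(a$testable, a$set_size > 1L)
  # singleton sets exist and are flagged untestable
  expect_false(se$testable[se$key == "A"])
})

test_that("usage is count over anchor-set total, NA on zero denominators, and sums to 1", {
  samples <- make_samples(2)
  counts <- rbind(c(80, 60, 0, 10), c(20, 40, 0, 30))
  counts <- cbind(counts, counts)[, 1:4]
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 101L), ends = c(200L, 400L))
  anchors <- build_anchor_sets(jt$junctions)
  u <- compute_usage(jt, anchors)
  ss <- anchors$side == "shared_start"
  expect_equal(unname(u[ss, 1]), c(0.8, 0.2))
  expect_true(all(is.na(u[ss, 3])))          # zero denominator
  # shared-end sets are singletons: usage 1 wherever defined
  expect_true(all(u[!ss, ][!is.na(u[!ss, ])] == 1))
  sums <- rowsum(ifelse(is.na(u), 0, u), anchors$anchor_id)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
})

test_that("usage sums to 1 within every anchor set of simulated data", {
  sim <- simulate_junction_counts(sim_config(n_genes = 40, seed = 5))
  anchors <- build_anchor_sets(sim$jt$junctions)
  u <- compute_usage(sim$jt, anchors)
  sums <- rowsum(ifelse(is.na(u), 0, u), anchors$anchor_id)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
})

test_that("differential usage applies the dual p-value and delta rule", {
  samples <- make_samples(3)
  # counts engineered so junction usages match the target fractions
  mk <- function(u_wt, u_het, depth = 100) {
    rbind(round(depth * c(u_wt, u_het)), round(depth * (1 - c(u_wt, u_het))))
  }
  strong <- mk(c(0.98, 1.00, 0.96), c(0.52, 0.48, 0.50))
  colnames(strong) <- samples$sample_id
  jt <- make_jt(strong, starts = c(101L, 101L), ends = c(200L, 400L))
  res <- usage_test(jt, samples)
  row <- res[res$side == "shared_start" & res$key == jt$junctions$key[1], ]
  expect_true(abs(row$delta - (-0.48)) < 0.021)
  expect_lt(row$p_value, 0.05)
  expect_true(row$significant)

  # small delta is never significant, whatever the p-value
  small <- mk(c(0.50, 0.52, 0.48), c(0.49, 0.51, 0.50))
  colnames(small) <- samples$sample_id
  jt2 <- make_jt(small, starts = c(101L, 101L), ends = c(200L, 400L))
  res2 <- usage_test(jt2, samples)
  expect_true(all(abs(res2$delta) < 0.20))
  expect_false(any(res2$significant))

  # identical groups: delta 0, not significant
  same <- mk(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  colnames(same) <- samples$sample_id
  jt3 <- make_jt(same, starts = c(101L, 101L), ends = c(200L, 400L))
  res3 <- usage_test(jt3, samples)
  expect_true(all(res3$delta == 0))
  expect_false(any(res3$significant))
  # zero variance in both groups with equal means is flagged degenerate
  expect_true(all(res3$degenerate[res3$tested]))
})

test_that("zero-variance groups with different means give p = 0, flagged", {
  samples <- make_samples(3)
  counts <- rbind(c(90, 90, 90, 30, 30, 30), c(10, 10, 10, 70, 70, 70))
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 101L), ends = c(200L, 400L))
  res <- usage_test(jt, samples)
  tested <- res[res$tested, ]
  expect_true(all(tested$p_value == 0))
  expect_true(all(tested$degenerate))
  expect_true(all(tested$significant))
})

test_that("junctions with under two defined usages per group are untested", {
  samples <- make_samples(3)
  counts <- rbind(c(50, 0, 0, 40, 35, 30), c(50, 0, 0, 60, 65, 70))
  colnames(counts) <- samples$sample_id  # WT defined in only one sample
  jt <- make_jt(counts, starts = c(101L, 101L), ends = c(200L, 400L))
  res <- usage_test(jt, samples)
  ss <- res[res$side == "shared_start", ]
  expect_false(any(ss$tested))
  expect_true(all(ss$reason == "fewer_than_2_defined_per_group"))
  expect_false(any(ss$significant))
})

test_that("the vectorised t-test matches stats::t.test and a permutation oracle", {
  samples <- make_samples(3)
  set.seed(42)
  diffs_t <- c(); diffs_p <- c()
  for (i in 1:30) {
    u_wt <- pmin(pmax(rnorm(3, 0.6, 0.08), 0.01), 0.99)
    u_het <- pmin(pmax(rnorm(3, 0.6 - (i %% 3) * 0.15, 0.08), 0.01), 0.99)
    depth <- 1000
    counts <- rbind(round(depth * c(u_wt, u_het)),
                    round(depth * (1 - c(u_wt, u_het))))
    colnames(counts) <- samples$sample_id
    jt <- make_jt(counts, starts = c(101L, 101L), ends = c(200L, 400L))
    res <- usage_test(jt, samples)
    row <- res[res$side == "shared_start", ][1, ]
    u <- counts[1, ] / colSums(counts)
    ref <- stats::t.test(u[4:6], u[1:3])$p.value
    diffs_t <- c(diffs_t, abs(row$p_value - ref))
    diffs_p <- c(diffs_p, abs(row$p_value - perm_p_value(u[1:3], u[4:6])))
  }
  expect_lt(max(diffs_t), 1e-10)
  # permutation p has granularity 1/20 on 3+3; agreement within MC error
  expect_lt(mean(diffs_p), 0.15)
  expect_lt(max(diffs_p), 0.40)
})

test_that("Benjamini-Hochberg adjustment matches closed forms and is monotone", {
  expect_equal(apply_fdr(0.01)$p_adjusted, 0.01)
  expect_equal(apply_fdr(c(0.01, 0.02, 0.03))$p_adjusted,
               c(0.03, 0.03, 0.03))
  expect_false(any(apply_fdr(rep(1, 5))$significant))
  expect_error(apply_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(200)
  adj <- apply_fdr(p)$p_adjusted
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone in the p ranks
  expect_true(all(adj >= p))
})

test_that("Psi follows the (I/2)/((I/2)+S) formula with its boundary cases", {
  samples <- make_samples(2)
  counts <- rbind(c(50, 50, 50, 50), c(50, 50, 50, 50), c(0, 0, 50, 50))
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 301L, 101L),
                ends = c(200L, 400L, 400L))
  event <- list(inclusion1 = jt$junctions$key[1],
                inclusion2 = jt$junctions$key[2],
                skip = jt$junctions$key[3])
  res <- compute_psi(jt, event, samples)
  # I = 100, S = 0 -> Psi = 1; I = 100, S = 50 -> Psi = 0.5
  expect_equal(res$per_sample$psi, c(1, 1, 0.5, 0.5))
  expect_equal(res$by_group$mean_psi,
               c(1, 0.5)[match(res$by_group$group, c("WT", "HET"))])
  expect_error(compute_psi(jt, list(inclusion1 = "nope", inclusion2 = "x",
                                    skip = "y"), samples),
               "absent from the junction table")
})

test_that("Psi is bounded and monotone in I and S; undefined only at I = S = 0", {
  psi <- function(I, S) (I / 2) / ((I / 2) + S)
  I <- seq(0, 400, by = 40); S <- seq(0, 200, by = 20)
  grid <- expand.grid(I = I, S = S)
  vals <- with(grid, psi(I, S))
  def <- grid$I + grid$S > 0
  expect_true(all(vals[def] >= 0 & vals[def] <= 1))
  # monotone increasing in I at fixed S > 0
  for (s in S[S > 0]) expect_true(all(diff(psi(I, s)) > 0))
  # monotone decreasing in S at fixed I > 0
  for (i in I[I > 0]) expect_true(all(diff(psi(i, S)) < 0))
  # package path agrees and warns on the undefined sample
  samples <- make_samples(2)
  counts <- rbind(c(0, 10, 0, 0), c(0, 10, 0, 0), c(0, 5, 0, 0))
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 301L, 101L),
                ends = c(200L, 400L, 400L))
  event <- list(inclusion1 = jt$junctions$key[1],
                inclusion2 = jt$junctions$key[2],
                skip = jt$junctions$key[3])
  expect_warning(res <- compute_psi(jt, event, samples), "undefined")
  expect_equal(res$by_group$n[res$by_group$group == "WT"], 1L)
})

test_that("unannotated-junction percentages count per-sample detections", {
  samples <- make_samples(2)
  ann <- read_annotation(make_cassette_annotation(FALSE))
  # junctions: 2 annotated (t1 introns), 1 unannotated (the skip)
  counts <- rbind(c(10, 10, 10, 10), c(10, 10, 10, 10), c(0, 5, 5, 5))
  colnames(counts) <- samples$sample_id
  jt <- make_jt(counts, starts = c(101L, 301L, 101L),
                ends = c(200L, 400L, 400L))
  res <- unannotated_junction_percentage(jt, ann, samples)
  expect_equal(res$per_sample$percent_unannotated,
               c(0, 100 / 3, 100 / 3, 100 / 3))
  # all-annotated table: 0% everywhere, degenerate comparison flagged
  jt0 <- make_jt(counts[1:2, ], starts = c(101L, 301L),
                 ends = c(200L, 400L))
  res0 <- unannotated_junction_percentage(jt0, ann, samples)
  expect_true(all(res0$per_sample$percent_unannotated == 0))
  expect_true(res0$degenerate)
})

test_that("unannotated percentages are null-stable between groups on synthetic data", {
  # no planted difference: the two groups should be indistinguishable
  ps <- vapply(1:20, function(s) {
    sim <- simulate_junction_counts(sim_config(n_genes = 80,
                                               planted_skip_fraction = 0,
                                               seed = 1000 + s))
    res <- unannotated_junction_percentage(sim$jt, sim$annotation,
                                           sim$samples)
    res$p_value
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 18L)
})

test_that("DE tables are classified by the padj and fold-change thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   fold_change = c(1.6, 1.2, 0.5, 1.5, 0.67),
                   p_adjusted = c(0.01, 0.001, 0.04, 0.06, 0.049))
  res <- filter_de_table(de)
  expect_equal(res$up, "a")                 # FC 1.5 boundary needs padj < 0.05
  expect_setequal(res$down, c("c", "e"))    # 0.67 boundary is inclusive
  expect_equal(res$table$class[res$table$gene == "b"], "unclassified")
  expect_equal(res$table$class[res$table$gene == "d"], "unclassified")
  expect_error(filter_de_table(transform(de, fold_change = -1)), "positive")
})

test_that("the full pipeline flags the planted cassette junctions as top hits", {
  sim <- simulate_junction_counts(sim_config(seed = 7))
  res <- splice_usage_pipeline(sim$jt, sim$annotation, sim$samples)
  tt <- res[res$tested, ]
  planted <- unlist(sim$truth[c("inclusion1", "inclusion2", "skip")])
  expect_true(tt$key[which.max(abs(tt$delta))] %in% planted)
  expect_true(all(tt$key[tt$significant] %in% planted))
  # the skipping junction is detected on both its anchor sides
  expect_setequal(tt$side[tt$key == sim$truth$skip],
                  c("shared_start", "shared_end"))
})
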