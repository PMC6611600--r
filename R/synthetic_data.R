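# Deterministic substream seeding: one root seed, substreams derived by a
# labeled hash kept below 2^31 so set.seed() always receives a valid value.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 97)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulation configuration for junction counts
#'
#' Defaults encode the study design being emulated: 3 WT vs 3 HET pooled
#' embryo samples, litter-matched pairs (each litter contributes one WT and
#' one HET pool), ~300 expected unique reads per expressed junction (a
#' desk-scale stand-in for full sequencing depth), negative-binomial counts
#' with dispersion 0.1, a log-scale litter effect SD of 0.3 large enough
#' that samples cluster by litter rather than genotype, one planted
#' heterozygous cassette-exon deletion with skip fraction 0.5 (half of
#' transcripts skip the exon in HET, none in WT), and a 2% rate of
#' low-count unannotated noise junctions.
#'
#' @param n_genes number of genes (default 200)
#' @param n_per_group samples per genotype group (default 3; minimum 2)
#' @param litter_pairing pair one WT and one HET sample per litter
#'   (default TRUE)
#' @param depth_scale expected unique reads per expressed junction
#'   (default 300)
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   variance = mu + alpha * mu^2 (default 0.1)
#' @param litter_sd log-scale SD of the shared litter multiplier
#'   (default 0.3)
#' @param planted_skip_fraction fraction f of HET transcripts skipping the
#'   planted cassette exon (default 0.5; 0 disables the planted event)
#' @param unannotated_noise_rate per-gene, per-sample probability of a
#'   spurious unannotated junction (default 0.02)
#' @param seed root seed; all substreams derive from it (default 1)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_genes = 200, n_per_group = 3, litter_pairing = TRUE,
                       depth_scale = 300, nb_dispersion = 0.1,
                       litter_sd = 0.3, planted_skip_fraction = 0.5,
                       unannotated_noise_rate = 0.02, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (planted_skip_fraction < 0 || planted_skip_fraction > 1) {
    stop("planted_skip_fraction must lie in [0, 1]")
  }
  if (any(c(n_genes, depth_scale, nb_dispersion, litter_sd) <= 0)) {
    stop("n_genes, depth_scale, nb_dispersion and litter_sd must be positive")
  }
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 litter_pairing = litter_pairing, depth_scale = depth_scale,
                 nb_dispersion = nb_dispersion, litter_sd = litter_sd,
                 planted_skip_fraction = planted_skip_fraction,
                 unannotated_noise_rate = unannotated_noise_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gene layout: gene g occupies [(g-1)*10000 + 1, (g-1)*10000 + 999] on
# chr1, with three exons. Transcript t1 uses the full middle exon
# (introns J1, J2). Every non-planted gene also has transcript t2 with an
# alternative 3' splice site of intron 1 (junction J1alt, annotated): a
# null alternative-splicing event whose usage fraction is shared by both
# groups, so anchor sets are testable under the null. The planted gene's
# middle exon is the cassette; its skipping junction joins exon 1 to
# exon 3 and is deliberately NOT annotated (an engineered deletion creates
# a junction absent from the reference annotation).
sim_gene_layout <- function(n_genes) {
  off <- (seq_len(n_genes) - 1L) * 10000L
  list(gene_id = sprintf("gene%03d", seq_len(n_genes)),
       start = off + 1L, end = off + 999L,
       exon_starts = cbind(off + 1L, off + 401L, off + 801L),
       exon_ends = cbind(off + 200L, off + 600L, off + 999L),
       alt_exon_start = off + 481L,
       j1_start = off + 201L, j1_end = off + 400L,
       j1alt_start = off + 201L, j1alt_end = off + 480L,
       j2_start = off + 601L, j2_end = off + 800L,
       skip_start = off + 201L, skip_end = off + 800L)
}

sim_annotation <- function(layout, planted) {
  n <- length(layout$gene_id)
  alt <- setdiff(seq_len(n), planted)
  genes <- data.frame(gene_id = layout$gene_id, chrom = "chr1",
                      start = layout$start, end = layout$end, strand = "+",
                      stringsAsFactors = FALSE)
  exons_t1 <- data.frame(
    feature = "exon",
    gene_id = rep(layout$gene_id, each = 3L),
    transcript_id = paste0(rep(layout$gene_id, each = 3L), ".t1"),
    chrom = "chr1",
    start = as.integer(t(layout$exon_starts)),
    end = as.integer(t(layout$exon_ends)),
    strand = "+", stringsAsFactors = FALSE)
  exons_t2 <- data.frame(
    feature = "exon",
    gene_id = rep(layout$gene_id[alt], each = 3L),
    transcript_id = paste0(rep(layout$gene_id[alt], each = 3L), ".t2"),
    chrom = "chr1",
    start = as.integer(t(cbind(layout$exon_starts[alt, 1L],
                               layout$alt_exon_start[alt],
                               layout$exon_starts[alt, 3L]))),
    end = as.integer(t(layout$exon_ends[alt, , drop = FALSE])),
    strand = "+", stringsAsFactors = FALSE)
  exons <- rbind(exons_t1, exons_t2)
  jn <- rbind(
    data.frame(gene_id = rep(layout$gene_id, each = 2L),
               chrom = "chr1",
               intron_start = as.integer(rbind(layout$j1_start,
                                               layout$j2_start)),
               intron_end = as.integer(rbind(layout$j1_end, layout$j2_end)),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = layout$gene_id[alt], chrom = "chr1",
               intron_start = layout$j1alt_start[alt],
               intron_end = layout$j1alt_end[alt],
               strand = "+", stringsAsFactors = FALSE))
  jn$key <- junction_key(jn$chrom, jn$intron_start, jn$intron_end, jn$strand)
  structure(list(genes = genes, exons = exons, junctions = jn),
            class = "annotation")
}

#' Simulate a junction count table with a planted cassette deletion
#'
#' Generates the full input bundle of the splicing analysis: a junction
#' table over `n_genes` three-exon genes, a matching annotation, a sample
#' sheet, and a truth record. Per gene, a log-normal baseline expression is
#' shared by all samples; each litter contributes a shared log-normal
#' multiplier (the litter batch effect) applied to both of its samples.
#' Junction counts are marginally negative-binomial with mean
#' `depth_scale * baseline * litter multiplier * splice share` and variance
#' mu + alpha mu^2; the dispersion enters at the gene x sample level (a
#' shared Gamma multiplier with Poisson junction counts conditional on it),
#' so the junctions of one gene are correlated and usage ratios carry only
#' counting noise, as in real RNA-seq. One gene carries the planted
#' cassette event: in HET samples its two inclusion junctions have splice
#' share `(1 - f)` and its skipping junction share `f`, so the expected
#' inclusion level is Psi = 1 - f; WT samples never skip (skip mean 0).
#' Every other gene carries a null alternative acceptor on its first
#' intron whose usage fraction (drawn once per gene, uniform on 0.2-0.8)
#' is identical in both groups, so anchor sets are testable under the
#' null. Unannotated noise junctions are added per sample at the
#' configured rate with low Poisson counts. Identical seed and
#' configuration give byte-identical output.
#'
#' @param config a [sim_config()]
#' @return list with `jt` (a `junction_table`; planted-event junction rows
#'   are always present even when all-zero), `annotation`, `samples`, and
#'   `truth` (planted gene and junction keys, per-sample true inclusion
#'   fraction, litter effects, baselines)
#' @export
simulate_junction_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_per_group
  layout <- sim_gene_layout(config$n_genes)
  planted <- config$n_genes %/% 2L + 1L  # deterministic middle gene
  annotation <- sim_annotation(layout, planted)
  samples <- data.frame(
    sample_id = c(sprintf("wt%d", seq_len(n)), sprintf("het%d", seq_len(n))),
    group = factor(rep(c("WT", "HET"), each = n), levels = c("WT", "HET")),
    litter = if (config$litter_pairing) {
      rep(sprintf("litter%d", seq_len(n)), times = 2L)
    } else {
      sprintf("litter%d", seq_len(2L * n))
    }, stringsAsFactors = FALSE)

  set.seed(derive_seed(config$seed, "baseline"))
  baseline <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 0.5)
  set.seed(derive_seed(config$seed, "altusage"))
  alt_usage <- stats::runif(config$n_genes, 0.2, 0.8)
  alt_usage[planted] <- 0  # the planted gene has no alternative acceptor
  set.seed(derive_seed(config$seed, "litter"))
  litters <- unique(samples$litter)
  litter_mult <- stats::rlnorm(length(litters), meanlog = 0,
                               sdlog = config$litter_sd)
  names(litter_mult) <- litters
  f <- config$planted_skip_fraction

  n_samp <- nrow(samples)
  het <- samples$group == "HET"
  sample_mult <- litter_mult[samples$litter]
  keys_j1 <- junction_key("chr1", layout$j1_start, layout$j1_end, "+")
  keys_j1alt <- junction_key("chr1", layout$j1alt_start,
                             layout$j1alt_end, "+")
  keys_j2 <- junction_key("chr1", layout$j2_start, layout$j2_end, "+")
  key_skip <- junction_key("chr1", layout$skip_start[planted],
                           layout$skip_end[planted], "+")

  # Gene-level dispersion: a shared Gamma multiplier (mean 1, variance
  # alpha) per gene and sample, Poisson junction counts conditional on it.
  # Marginally each junction count is NB with mean share * lambda_g *
  # litter * depth and variance mu + alpha * mu^2, but counts within a
  # gene are correlated, so usage noise is binomial-scale.
  gene_mean <- outer(baseline * config$depth_scale, sample_mult)
  set.seed(derive_seed(config$seed, "dispersion"))
  shape <- 1 / config$nb_dispersion
  gamma_gs <- matrix(stats::rgamma(config$n_genes * n_samp, shape = shape,
                                   rate = shape),
                     nrow = config$n_genes)
  base <- gene_mean * gamma_gs

  # splice shares per junction: inclusion isoform fraction is 1 in WT and
  # (1 - f) in HET for the planted gene; the alternative acceptor splits
  # intron-1 reads (1 - rho) : rho identically in both groups
  incl <- matrix(1, nrow = config$n_genes, ncol = n_samp)
  incl[planted, het] <- 1 - f
  share_j1 <- (1 - alt_usage) * incl
  share_j1alt <- alt_usage * incl
  share_j2 <- incl
  mu_skip <- base[planted, ] * ifelse(het, f, 0)

  set.seed(derive_seed(config$seed, "counts"))
  draw <- function(mu) {
    out <- integer(length(mu))
    pos <- mu > 0
    out[pos] <- stats::rpois(sum(pos), lambda = mu[pos])
    out
  }
  c_j1 <- matrix(draw(base * share_j1), nrow = config$n_genes)
  c_j1alt <- matrix(draw(base * share_j1alt), nrow = config$n_genes)
  c_j2 <- matrix(draw(base * share_j2), nrow = config$n_genes)
  c_skip <- draw(mu_skip)

  keep_alt <- seq_len(config$n_genes) != planted
  counts <- rbind(c_j1, c_j1alt[keep_alt, , drop = FALSE], c_j2,
                  matrix(c_skip, nrow = 1L))
  rownames(counts) <- c(keys_j1, keys_j1alt[keep_alt], keys_j2, key_skip)
  colnames(counts) <- samples$sample_id
  meta <- data.frame(
    key = rownames(counts), chrom = "chr1",
    intron_start = c(layout$j1_start, layout$j1alt_start[keep_alt],
                     layout$j2_start, layout$skip_start[planted]),
    intron_end = c(layout$j1_end, layout$j1alt_end[keep_alt],
                   layout$j2_end, layout$skip_end[planted]),
    strand = "+", stringsAsFactors = FALSE)
  meta$annotated <- meta$key %in% annotation$junctions$key

  set.seed(derive_seed(config$seed, "noise"))
  noise <- list()
  for (s in seq_len(n_samp)) {
    hit <- which(stats::runif(config$n_genes) < config$unannotated_noise_rate)
    if (length(hit) == 0L) next
    shift <- sample(5:50, length(hit), replace = TRUE)
    noise[[length(noise) + 1L]] <- data.frame(
      key = junction_key("chr1", layout$j1_start[hit],
                         layout$j1_end[hit] + shift, "+"),
      chrom = "chr1", intron_start = layout$j1_start[hit],
      intron_end = layout$j1_end[hit] + shift, strand = "+",
      sample = samples$sample_id[s],
      count = stats::rpois(length(hit), 3) + 1L,
      stringsAsFactors = FALSE)
  }
  if (length(noise) > 0L) {
    nz <- do.call(rbind, noise)
    nkeys <- unique(nz$key)
    nmeta <- nz[!duplicated(nz$key),
                c("key", "chrom", "intron_start", "intron_end", "strand")]
    nmeta$annotated <- FALSE
    ncounts <- matrix(0L, nrow = length(nkeys), ncol = n_samp,
                      dimnames = list(nkeys, samples$sample_id))
    ncounts[cbind(match(nz$key, nkeys), match(nz$sample,
                                              samples$sample_id))] <- nz$count
    counts <- rbind(counts, ncounts)
    meta <- rbind(meta, nmeta)
  }
  rownames(meta) <- NULL
  jt <- structure(list(junctions = meta, counts = counts),
                  class = "junction_table")
  truth <- list(
    planted_gene = layout$gene_id[planted],
    inclusion1 = keys_j1[planted], inclusion2 = keys_j2[planted],
    skip = key_skip,
    true_inclusion = stats::setNames(ifelse(het, 1 - f, 1),
                                     samples$sample_id),
    alt_usage = stats::setNames(alt_usage, layout$gene_id),
    litter_effects = litter_mult, baseline = baseline,
    config = unclass(config))
  list(jt = jt, annotation = annotation, samples = samples, truth = truth)
}

#' Write a simulated junction dataset to a directory
#'
#' Emits the same formats the readers accept: one SJ.out.tab file per
#' sample (zero-count junctions omitted, as an aligner would), the
#' annotation TSV, the CSV sample sheet, and a truth JSON.
#'
#' @param sim output of [simulate_junction_counts()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_sim_junctions <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$samples$sample_id) {
    cnt <- sim$jt$counts[, s]
    keep <- cnt > 0
    j <- sim$jt$junctions[keep, , drop = FALSE]
    rec <- data.frame(chrom = j$chrom, intron_start = j$intron_start,
                      intron_end = j$intron_end, strand = j$strand,
                      motif = 0L, annotated = j$annotated,
                      unique_count = as.integer(cnt[keep]), multi_count = 0L,
                      max_overhang = 50L, sample_id = s,
                      stringsAsFactors = FALSE)
    write_sj_tab(rec, file.path(dir, paste0(s, ".SJ.out.tab")))
  }
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  utils::write.csv(sim$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated junction dataset back from a directory
#'
#' @param dir directory written by [write_sim_junctions()]
#' @return list with `jt`, `annotation`, `samples` and, when present,
#'   `truth`
#' @export
read_sim_junctions <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  sj <- lapply(samples$sample_id, function(s) {
    read_sj_tab(file.path(dir, paste0(s, ".SJ.out.tab")), s)
  })
  jt <- junction_table(sj)
  jt$counts <- jt$counts[, samples$sample_id, drop = FALSE]
  annotation <- read_annotation(file.path(dir, "annotation.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(jt = jt, annotation = annotation, samples = samples, truth = truth)
}

.stage_vocab <- c("E3.5", "E7.5", "E8.5", "E9.5", "E10.5", "E11.5", "E14.5",
                  "E15.5", "E16.5", "E17.5", "E18.5", "P0", "P21")

#' Simulate a genetic cross with stage-specific lethality
#'
#' Draws litters of embryos with multinomial genotypes under the declared
#' segregation ratio, then records them as collected at a given stage:
#' embryos whose genotype dies before the collection stage appear as
#' untyped resorptions; surviving embryos are typed, except for a small
#' background untyped rate.
#'
#' @param n_litters number of litters
#' @param litter_size mean litter size (Poisson, minimum 1)
#' @param stage collection stage, from the E/P stage vocabulary
#' @param ratio named genotype weights, e.g. `c("+/+" = 1, "+/-" = 2,
#'   "-/-" = 1)`
#' @param lethality named map genotype -> last stage alive (embryos of that
#'   genotype collected after it are resorbed), e.g. `c("-/-" = "E3.5")`
#' @param untyped_rate background probability a surviving embryo is
#'   untyped (default 0.05)
#' @param seed integer seed
#' @return data.frame in [read_genotype_records()] format, one row per
#'   embryo, with an extra `true_genotype` column
#' @export
simulate_cross <- function(n_litters, litter_size, stage,
                           ratio = c("+/+" = 1, "+/-" = 2, "-/-" = 1),
                           lethality = c(), untyped_rate = 0.05, seed = 1) {
  if (!stage %in% .stage_vocab) {
    stop("unknown stage '", stage, "'; legal stages: ",
         paste(.stage_vocab, collapse = ", "))
  }
  if (length(lethality) > 0L && !all(lethality %in% .stage_vocab)) {
    stop("lethality stages must be in the stage vocabulary")
  }
  if (any(ratio < 0) || sum(ratio) <= 0) stop("ratio weights must be >= 0")
  set.seed(derive_seed(seed, "cross"))
  stage_idx <- match(stage, .stage_vocab)
  rows <- list()
  for (l in seq_len(n_litters)) {
    size <- max(1L, stats::rpois(1L, litter_size))
    geno <- sample(names(ratio), size, replace = TRUE,
                   prob = ratio / sum(ratio))
    last_alive <- if (length(lethality) > 0L) unname(lethality[geno]) else
      rep(NA_character_, size)
    dead <- !is.na(last_alive) &
      match(last_alive, .stage_vocab) < stage_idx
    untyped <- dead | stats::runif(size) < untyped_rate
    rows[[l]] <- data.frame(
      stage = stage,
      genotype = ifelse(untyped, "untyped", geno),
      resorbed = dead,
      litter = sprintf("litter%d", l),
      true_genotype = geno, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a blastocyst culture cohort
#'
#' Each embryo starts as a compacted morula and advances one ladder step
#' per day with probability `progression_prob`. Embryos whose genotype is
#' in `hatch_block` can never pass expanded blastocyst and instead die with
#' hazard `block_hazard` per day once capped; all embryos are exposed to a
#' small baseline daily death hazard. Defaults (progression 0.65, block
#' hazard 0.6/day, baseline hazard 0.005/day) make a het x het cohort with
#' hatch-blocked homozygotes lose about a quarter of its embryos over five
#' days.
#'
#' @param genotypes character vector of embryo genotypes
#' @param n_days number of culture days (default 5)
#' @param progression_prob daily probability of advancing one ladder step
#'   (default 0.65)
#' @param hatch_block genotypes that cannot hatch (default `"-/-"`)
#' @param block_hazard daily death hazard of a hatch-blocked embryo at its
#'   cap (default 0.6)
#' @param base_hazard daily death hazard of every live embryo
#'   (default 0.005)
#' @param seed integer seed
#' @return data.frame in [read_culture_records()] format (one row per
#'   embryo per day, dead persisting)
#' @export
simulate_culture_cohort <- function(genotypes, n_days = 5,
                                    progression_prob = 0.65,
                                    hatch_block = "-/-",
                                    block_hazard = 0.6,
                                    base_hazard = 0.005, seed = 1) {
  stopifnot(progression_prob >= 0, progression_prob <= 1,
            block_hazard >= 0, block_hazard <= 1,
            base_hazard >= 0, base_hazard <= 1)
  set.seed(derive_seed(seed, "culture"))
  n <- length(genotypes)
  cap <- ifelse(genotypes %in% hatch_block,
                match("expanded_blastocyst", .culture_ladder),
                length(.culture_ladder))
  state <- rep(1L, n)   # start: compacted morula
  dead <- rep(FALSE, n)
  rows <- list()
  for (day in seq_len(n_days)) {
    adv <- !dead & stats::runif(n) < progression_prob
    state <- ifelse(adv, pmin(state + 1L, cap), state)
    at_cap <- !dead & genotypes %in% hatch_block & state >= cap
    hazard <- ifelse(at_cap, block_hazard + base_hazard, base_hazard)
    dies <- !dead & stats::runif(n) < hazard
    dead <- dead | dies
    rows[[day]] <- data.frame(
      embryo_id = sprintf("embryo%03d", seq_len(n)), day = day,
      status = ifelse(dead, "dead", .culture_ladder[state]),
      genotype = genotypes, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
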