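#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout: 1-based, fully-closed INTRON
# coordinates (the STAR SJ.out.tab dialect). intron_start is the first
# intronic base, intron_end the last. Only unique-read counts (column 7)
# feed downstream statistics; multi-mapped counts are carried but unused.

.sj_strand_codes <- c(`0` = "*", `1` = "+", `2` = "-")

#' Make a junction key
#'
#' Junction identity is the tuple (chrom, intron_start, intron_end, strand),
#' rendered as `"chrom:start-end:strand"`. Strand `"*"` (unknown) is retained
#' as part of the identity rather than collapsed onto `+`/`-`.
#'
#' @param chrom chromosome name
#' @param intron_start,intron_end 1-based first/last intronic base
#' @param strand one of `"+"`, `"-"`, `"*"`
#' @return character vector of keys
#' @export
junction_key <- function(chrom, intron_start, intron_end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(intron_start),
          as.integer(intron_end), strand)
}

#' Read a STAR SJ.out.tab splice-junction file
#'
#' Parses the 9-column tab-delimited junction table STAR emits per sample:
#' chromosome, intron start, intron end (1-based, closed), strand code
#' (0 unknown / 1 `+` / 2 `-`), intron motif, annotated flag, unique-read
#' count, multi-mapped read count, maximum spliced-alignment overhang.
#'
#' @param path path to an SJ.out.tab-style file
#' @param sample_id sample identifier attached to every record
#' @return data.frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `motif`, `annotated` (logical), `unique_count`, `multi_count`,
#'   `max_overhang`, `sample_id`
#' @export
read_sj_tab <- function(path, sample_id) {
  stopifnot(is.character(path), length(path) == 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_sj_table(sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("%s: line %d: expected 9 tab-separated columns, found %d",
                 path, bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 8L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[1L]
    stop(sprintf("%s: line %d: non-numeric value in a numeric column",
                 path, bad))
  }
  rec <- data.frame(
    chrom        = m[, 1L],
    intron_start = as.integer(num[, 1L]),
    intron_end   = as.integer(num[, 2L]),
    strand       = unname(.sj_strand_codes[as.character(as.integer(num[, 3L]))]),
    motif        = as.integer(num[, 4L]),
    annotated    = as.integer(num[, 5L]) != 0L,
    unique_count = as.integer(num[, 6L]),
    multi_count  = as.integer(num[, 7L]),
    max_overhang = as.integer(num[, 8L]),
    sample_id    = sample_id,
    stringsAsFactors = FALSE
  )
  if (anyNA(rec$strand)) {
    bad <- which(is.na(rec$strand))[1L]
    stop(sprintf("%s: line %d: strand code must be 0, 1 or 2", path, bad))
  }
  if (any(rec$intron_start > rec$intron_end)) {
    bad <- which(rec$intron_start > rec$intron_end)[1L]
    stop(sprintf("%s: line %d: intron start exceeds intron end", path, bad))
  }
  if (any(rec$unique_count < 0L) || any(rec$multi_count < 0L)) {
    bad <- which(rec$unique_count < 0L | rec$multi_count < 0L)[1L]
    stop(sprintf("%s: line %d: negative read count", path, bad))
  }
  key <- junction_key(rec$chrom, rec$intron_start, rec$intron_end, rec$strand)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("%s: line %d: duplicate junction %s", path, bad, key[bad]))
  }
  rec
}

empty_sj_table <- function(sample_id = character(0)) {
  data.frame(chrom = character(0), intron_start = integer(0),
             intron_end = integer(0), strand = character(0),
             motif = integer(0), annotated = logical(0),
             unique_count = integer(0), multi_count = integer(0),
             max_overhang = integer(0),
             sample_id = rep(NA_character_, 0),
             stringsAsFactors = FALSE)
}

#' Write a STAR SJ.out.tab splice-junction file
#'
#' Inverse of [read_sj_tab()]: writes the 9-column dialect with the same
#' coordinate convention, so that a write/read round trip is the identity.
#'
#' @param records data.frame as returned by [read_sj_tab()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sj_tab <- function(records, path) {
  code <- match(records$strand, .sj_strand_codes) - 1L
  out <- data.frame(records$chrom, records$intron_start, records$intron_end,
                    code, records$motif, as.integer(records$annotated),
                    records$unique_count, records$multi_count,
                    records$max_overhang)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble per-sample junction records into a junction table
#'
#' Takes a list of per-sample data.frames (one per [read_sj_tab()] call),
#' forms the union of junctions, and zero-fills counts for junctions a
#' sample did not report (STAR omits junctions with no reads). The
#' `annotated` flag of a junction is TRUE if any sample flagged it.
#'
#' @param sj_list list of per-sample junction data.frames
#' @return an object of class `junction_table`: a list with `junctions`
#'   (data.frame of key, chrom, intron_start, intron_end, strand, annotated)
#'   and `counts` (integer matrix, junctions x samples, of unique-read counts)
#' @export
junction_table <- function(sj_list) {
  stopifnot(is.list(sj_list), length(sj_list) > 0L)
  all <- do.call(rbind, sj_list)
  sample_ids <- unique(all$sample_id)
  all$key <- junction_key(all$chrom, all$intron_start, all$intron_end,
                          all$strand)
  keys <- unique(all$key)
  meta <- all[!duplicated(all$key),
              c("key", "chrom", "intron_start", "intron_end", "strand")]
  meta$annotated <- as.logical(tapply(all$annotated, all$key, any)[meta$key])
  rownames(meta) <- NULL
  counts <- matrix(0L, nrow = length(keys), ncol = length(sample_ids),
                   dimnames = list(keys, sample_ids))
  counts[cbind(match(all$key, keys), match(all$sample_id, sample_ids))] <-
    all$unique_count
  structure(list(junctions = meta, counts = counts), class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("junction_table: %d junctions x %d samples (%d annotated)\n",
              nrow(x$counts), ncol(x$counts), sum(x$junctions$annotated)))
  invisible(x)
}

#' Read a lightweight gene/exon annotation
#'
#' The accepted format is a GTF-lite TSV with header
#' `feature  gene_id  transcript_id  chrom  start  end  strand`, one `gene`
#' row per gene (transcript_id `"."`) and one `exon` row per exon of each
#' transcript. Annotated splice junctions are derived as the introns between
#' consecutive exons of each transcript; a junction that no transcript
#' encodes (e.g. an exon-skipping junction) is therefore not annotated.
#'
#' @param path path to the annotation file
#' @return an object of class `annotation`: list with data.frames `genes`
#'   (gene_id, chrom, start, end, strand), `exons`, and `junctions`
#'   (gene_id, chrom, intron_start, intron_end, strand, key)
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "character", "integer", "integer",
                                         "character"))
  needed <- c("feature", "gene_id", "transcript_id", "chrom", "start",
              "end", "strand")
  if (!all(needed %in% names(df))) {
    stop("annotation file must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(structure(list(genes = df[0, c("gene_id", "chrom", "start", "end",
                                          "strand")],
                          exons = df[0, ], junctions = empty_junction_df()),
                     class = "annotation"))
  }
  genes <- df[df$feature == "gene", c("gene_id", "chrom", "start", "end",
                                      "strand")]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  exons <- df[df$feature == "exon", ]
  rownames(exons) <- NULL
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (anyNA(span$start)) {
    stop("exon row references unknown gene_id: ",
         exons$gene_id[is.na(span$start)][1L])
  }
  outside <- exons$start < span$start | exons$end > span$end
  if (any(outside)) {
    stop(sprintf("exon of transcript %s lies outside the span of gene %s",
                 exons$transcript_id[outside][1L],
                 exons$gene_id[outside][1L]))
  }
  jl <- lapply(split(exons, exons$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) > 1L && any(tx$start[-1L] <= tx$end[-nrow(tx)])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1L])
    }
    if (nrow(tx) < 2L) return(NULL)
    data.frame(gene_id = tx$gene_id[1L], chrom = tx$chrom[1L],
               intron_start = tx$end[-nrow(tx)] + 1L,
               intron_end = tx$start[-1L] - 1L,
               strand = tx$strand[1L], stringsAsFactors = FALSE)
  })
  jn <- do.call(rbind, jl)
  if (is.null(jn)) {
    jn <- empty_junction_df()
  } else {
    jn$key <- junction_key(jn$chrom, jn$intron_start, jn$intron_end,
                           jn$strand)
    jn <- jn[!duplicated(paste(jn$gene_id, jn$key)), ]
    rownames(jn) <- NULL
  }
  structure(list(genes = genes, exons = exons, junctions = jn),
            class = "annotation")
}

empty_junction_df <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             intron_start = integer(0), intron_end = integer(0),
             strand = character(0), key = character(0),
             stringsAsFactors = FALSE)
}

#' Write a lightweight annotation file
#'
#' @param annotation an `annotation` object ([read_annotation()] format)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  gene_rows <- data.frame(feature = "gene", gene_id = g$gene_id,
                          transcript_id = ".", chrom = g$chrom,
                          start = g$start, end = g$end, strand = g$strand,
                          stringsAsFactors = FALSE)
  e <- annotation$exons
  exon_rows <- e[, c("feature", "gene_id", "transcript_id", "chrom",
                     "start", "end", "strand")]
  utils::write.table(rbind(gene_rows, exon_rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample sheet
#'
#' CSV with header `sample_id,group,litter`. Groups are the two genotype
#' arms of the study design (`WT`, `HET`); every sample carries a litter id
#' because litters are the pairing/batch unit of the design.
#'
#' @param path path to the CSV sample sheet
#' @return data.frame with columns `sample_id`, `group` (factor with levels
#'   WT, HET), `litter`
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("sample_id", "group", "litter")
  if (!all(needed %in% names(df))) {
    stop("sample sheet must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  }
  if (!all(df$group %in% c("WT", "HET"))) {
    stop("group must be one of: WT, HET (found ",
         paste(setdiff(unique(df$group), c("WT", "HET")), collapse = ", "),
         ")")
  }
  if (any(!nzchar(df$litter)) || anyNA(df$litter)) {
    stop("every sample must have a non-empty litter id")
  }
  df$group <- factor(df$group, levels = c("WT", "HET"))
  df
}

.genotype_levels <- c("+/+", "+/-", "-/-", "untyped")

#' Read per-embryo genotype records
#'
#' CSV with header `stage,genotype,resorbed,litter`; one row per embryo or
#' pup. `genotype` is one of `+/+`, `+/-`, `-/-`, `untyped`; `resorbed` is
#' TRUE/FALSE (resorptions are recorded but excluded from ratio tests).
#'
#' @param path path to the CSV file
#' @return data.frame with columns `stage`, `genotype`, `resorbed`, `litter`
#' @export
read_genotype_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stage = "character",
                                       genotype = "character",
                                       resorbed = "logical",
                                       litter = "character"))
  needed <- c("stage", "genotype", "resorbed", "litter")
  if (!all(needed %in% names(df))) {
    stop("genotype records must have columns: ",
         paste(needed, collapse = ", "))
  }
  bad <- setdiff(unique(df$genotype), .genotype_levels)
  if (length(bad) > 0L) {
    stop("unknown genotype '", bad[1L], "'; legal values: ",
         paste(.genotype_levels, collapse = ", "))
  }
  df
}

# Ordinal blastocyst scoring ladder. pre_morula is a pre-ladder stage kept
# only for anomalous records (e.g. an embryo that never compacted); dead is
# absorbing and outside the ladder order.
.culture_ladder <- c("compacted_morula", "blastocyst", "expanded_blastocyst",
                     "hatched", "outgrowth")
.culture_statuses <- c(.culture_ladder, "dead")

normalize_status <- function(status) {
  s <- tolower(trimws(status))
  s <- gsub("[ -]+", "_", s)
  s[s %in% c("trophectoderm_and_icm_outgrowth", "icm_outgrowth",
             "trophectoderm_outgrowth")] <- "outgrowth"
  s[s == "hatched_blastocyst"] <- "hatched"
  s
}

#' Read per-embryo daily culture records
#'
#' CSV with header `embryo_id,day,status` and optionally `genotype` and
#' `litter`. Status strings are case/space-insensitive; the six legal
#' statuses are the five-step blastocyst ladder (compacted_morula <
#' blastocyst < expanded_blastocyst < hatched < outgrowth) plus `dead`.
#'
#' @param path path to the CSV file
#' @return data.frame with columns `embryo_id`, `day` (integer), `status`,
#'   and optionally `genotype`, `litter`
#' @export
read_culture_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("embryo_id", "day", "status")
  if (!all(needed %in% names(df))) {
    stop("culture records must have columns: ",
         paste(needed, collapse = ", "))
  }
  df$embryo_id <- as.character(df$embryo_id)
  df$day <- as.integer(df$day)
  df$status <- normalize_status(df$status)
  bad <- setdiff(unique(df$status), c(.culture_statuses, "pre_morula"))
  if (length(bad) > 0L) {
    stop("unknown culture status '", bad[1L], "'; the six legal statuses ",
         "are: ", paste(.culture_statuses, collapse = ", "))
  }
  if ("genotype" %in% names(df)) {
    badg <- setdiff(unique(df$genotype), c(.genotype_levels, NA, ""))
    if (length(badg) > 0L) {
      stop("unknown genotype '", badg[1L], "' in culture records")
    }
  }
  df
}
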