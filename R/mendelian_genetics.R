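#' Chi-square goodness of fit to a segregation ratio
#'
#' Pearson goodness-of-fit test of observed genotype counts against
#' expected Mendelian weights (e.g. 1:2:1 for a het x het cross, 1:1 for
#' het x WT). Expected counts are the ratio-normalised total; the statistic
#' is sum((O - E)^2 / E) with no continuity correction and the p-value is
#' the upper tail of the chi-square distribution with df = (number of
#' categories with non-zero expectation) - 1. Categories with zero ratio
#' weight are dropped with a warning (a cross that cannot produce a
#' genotype contributes no expectation). The test is invariant to scaling
#' of the ratio weights.
#'
#' @param observed non-negative counts per category (untyped and resorbed
#'   individuals must be excluded by the caller)
#' @param expected_ratio non-negative weights, same length as `observed`
#' @return list of class `chisq_gof` with `statistic`, `df`, `p_value`,
#'   `observed`, `expected`
#' @export
chisq_gof <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio)) {
    stop("observed and expected_ratio must have the same length")
  }
  if (any(observed < 0) || any(expected_ratio < 0)) {
    stop("counts and ratio weights must be non-negative")
  }
  drop <- expected_ratio == 0
  if (any(drop)) {
    if (any(observed[drop] > 0)) {
      warning(sum(observed[drop]), " observation(s) in categories with ",
              "zero expected weight were dropped from the test")
    } else {
      warning("dropping ", sum(drop),
              " category(ies) with zero expected weight")
    }
    observed <- observed[!drop]
    expected_ratio <- expected_ratio[!drop]
  }
  n <- sum(observed)
  if (n == 0) stop("total observed count is zero")
  if (length(observed) < 2L) stop("need at least two categories to test")
  expected <- n * expected_ratio / sum(expected_ratio)
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tabulate per-embryo genotype records by stage
#'
#' Collapses per-embryo rows (stage, genotype, resorbed, litter) into a
#' stage x genotype table with untyped and resorption bookkeeping, the
#' number of distinct litters per stage, and a TOTAL row equal to the
#' column sums (litters counted as distinct litter ids overall).
#'
#' @param records data.frame in [read_genotype_records()] format
#' @param stages optional ordered stage vocabulary; defaults to order of
#'   appearance. Unknown stages in `records` are an error when supplied.
#' @return data.frame with columns `stage`, `wt` (+/+), `het` (+/-),
#'   `hom` (-/-), `untyped`, `resorptions`, `total` (typed embryos only;
#'   untyped are bookkept separately), `litters`
#' @export
tabulate_genotypes <- function(records, stages = NULL) {
  if (nrow(records) == 0L) {
    return(data.frame(stage = character(0), wt = integer(0),
                      het = integer(0), hom = integer(0),
                      untyped = integer(0), resorptions = integer(0),
                      total = integer(0), litters = integer(0),
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(records$genotype), .genotype_levels)
  if (length(bad) > 0L) stop("unknown genotype: ", bad[1L])
  if (is.null(stages)) {
    stages <- unique(records$stage)
  } else if (!all(records$stage %in% stages)) {
    stop("stage not in declared vocabulary: ",
         setdiff(unique(records$stage), stages)[1L])
  }
  one <- function(d, label) {
    data.frame(stage = label,
               wt = sum(d$genotype == "+/+"),
               het = sum(d$genotype == "+/-"),
               hom = sum(d$genotype == "-/-"),
               untyped = sum(d$genotype == "untyped"),
               resorptions = sum(d$resorbed),
               total = sum(d$genotype != "untyped"),
               litters = length(unique(d$litter)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(stages[stages %in% records$stage], function(s) {
    one(records[records$stage == s, , drop = FALSE], s)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, one(records, "TOTAL"))
  rownames(out) <- NULL
  out
}

#' Per-stage Mendelian ratio report
#'
#' Runs [chisq_gof()] on the typed genotype counts of every stage row of a
#' [tabulate_genotypes()] table (untyped and resorbed are excluded), plus
#' the TOTAL row, against the expected ratio of the declared cross
#' (het x het: 1:2:1 over +/+, +/-, -/-; het x WT: 1:1 over +/+, +/-).
#' Stages whose p-value falls below `alpha` are flagged as deviating from
#' the Mendelian expectation. Stages with zero typed embryos are skipped
#' with a warning.
#'
#' @param table a [tabulate_genotypes()] data.frame
#' @param expected_ratio named weights over genotype categories, e.g.
#'   `c("+/+" = 1, "+/-" = 2, "-/-" = 1)`
#' @param alpha flagging level (default 0.05)
#' @return data.frame with `stage`, observed typed counts, `statistic`,
#'   `df`, `p_value`, `flagged`
#' @export
mendelian_report <- function(table,
                             expected_ratio = c("+/+" = 1, "+/-" = 2,
                                                "-/-" = 1),
                             alpha = 0.05) {
  if (any(expected_ratio < 0) || sum(expected_ratio) <= 0) {
    stop("ratio weights must be non-negative with a positive sum")
  }
  colmap <- c("+/+" = "wt", "+/-" = "het", "-/-" = "hom")
  cats <- names(expected_ratio)
  if (!all(cats %in% names(colmap))) {
    stop("ratio categories must be among: ",
         paste(names(colmap), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    obs <- as.numeric(table[i, colmap[cats]])
    base <- data.frame(stage = table$stage[i], stringsAsFactors = FALSE)
    for (k in seq_along(cats)) base[[cats[k]]] <- obs[k]
    if (sum(obs) == 0) {
      warning("stage ", table$stage[i], " has zero typed embryos; skipped")
      base$statistic <- NA_real_; base$df <- NA_integer_
      base$p_value <- NA_real_; base$flagged <- NA
      return(base)
    }
    fit <- chisq_gof(obs, unname(expected_ratio))
    base$statistic <- fit$statistic
    base$df <- fit$df
    base$p_value <- fit$p_value
    base$flagged <- fit$p_value < alpha
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
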