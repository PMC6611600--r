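#' The blastocyst scoring ladder
#'
#' Ordinal stages used to score cultured pre-implantation embryos each day:
#' compacted morula (no discernible cell boundaries, no cavity) <
#' blastocyst (cavity under half the embryo volume) < expanded blastocyst
#' (cavity over half) < hatched (escaped the zona pellucida) < outgrowth
#' (discernible inner cell mass with trophectoderm spreading). `dead` is an
#' absorbing state outside the ladder; `pre_morula` is a pre-ladder stage
#' for anomalous records.
#'
#' @return character vector of ladder stages in increasing order
#' @export
culture_ladder <- function() .culture_ladder

ladder_rank <- function(status) {
  # pre_morula ranks below the ladder; dead has no rank (NA)
  r <- match(status, .culture_ladder)
  r[status == "pre_morula"] <- 0L
  r
}

#' Validate per-embryo culture trajectories
#'
#' Checks the ordinal semantics of the scoring ladder: within one embryo,
#' non-dead status never regresses with day, and death is absorbing (no
#' later non-dead record). Duplicate (embryo, day) records are an error.
#'
#' @param records data.frame in [read_culture_records()] format
#' @return list with `valid` (logical) and `violations` (data.frame of
#'   embryo_id, day, problem)
#' @export
validate_trajectories <- function(records) {
  key <- paste(records$embryo_id, records$day)
  if (anyDuplicated(key)) {
    stop("duplicate (embryo, day) record: ", key[duplicated(key)][1L])
  }
  viol <- list()
  for (d in split(records, records$embryo_id)) {
    d <- d[order(d$day), ]
    dead_seen <- FALSE
    last_rank <- -Inf
    for (i in seq_len(nrow(d))) {
      st <- d$status[i]
      if (dead_seen && st != "dead") {
        viol[[length(viol) + 1L]] <-
          data.frame(embryo_id = d$embryo_id[i], day = d$day[i],
                     problem = "status after death", stringsAsFactors = FALSE)
      } else if (st == "dead") {
        dead_seen <- TRUE
      } else {
        r <- ladder_rank(st)
        if (!is.na(r) && r < last_rank) {
          viol[[length(viol) + 1L]] <-
            data.frame(embryo_id = d$embryo_id[i], day = d$day[i],
                       problem = "ladder regression",
                       stringsAsFactors = FALSE)
        }
        last_rank <- max(last_rank, r, na.rm = TRUE)
      }
    }
  }
  violations <- if (length(viol) > 0L) do.call(rbind, viol) else
    data.frame(embryo_id = character(0), day = integer(0),
               problem = character(0), stringsAsFactors = FALSE)
  list(valid = nrow(violations) == 0L, violations = violations)
}

# Status matrix embryos x days with dead carried forward; errors on a
# missing day for a live embryo.
status_matrix <- function(records) {
  days <- sort(unique(records$day))
  embryos <- unique(records$embryo_id)
  m <- matrix(NA_character_, nrow = length(embryos), ncol = length(days),
              dimnames = list(embryos, as.character(days)))
  m[cbind(match(records$embryo_id, embryos),
          match(records$day, days))] <- records$status
  for (i in seq_len(nrow(m))) {
    dead <- FALSE
    for (j in seq_len(ncol(m))) {
      if (is.na(m[i, j])) {
        if (dead) m[i, j] <- "dead"
        else stop("missing day ", days[j], " record for live embryo ",
                  embryos[i])
      }
      if (m[i, j] == "dead") dead <- TRUE
    }
  }
  m
}

#' Summarise a culture cohort by day
#'
#' Builds the per-day outcome table of a blastocyst culture: counts of
#' embryos at each ladder status (each embryo counted once, at its status
#' of the day), new deaths that day, cumulative dead count and percentage
#' of N, and healthy (alive) count and percentage. Percentages are reported
#' to one decimal place.
#'
#' @param records validated data.frame in [read_culture_records()] format
#' @return object of class `culture_summary`: list with `by_day` data.frame
#'   (day, one column per ladder status, new_deaths, cum_dead,
#'   pct_dead, healthy, pct_healthy), `n`, and `litters` (NA when the
#'   records carry no litter column)
#' @export
summarize_culture <- function(records) {
  v <- validate_trajectories(records)
  if (!v$valid) {
    stop("invalid trajectories; first violation: embryo ",
         v$violations$embryo_id[1L], " day ", v$violations$day[1L], " (",
         v$violations$problem[1L], ")")
  }
  m <- status_matrix(records)
  n <- nrow(m)
  days <- as.integer(colnames(m))
  rows <- lapply(seq_along(days), function(j) {
    st <- m[, j]
    counts <- vapply(.culture_ladder, function(s) sum(st == s), integer(1))
    cum_dead <- sum(st == "dead")
    prev_dead <- if (j == 1L) 0L else sum(m[, j - 1L] == "dead")
    out <- data.frame(day = days[j], stringsAsFactors = FALSE)
    for (s in .culture_ladder) out[[s]] <- counts[[s]]
    out$new_deaths <- cum_dead - prev_dead
    out$cum_dead <- cum_dead
    out$pct_dead <- round(100 * cum_dead / n, 1)
    out$healthy <- n - cum_dead
    out$pct_healthy <- round(100 * (n - cum_dead) / n, 1)
    out
  })
  by_day <- do.call(rbind, rows)
  litters <- if ("litter" %in% names(records)) {
    length(unique(records$litter))
  } else NA_integer_
  structure(list(by_day = by_day, n = n, litters = litters),
            class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat(sprintf("Blastocyst culture summary: N = %d embryos%s\n", x$n,
              if (is.na(x$litters)) "" else
                sprintf(" from %d litters", x$litters)))
  print(x$by_day, row.names = FALSE)
  invisible(x)
}

#' Final-day outcome rates
#'
#' The percentage of embryos whose final-day status is at or beyond a given
#' ladder stage (e.g. hatched-or-beyond, outgrowth). Dead embryos never
#' qualify. The denominator is all embryos or the final-day survivors; the
#' rate is rounded to the nearest integer percent, the convention for
#' prose-style rates.
#'
#' @param records data.frame in [read_culture_records()] format
#' @param at_least ladder stage that defines the outcome (default
#'   `"hatched"`)
#' @param denominator `"all"` (default) or `"survivors"`
#' @return list with `count`, `denominator`, `rate` (integer percent)
#' @export
outcome_rates <- function(records, at_least = "hatched",
                          denominator = c("all", "survivors")) {
  denominator <- match.arg(denominator)
  if (!at_least %in% .culture_ladder) {
    stop("at_least must be one of: ", paste(.culture_ladder, collapse = ", "))
  }
  m <- status_matrix(records)
  final <- m[, ncol(m)]
  qual <- !is.na(ladder_rank(final)) &
    ladder_rank(final) >= ladder_rank(at_least)
  denom <- if (denominator == "all") length(final) else sum(final != "dead")
  if (denom == 0L) stop("empty denominator")
  list(count = sum(qual), denominator = denom,
       rate = round(100 * sum(qual) / denom))
}
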