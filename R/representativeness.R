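#' Log-linear interpolation of historical population sizes
#'
#' Interpolates sparse historical population-size point estimates
#' assuming exponential growth between anchors (linear in log count).
#' Extrapolation outside the anchor range is refused.
#'
#' @param points Data frame with columns `year` and `count` (>= 2 rows,
#'   positive counts).
#' @param years Years at which to interpolate.
#' @return Data frame with columns `year` and `count`.
#' @export
interpolate_population <- function(points, years) {
  stopifnot(is.data.frame(points), all(c("year", "count") %in%
                                         names(points)))
  points <- points[order(points$year), , drop = FALSE]
  if (nrow(points) < 2L)
    stop("need at least two population anchors", call. = FALSE)
  if (any(points$count <= 0))
    stop("population anchors must be positive", call. = FALSE)
  if (any(years < min(points$year) | years > max(points$year)))
    stop("extrapolation outside the anchor years is not supported",
         call. = FALSE)
  cnt <- exp(stats::approx(points$year, log(points$count),
                           xout = years, ties = "ordered")$y)
  data.frame(year = years, count = cnt)
}

alive_at_midyear <- function(records, year) {
  sum(records$birth_imp <= year + 0.5 & records$death_imp > year + 0.5,
      na.rm = TRUE)
}

#' Yearly population coverage of a genealogy sample
#'
#' Coverage in year t is the number of sample records alive at mid-year t
#' divided by the (interpolated) population size.  Values above 1 are
#' flagged as anomalies rather than dropped.
#'
#' @param records Genealogy records data frame (usable birth and death
#'   dates; records missing a death date are excluded from the alive
#'   counts).
#' @param population Data frame with columns `year` and `count`, e.g.
#'   from [interpolate_population()].
#' @return Data frame with columns `year`, `n_alive_sample`,
#'   `population_size`, `coverage`, `anomaly`.
#' @export
coverage_series <- function(records, population) {
  stopifnot(all(c("year", "count") %in% names(population)))
  if (any(population$count <= 0))
    stop("population size is zero at queried year(s)", call. = FALSE)
  records <- impute_exact_dates(records)
  alive <- vapply(population$year, function(y)
    alive_at_midyear(records, y), numeric(1))
  cov <- alive / population$count
  data.frame(year = population$year, n_alive_sample = alive,
             population_size = population$count, coverage = cov,
             anomaly = cov > 1)
}

place_similarity <- function(a, b) {
  # normalized edit-distance ratio on normalized place strings
  a <- normalize_place(a); b <- normalize_place(b)
  if (!nzchar(a) || !nzchar(b)) return(NA_real_)
  1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
}

#' Link a scholar roster into genealogy records
#'
#' Candidate pairs are blocked on birth and death year (within
#' `year_tolerance`); a candidate is confirmed when months agree wherever
#' both are known (if `require_month`) and the normalized place
#' similarity of the birth or the death place reaches
#' `place_threshold`.  Conflicts are resolved greedily by highest score
#' with a deterministic identifier-order tie-break; the result is
#' one-to-at-most-one in both directions.
#'
#' @param records Genealogy records data frame.
#' @param roster Scholar roster (see [generate_scholar_roster()] for the
#'   layout; the truth-link `person_id` column is not used for matching).
#' @param year_tolerance Allowed absolute difference in birth/death year.
#' @param require_month Require month agreement where both sides know it.
#' @param place_threshold Minimum normalized place similarity in \[0, 1\].
#' @return Data frame of class `match_result` with columns `roster_id`,
#'   `genealogy_id`, `match_score`, `matched_on`; unmatched roster ids
#'   are in attribute `unmatched`.
#' @export
match_scholars <- function(records, roster, year_tolerance = 0,
                           require_month = TRUE, place_threshold = 0.85) {
  rb_year <- floor(records$birth_date)
  rd_year <- floor(records$death_date)
  rb_month <- month_of_frac(records$birth_date, records$birth_precision)
  rd_month <- month_of_frac(records$death_date, records$death_precision)

  cand <- list()
  for (i in seq_len(nrow(roster))) {
    hit <- which(!is.na(rb_year) & !is.na(rd_year) &
                   abs(rb_year - roster$birth_year[i]) <= year_tolerance &
                   abs(rd_year - roster$death_year[i]) <= year_tolerance)
    for (j in hit) {
      months_checked <- 0L; months_agree <- 0L
      if (!is.na(roster$birth_month[i]) && !is.na(rb_month[j])) {
        months_checked <- months_checked + 1L
        months_agree <- months_agree +
          (roster$birth_month[i] == rb_month[j])
      }
      if (!is.na(roster$death_month[i]) && !is.na(rd_month[j])) {
        months_checked <- months_checked + 1L
        months_agree <- months_agree +
          (roster$death_month[i] == rd_month[j])
      }
      if (require_month && months_agree < months_checked) next
      sims <- c(place_similarity(roster$birth_place[i],
                                 records$birth_place[j]),
                place_similarity(roster$death_place[i],
                                 records$death_place[j]))
      best_sim <- suppressWarnings(max(sims, na.rm = TRUE))
      if (!is.finite(best_sim) || best_sim < place_threshold) next
      fields <- c("year",
                  if (months_checked > 0L) "month",
                  "place")
      cand[[length(cand) + 1L]] <- data.frame(
        roster_id = roster$scholar_id[i],
        genealogy_id = records$person_id[j],
        match_score = best_sim + 0.1 * months_agree,
        matched_on = paste(fields, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$match_score, cand$roster_id,
                       cand$genealogy_id), , drop = FALSE]
    taken_r <- character(0); taken_g <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$roster_id[i] %in% taken_r ||
          cand$genealogy_id[i] %in% taken_g) next
      keep[i] <- TRUE
      taken_r <- c(taken_r, cand$roster_id[i])
      taken_g <- c(taken_g, cand$genealogy_id[i])
    }
    out <- cand[keep, , drop = FALSE]
  } else {
    out <- data.frame(roster_id = character(0),
                      genealogy_id = character(0),
                      match_score = numeric(0),
                      matched_on = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unmatched") <- setdiff(roster$scholar_id, out$roster_id)
  class(out) <- c("match_result", "data.frame")
  out
}

#' Per-period scholar oversampling factor
#'
#' Ratio of the share of (matched) scholars among sample records alive at
#' each period midpoint to the share of scholars in the total population:
#' values above 1 mean elites are overrepresented in the genealogy.
#' Undefined ratios (zero denominators) are returned as NA and flagged.
#'
#' @param records Genealogy records data frame.
#' @param matches A `match_result` from [match_scholars()].
#' @param scholar_population Data frame with columns `period_lo`,
#'   `period_hi`, `n_scholars` — scholars alive in the total population
#'   at each period midpoint.
#' @param population Data frame with `year`/`count` anchors for
#'   [interpolate_population()].
#' @param periods Matrix or data frame of period intervals
#'   (`period_lo`, `period_hi`); defaults to `scholar_population`'s.
#' @return Data frame with period bounds, the two shares, `oversampling`,
#'   and a `flagged` column for undefined ratios.
#' @export
oversampling_series <- function(records, matches, scholar_population,
                                population, periods = NULL) {
  if (is.null(periods))
    periods <- scholar_population[, c("period_lo", "period_hi")]
  records <- impute_exact_dates(records)
  matched_ids <- matches$genealogy_id
  out <- lapply(seq_len(nrow(periods)), function(i) {
    mid <- (periods$period_lo[i] + periods$period_hi[i]) / 2
    n_alive <- alive_at_midyear(records, mid)
    msub <- records[records$person_id %in% matched_ids, , drop = FALSE]
    n_sch_sample <- alive_at_midyear(msub, mid)
    srow <- which(scholar_population$period_lo == periods$period_lo[i])
    n_sch_pop <- if (length(srow)) scholar_population$n_scholars[srow[1]]
    else NA_real_
    pop_size <- interpolate_population(population, mid)$count
    share_sample <- if (n_alive > 0) n_sch_sample / n_alive else NA_real_
    share_pop <- if (!is.na(n_sch_pop) && pop_size > 0)
      n_sch_pop / pop_size else NA_real_
    ov <- if (!is.na(share_sample) && !is.na(share_pop) && share_pop > 0)
      share_sample / share_pop else NA_real_
    data.frame(period_lo = periods$period_lo[i],
               period_hi = periods$period_hi[i],
               n_alive_sample = n_alive,
               share_scholars_sample = share_sample,
               share_scholars_population = share_pop,
               oversampling = ov,
               flagged = is.na(ov))
  })
  do.call(rbind, out)
}

#' Correlation between a sampling diagnostic and elite resemblance
#'
#' Resemblance in a period is the negative absolute difference between
#' the sample's e30 and the elite (scholar) e30 — larger values mean the
#' sample looks more like the elite.  Returns the Pearson correlation of
#' the driver series (coverage, oversampling, ...) with resemblance.
#'
#' @param e30_sample Per-period e30 from the genealogy sample.
#' @param e30_elite Per-period elite e30 (conventionally the woLT
#'   variant, which is the more comparable one).
#' @param driver Per-period diagnostic series, aligned with the e30
#'   series.
#' @param resemblance_fn Resemblance functional; default
#'   `-|e30_sample - e30_elite|` (pluggable, since any monotone
#'   alternative is defensible).
#' @return Pearson correlation coefficient; NA with a warning when
#'   either series has zero variance.
#' @export
resemblance_correlation <- function(e30_sample, e30_elite, driver,
                                    resemblance_fn = function(s, e)
                                      -abs(s - e)) {
  stopifnot(length(e30_sample) == length(e30_elite),
            length(driver) == length(e30_sample))
  ok <- stats::complete.cases(e30_sample, e30_elite, driver)
  if (sum(ok) < 3L)
    stop("need at least 3 aligned periods", call. = FALSE)
  res <- resemblance_fn(e30_sample[ok], e30_elite[ok])
  if (stats::sd(res) == 0 || stats::sd(driver[ok]) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(driver[ok], res)
}
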