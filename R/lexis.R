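#' Person-years lived inside one Lexis cell
#'
#' Time lived in the intersection of an age interval, a calendar-period
#' interval, and the (possibly left-truncated) lifeline
#' `[birth + entry_age, death)`.  All intervals are half-open
#' `[lo, hi)`.
#'
#' @param record A one-row records data frame (exact or imputable dates).
#' @param age_cell Numeric length-2 age interval in years.
#' @param period_cell Numeric length-2 calendar interval.
#' @param entry_age Optional delayed-entry age in years (left truncation);
#'   NULL or 0 means observed from birth.
#' @return Person-years (>= 0).
#' @export
person_cell_exposure <- function(record, age_cell, period_cell,
                                 entry_age = NULL) {
  record <- impute_exact_dates(record)
  b <- record$birth_imp; d <- record$death_imp
  if (is.na(b) || is.na(d))
    stop("record lacks usable dates", call. = FALSE)
  e <- if (is.null(entry_age) || is.na(entry_age)) 0 else entry_age
  if (e > d - b)
    stop("entry_age exceeds death age", call. = FALSE)
  start <- max(b + e, b + age_cell[1], period_cell[1])
  end <- min(d, b + age_cell[2], period_cell[2])
  max(0, end - start)
}

#' Tabulate lifelines to a Lexis grid of deaths and exposures
#'
#' Converts individual records into death counts (by age at death and
#' period of death) and person-year exposures on an age-by-period lattice
#' of half-open cells.  Year-precision dates are imputed at mid-year.
#' With `use_entry_age = TRUE` (the "wLT" left-truncated variant)
#' exposure before each person's entry age is not counted; with
#' `use_entry_age = FALSE` ("woLT") entry ages are ignored.  Records with
#' a missing death date are excluded and counted, unless
#' `right_censor_year` is given, in which case they contribute exposure
#' up to that year but no death (right-censoring robustness variant).
#'
#' @param records Records data frame.
#' @param age_edges Strictly increasing age-interval edges in years
#'   (default 5-y groups 30-80 with the open interval closed at 100).
#' @param period_edges Strictly increasing calendar-period edges.
#' @param use_entry_age Honor the `entry_age` column (left truncation).
#' @param right_censor_year Optional censoring year for deathless records.
#' @return An object of class `lexis_grid`: list with `age_edges`,
#'   `period_edges`, integer matrix `deaths`, numeric matrix `exposures`
#'   (ages x periods), and the `truncated` flag.
#' @export
tabulate_lexis <- function(records,
                           age_edges = c(seq(30, 80, by = 5), 100),
                           period_edges, use_entry_age = FALSE,
                           right_censor_year = NULL) {
  stopifnot(nrow(records) > 0L, length(age_edges) >= 2L,
            all(diff(age_edges) > 0), length(period_edges) >= 2L,
            all(diff(period_edges) > 0))
  records <- impute_exact_dates(records)
  b <- records$birth_imp
  d <- records$death_imp
  has_death <- !is.na(d) & !is.na(records$death_precision) &
    records$death_precision != "missing"
  n_missing_death <- sum(!has_death | is.na(b))

  if (is.null(right_censor_year)) {
    keep <- has_death & !is.na(b)
  } else {
    keep <- !is.na(b)
    d[keep & !has_death] <- right_censor_year
  }
  b <- b[keep]; d <- d[keep]
  counted_death <- has_death[keep]

  entry <- rep(0, sum(keep))
  if (use_entry_age && !is.null(records$entry_age)) {
    e <- records$entry_age[keep]
    e[is.na(e)] <- 0
    if (any(e > d - b))
      stop("entry_age exceeds death age for record(s): ",
           paste(utils::head(records$person_id[keep][e > d - b], 5),
                 collapse = ", "), call. = FALSE)
    entry <- pmax(e, 0)
  }

  na <- length(age_edges) - 1L
  np <- length(period_edges) - 1L
  deaths <- matrix(0L, na, np)
  exposures <- matrix(0, na, np)

  # deaths: one cell per death (age at death x period of death)
  age_at_death <- d - b
  ai <- findInterval(age_at_death, age_edges,
                     rightmost.closed = FALSE, left.open = FALSE)
  pi_ <- findInterval(d, period_edges)
  ok <- counted_death & ai >= 1 & ai <= na &
    age_at_death < age_edges[na + 1L] & pi_ >= 1 & pi_ <= np &
    d < period_edges[np + 1L]
  if (any(ok)) {
    tab <- table(factor(ai[ok], levels = seq_len(na)),
                 factor(pi_[ok], levels = seq_len(np)))
    deaths <- deaths + matrix(as.integer(tab), na, np)
  }

  # exposures: for each age band, the calendar interval [s, e) spent in
  # that band is split across period bins via the clamp identity
  #   exposure in [p_lo, p_hi) = f(p_hi) - f(p_lo),  f(t) = clamp(t, s, e)
  obs_start <- b + entry
  for (i in seq_len(na)) {
    s <- pmax(obs_start, b + age_edges[i])
    e <- pmin(d, b + age_edges[i + 1L])
    live <- e > s
    if (!any(live)) next
    s <- s[live]; e <- e[live]
    f_prev <- pmin(pmax(period_edges[1L], s), e)
    for (j in seq_len(np)) {
      f_next <- pmin(pmax(period_edges[j + 1L], s), e)
      exposures[i, j] <- exposures[i, j] + sum(f_next - f_prev)
      f_prev <- f_next
    }
  }

  structure(list(age_edges = age_edges, period_edges = period_edges,
                 deaths = deaths, exposures = exposures,
                 truncated = isTRUE(use_entry_age),
                 n_missing_death = n_missing_death,
                 n_records = sum(keep)),
            class = "lexis_grid")
}

#' @export
print.lexis_grid <- function(x, ...) {
  cat(sprintf(
    "<lexis_grid> %d age band(s) x %d period(s); %d death(s), %.1f person-years%s\n",
    nrow(x$deaths), ncol(x$deaths), sum(x$deaths), sum(x$exposures),
    if (x$truncated) " (left-truncated)" else ""))
  invisible(x)
}

#' Long-format view of a Lexis grid
#'
#' @param x A `lexis_grid`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `age_lo`, `age_hi`, `period_lo`,
#'   `period_hi`, `deaths`, `exposure`.
#' @export
as.data.frame.lexis_grid <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  na <- nrow(x$deaths); np <- ncol(x$deaths)
  data.frame(
    age_lo = rep(x$age_edges[-(na + 1L)], np),
    age_hi = rep(x$age_edges[-1L], np),
    period_lo = rep(x$period_edges[-(np + 1L)], each = na),
    period_hi = rep(x$period_edges[-1L], each = na),
    deaths = as.integer(x$deaths),
    exposure = as.numeric(x$exposures))
}

#' Write a Lexis grid as long-format delimited text
#' @param grid A `lexis_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexis_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Collapse a Lexis grid's periods into one interval, or aggregate fine
# age bands up to coarser edges; used by the life-table stage.
aggregate_lexis <- function(grid, age_edges = NULL, period = NULL) {
  ae <- grid$age_edges; pe <- grid$period_edges
  D <- grid$deaths; E <- grid$exposures
  if (!is.null(period)) {
    jj <- which(pe[-length(pe)] >= period[1] & pe[-1L] <= period[2])
    if (!length(jj)) stop("period outside grid", call. = FALSE)
    D <- matrix(rowSums(D[, jj, drop = FALSE]), ncol = 1)
    E <- matrix(rowSums(E[, jj, drop = FALSE]), ncol = 1)
    pe <- period
  }
  if (!is.null(age_edges)) {
    if (!all(age_edges %in% ae))
      stop("coarse age edges must be a subset of the grid's edges",
           call. = FALSE)
    idx <- findInterval(ae[-length(ae)], age_edges)
    keep <- ae[-length(ae)] >= age_edges[1] &
      ae[-1L] <= age_edges[length(age_edges)]
    D <- apply(D, 2, function(col) tapply(col[keep], idx[keep], sum))
    E <- apply(E, 2, function(col) tapply(col[keep], idx[keep], sum))
    D <- matrix(D, ncol = length(pe) - 1L)
    E <- matrix(E, ncol = length(pe) - 1L)
    ae <- age_edges
  }
  structure(list(age_edges = ae, period_edges = pe,
                 deaths = matrix(as.integer(D), nrow = length(ae) - 1L),
                 exposures = E, truncated = grid$truncated,
                 n_missing_death = grid$n_missing_death,
                 n_records = grid$n_records),
            class = "lexis_grid")
}
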