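#' Read genealogy records from delimited text
#'
#' Parses individual-level genealogy records with mixed date precision
#' (ISO-8601 day, `YYYY-MM` month, bare-year).  Rows with unparseable
#' dates or a death preceding birth are collected into a rejects table
#' with a reason, never silently dropped.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param schema Named character vector mapping the standard field names
#'   (`person_id`, `sex`, `birth_date`, `death_date`, `birth_place`,
#'   `death_place`, optionally `elite`, `entry_age`) to the file's column
#'   names.  Defaults to the identity mapping of [write_records()] output.
#' @return A list with `records` (standardized data frame: fractional-year
#'   dates plus precision flags) and `rejects` (data frame of rejected
#'   rows with a `reason` column).
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  default <- c(person_id = "person_id", sex = "sex",
               birth_date = "birth_date", death_date = "death_date",
               birth_place = "birth_place", death_place = "death_place",
               elite = "elite", entry_age = "entry_age")
  if (is.null(schema)) schema <- default
  mandatory <- c("person_id", "sex", "birth_date", "death_date",
                 "birth_place", "death_place")
  missing_map <- setdiff(mandatory, names(schema))
  if (length(missing_map))
    stop("schema does not map mandatory column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty records file: ", path, call. = FALSE)
  absent <- setdiff(unname(schema[mandatory]), names(raw))
  if (length(absent))
    stop("mandatory column(s) missing from file: ",
         paste(absent, collapse = ", "), call. = FALSE)

  b <- parse_vital_date(raw[[schema[["birth_date"]]]])
  d <- parse_vital_date(raw[[schema[["death_date"]]]])
  records <- data.frame(
    person_id = raw[[schema[["person_id"]]]],
    sex = raw[[schema[["sex"]]]],
    birth_date = b$value, birth_precision = b$precision,
    death_date = d$value, death_precision = d$precision,
    birth_place = raw[[schema[["birth_place"]]]],
    death_place = raw[[schema[["death_place"]]]],
    stringsAsFactors = FALSE)
  if ("elite" %in% names(schema) && schema[["elite"]] %in% names(raw))
    records$elite <- as.logical(raw[[schema[["elite"]]]])
  if ("entry_age" %in% names(schema) && schema[["entry_age"]] %in% names(raw))
    records$entry_age <- suppressWarnings(
      as.numeric(raw[[schema[["entry_age"]]]]))

  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$birth_precision)] <- "unparseable birth date"
  reason[is.na(records$death_precision)] <- "unparseable death date"
  both <- !is.na(records$birth_date) & !is.na(records$death_date) &
    is.na(reason)
  yr_prec <- records$birth_precision == "year" |
    records$death_precision == "year"
  bad_order <- both & ((!yr_prec & records$death_date < records$birth_date) |
                       (yr_prec & floor(records$death_date) <
                          floor(records$birth_date)))
  reason[bad_order] <- "death precedes birth"
  keep <- is.na(reason)
  rejects <- cbind(raw[!keep, , drop = FALSE],
                   reason = reason[!keep])
  rownames(rejects) <- NULL
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Build a territory membership rule
#'
#' Historical-territory assignment is a declarative predicate over
#' normalized place strings (no GIS boundary work): either an explicit
#' gazetteer of place names or a regular expression.
#'
#' @param places Character vector of in-territory place names, or NULL.
#' @param pattern Regular expression matched against normalized places,
#'   or NULL.  Exactly one of `places`/`pattern` must be given.
#' @return A predicate function over normalized place strings.
#' @export
territory_rule <- function(places = NULL, pattern = NULL) {
  if (is.null(places) == is.null(pattern))
    stop("give exactly one of 'places' or 'pattern'", call. = FALSE)
  if (!is.null(places)) {
    norm <- normalize_place(places)
    function(x) x %in% norm
  } else {
    function(x) grepl(pattern, x)
  }
}

#' Territory membership of records
#'
#' A record belongs to the territory if its birth place OR its death
#' place satisfies the rule.  Records with both places missing are
#' excluded (FALSE).
#'
#' @param records Records data frame.
#' @param rule Predicate from [territory_rule()] (takes normalized place
#'   strings).
#' @return Logical vector, one element per record.
#' @export
assign_territory <- function(records, rule) {
  bp <- normalize_place(records$birth_place)
  dp <- normalize_place(records$death_place)
  (nzchar(bp) & rule(bp)) | (nzchar(dp) & rule(dp))
}

death_age_years <- function(records) {
  exact <- !(records$birth_precision %in% c("year", "missing")) &
    !(records$death_precision %in% c("year", "missing"))
  age <- ifelse(exact, records$death_date - records$birth_date,
                floor(records$death_date) - floor(records$birth_date))
  age[is.na(records$birth_date) | is.na(records$death_date)] <- NA_real_
  age
}

#' Clean genealogy records with an auditable report
#'
#' Applies, in order: the territory rule (if given), the sex filter,
#' duplicate removal (identical birth date, death date and normalized
#' birth place; the lexicographically smallest `person_id` survives),
#' removal of death ages above `max_age` (likely transcription errors),
#' removal of deaths after `last_year`, and — optionally — removal of
#' records without exact (day-precision) dates.  Every removal is counted
#' in a report whose stage counts reconcile exactly.
#'
#' @param records Records data frame (see [read_records()]).
#' @param max_age Maximum credible death age in years (default 100).
#' @param last_year Last calendar year of deaths retained (default 1910;
#'   deaths in `last_year` itself are kept).
#' @param sex Sex to retain (default "male"); NULL keeps all.
#' @param drop_inexact_dates Also remove records whose birth or death
#'   date is not day-precision.
#' @param rule Optional territory predicate from [territory_rule()];
#'   if NULL the records are assumed already territory-filtered.
#' @return A list with `records` (survivors) and `report` (data frame of
#'   class `cleaning_report` with columns `stage`, `n_removed`,
#'   `n_remaining`).
#' @export
clean_records <- function(records, max_age = 100, last_year = 1910,
                          sex = "male", drop_inexact_dates = FALSE,
                          rule = NULL) {
  stages <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(stage, keep) {
    stages <<- c(stages, stage)
    removed <<- c(removed, sum(!keep))
    records <<- records[keep, , drop = FALSE]
    remaining <<- c(remaining, nrow(records))
  }
  n_input <- nrow(records)

  keep <- if (is.null(rule)) rep(TRUE, n_input) else
    assign_territory(records, rule)
  note("territory", keep)

  keep <- if (is.null(sex)) rep(TRUE, nrow(records)) else
    records$sex == sex
  note("sex", keep)

  key <- paste(sprintf("%.6f", records$birth_date),
               sprintf("%.6f", records$death_date),
               normalize_place(records$birth_place), sep = "|")
  ord <- order(key, records$person_id)
  first_id <- records$person_id[ord][!duplicated(key[ord])]
  note("duplicates", records$person_id %in% first_id)

  age <- death_age_years(records)
  note("age_above_max", is.na(age) | age <= max_age)

  death_year <- floor(records$death_date)
  note("period", is.na(death_year) | death_year <= last_year)

  keep <- if (drop_inexact_dates)
    records$birth_precision == "day" & records$death_precision == "day"
  else rep(TRUE, nrow(records))
  note("inexact_dates", keep)

  if (nrow(records) == 0L)
    warning("cleaning removed every record", call. = FALSE)
  rownames(records) <- NULL
  report <- data.frame(stage = stages, n_removed = removed,
                       n_remaining = remaining)
  attr(report, "n_input") <- n_input
  class(report) <- c("cleaning_report", "data.frame")
  list(records = records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d input record(s)\n",
              attr(x, "n_input")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s removed %6d -> %6d remaining\n",
                x$stage[i], x$n_removed[i], x$n_remaining[i]))
  invisible(x)
}

#' Write a cleaning report as delimited text
#' @param report A `cleaning_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  out <- as.data.frame(report)
  out <- rbind(data.frame(stage = "input", n_removed = 0L,
                          n_remaining = attr(report, "n_input")), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
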