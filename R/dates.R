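# Vital dates are stored as fractional years plus a precision flag in
# {"day", "month", "year", "missing"}.  Serialization uses a fixed 365-day
# year grid so that write -> read -> write is byte-stable:
#   day   precision: ISO date with day-of-year d; read back as y + (d-0.5)/365
#   month precision: "YYYY-MM";                  read back as y + (m-0.5)/12
#   year  precision: bare "YYYY";                read back as y (imputation
#                    to mid-year happens only at tabulation time)

frac_to_date_string <- function(value, precision) {
  out <- character(length(value))
  out[is.na(value) | precision == "missing"] <- ""
  idx <- which(!is.na(value) & precision == "day")
  if (length(idx)) {
    y <- floor(value[idx])
    doy <- pmin(floor((value[idx] - y) * 365) + 1L, 365L)
    base <- as.Date(sprintf("%04d-01-01", y))
    out[idx] <- format(base + (doy - 1L), "%Y-%m-%d")
  }
  idx <- which(!is.na(value) & precision == "month")
  if (length(idx)) {
    y <- floor(value[idx])
    m <- pmin(floor((value[idx] - y) * 12) + 1L, 12L)
    out[idx] <- sprintf("%04d-%02d", y, m)
  }
  idx <- which(!is.na(value) & precision == "year")
  if (length(idx)) out[idx] <- sprintf("%04d", floor(value[idx]))
  out
}

parse_vital_date <- function(x) {
  x <- trimws(ifelse(is.na(x), "", as.character(x)))
  n <- length(x)
  value <- rep(NA_real_, n)
  precision <- rep(NA_character_, n)  # NA = unparseable; "missing" = empty
  precision[x == ""] <- "missing"
  is_year <- grepl("^\\d{4}$", x)
  value[is_year] <- as.numeric(x[is_year])
  precision[is_year] <- "year"
  is_month <- grepl("^\\d{4}-\\d{2}$", x)
  if (any(is_month)) {
    y <- as.numeric(substr(x[is_month], 1, 4))
    m <- as.numeric(substr(x[is_month], 6, 7))
    ok <- m >= 1 & m <= 12
    value[is_month][ok] <- (y + (m - 0.5) / 12)[ok]
    precision[is_month][ok] <- "month"
  }
  is_day <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(is_day)) {
    d <- as.Date(x[is_day], format = "%Y-%m-%d")
    ok <- !is.na(d)
    y <- as.numeric(format(d[ok], "%Y"))
    doy <- as.numeric(d[ok] - as.Date(sprintf("%04.0f-01-01", y)))
    value[is_day][ok] <- y + (pmin(doy, 364) + 0.5) / 365
    precision[is_day][ok] <- "day"
  }
  list(value = value, precision = precision)
}

# Impute exact event times for tabulation/interval-stabbing: year-precision
# dates sit at mid-year (+0.5), unbiased under uniform within-year timing.
impute_exact_dates <- function(records) {
  bi <- records$birth_date
  di <- records$death_date
  bi[records$birth_precision == "year"] <-
    bi[records$birth_precision == "year"] + 0.5
  di[records$death_precision == "year"] <-
    di[records$death_precision == "year"] + 0.5
  records$birth_imp <- bi
  records$death_imp <- di
  records
}

month_of_frac <- function(value, precision) {
  m <- floor((value - floor(value)) * 12) + 1L
  m <- pmin(pmax(m, 1L), 12L)
  m[precision %in% c("year", "missing") | is.na(value)] <- NA_integer_
  m
}

#' Normalize a place string
#'
#' Case-folds, transliterates accents to ASCII, strips punctuation, and
#' collapses whitespace.  Used both for deduplication keys and for fuzzy
#' place matching in record linkage.
#'
#' @param x Character vector of place names (NA allowed).
#' @return Normalized character vector ("" for missing input).
#' @export
normalize_place <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  x <- tolower(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  x[is.na(x)] <- ""
  x <- gsub("[^a-z0-9 ]+", "", x)
  trimws(gsub(" +", " ", x))
}
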