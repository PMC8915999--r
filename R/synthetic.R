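#' Ascertainment model for genealogy sampling
#'
#' Describes how a crowdsourced genealogy samples a historical population:
#' a base inclusion probability that may drift over calendar time, an
#' elite visibility multiplier (elites are more visible in historical
#' records and hence oversampled), plus the record-quality defects typical
#' of such data — duplicated profiles, transcription errors inflating
#' death ages past 100, and profiles carrying only a year of birth/death.
#'
#' @param base_inclusion Inclusion probability at the anchor birth year, in
#'   \[0, 1\].
#' @param inclusion_time_slope Change in inclusion probability per calendar
#'   year of birth; realized probabilities are clamped to \[0, 1\].
#' @param elite_inclusion_multiplier Multiplier (>= 1) applied to the
#'   inclusion probability of elite individuals, before clamping.
#' @param duplicate_rate Probability that an included record spawns a
#'   near-duplicate profile (same vital dates, perturbed place spelling).
#' @param age_error_rate Probability that a recorded death age is inflated
#'   past 100 years (transcription error).
#' @param missing_exact_date_rate Probability that a record keeps only the
#'   year of its vital dates.
#' @return An object of class `ascertainment_model`.
#' @export
ascertainment_model <- function(base_inclusion = 0.1,
                                inclusion_time_slope = 0,
                                elite_inclusion_multiplier = 1,
                                duplicate_rate = 0,
                                age_error_rate = 0,
                                missing_exact_date_rate = 0) {
  prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid '%s': must be a probability in [0, 1]", name),
           call. = FALSE)
  }
  prob(base_inclusion, "base_inclusion")
  prob(duplicate_rate, "duplicate_rate")
  prob(age_error_rate, "age_error_rate")
  prob(missing_exact_date_rate, "missing_exact_date_rate")
  if (!is.numeric(inclusion_time_slope) || length(inclusion_time_slope) != 1L ||
      is.na(inclusion_time_slope))
    stop("invalid 'inclusion_time_slope': must be a single number",
         call. = FALSE)
  if (!is.numeric(elite_inclusion_multiplier) ||
      length(elite_inclusion_multiplier) != 1L ||
      is.na(elite_inclusion_multiplier) || elite_inclusion_multiplier < 1)
    stop("invalid 'elite_inclusion_multiplier': must be >= 1", call. = FALSE)
  structure(list(base_inclusion = base_inclusion,
                 inclusion_time_slope = inclusion_time_slope,
                 elite_inclusion_multiplier = elite_inclusion_multiplier,
                 duplicate_rate = duplicate_rate,
                 age_error_rate = age_error_rate,
                 missing_exact_date_rate = missing_exact_date_rate),
            class = "ascertainment_model")
}

# Synthetic place vocabulary; deliberately includes accents so that place
# normalization and fuzzy matching are exercised.
default_places <- function() {
  c("Altbruck", "Bergheim", "Celle", "Dornstadt", "Eichberg",
    "Falkenau", "Grünwald", "Hochdorf", "Immenstadt", "Jever",
    "Krähenfeld", "Lindau")
}

#' Generate a synthetic historical population with known mortality truth
#'
#' Each person receives an exact (day-precision) birth date uniform over
#' `birth_year_range`, an elite indicator, and a death age drawn by
#' inverse-CDF sampling from the Gompertz-Makeham model (elite hazards
#' multiplied by the model's `elite_hazard_ratio`).  The returned truth
#' object records the model, the anchor year (midpoint of the birth-year
#' range, used by both the period trend and the ascertainment time slope),
#' the elite ids, and analytic e30 values for both strata, so that every
#' downstream estimator can be checked against ground truth.
#'
#' @param n Population size (> 0).
#' @param mortality A [mortality_model()].
#' @param birth_year_range Numeric length-2 interval of birth years.
#' @param elite_fraction Proportion of elite individuals in \[0, 1\].
#' @param seed Integer seed; output is bit-identical under a fixed seed.
#' @param places Character vector of place names to sample from.
#' @return A list with elements `records` (data frame of individual
#'   records) and `truth` (list of ground-truth quantities).
#' @export
generate_population <- function(n, mortality = mortality_model(),
                                birth_year_range = c(1600, 1850),
                                elite_fraction = 0.05, seed = 1,
                                places = default_places()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("invalid 'n': must be a positive count", call. = FALSE)
  if (elite_fraction < 0 || elite_fraction > 1)
    stop("invalid 'elite_fraction': must be in [0, 1]", call. = FALSE)
  stopifnot(inherits(mortality, "mortality_model"),
            length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2])
  set.seed(seed)
  n <- as.integer(n)
  anchor <- mean(birth_year_range)
  birth <- stats::runif(n, birth_year_range[1], birth_year_range[2])
  elite <- stats::runif(n) < elite_fraction
  hm <- ifelse(elite, mortality$elite_hazard_ratio, 1)
  lifespan <- draw_lifespans(mortality, n, hazard_multiplier = hm,
                             trend_years = birth - anchor)
  records <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = "male",
    birth_date = birth,
    birth_precision = "day",
    death_date = birth + lifespan,
    death_precision = "day",
    birth_place = sample(places, n, replace = TRUE),
    death_place = sample(places, n, replace = TRUE),
    elite = elite,
    entry_age = NA_real_,
    stringsAsFactors = FALSE)
  truth <- list(
    model = mortality,
    anchor = anchor,
    birth_year_range = birth_year_range,
    elite_fraction = elite_fraction,
    scholar_ids = records$person_id[elite],
    e30_general = analytic_remaining_e(mortality, 30),
    e30_elite = analytic_remaining_e(
      mortality, 30, hazard_multiplier = mortality$elite_hazard_ratio))
  list(records = records, truth = truth)
}

perturb_place <- function(x) {
  # case/accent/punctuation noise only, so normalize_place() still
  # recovers the dedup key
  mode <- sample(3L, length(x), replace = TRUE)
  out <- x
  out[mode == 1L] <- toupper(out[mode == 1L])
  out[mode == 2L] <- paste0(out[mode == 2L], ",")
  out[mode == 3L] <- chartr("aeou", "áéöü",
                            tolower(out[mode == 3L]))
  out
}

#' Sample a biased genealogy from a synthetic population
#'
#' Applies the ascertainment model: each person is included independently
#' with probability `clamp(base + slope * (birth_year - anchor))`, further
#' multiplied by the elite multiplier (then clamped again) for elite
#' individuals.  Included records are then degraded at the configured
#' rates: near-duplicate profiles (same vital dates, perturbed place
#' spelling), death ages inflated past 100 years, and dates coarsened to
#' year precision.
#'
#' @param population Result of [generate_population()], or a records data
#'   frame with an `elite` column.
#' @param model An [ascertainment_model()].
#' @param seed Integer seed.
#' @param anchor Anchor year for the time slope; defaults to the
#'   population truth's anchor (midpoint of the birth-year range).
#' @return A list with `records` (the sampled genealogy) and `truth`
#'   (realized coverage, stratum inclusion rates, expected oversampling,
#'   injected-defect counts).
#' @export
sample_genealogy <- function(population, model = ascertainment_model(),
                             seed = 1, anchor = NULL) {
  stopifnot(inherits(model, "ascertainment_model"))
  if (is.list(population) && !is.data.frame(population) &&
      !is.null(population$records)) {
    if (is.null(anchor)) anchor <- population$truth$anchor
    population <- population$records
  }
  if (nrow(population) == 0L)
    stop("population is empty", call. = FALSE)
  if (is.null(anchor))
    anchor <- mean(range(floor(population$birth_date)))
  set.seed(seed)
  n <- nrow(population)
  elite <- if (!is.null(population$elite)) population$elite else
    rep(FALSE, n)
  p <- model$base_inclusion +
    model$inclusion_time_slope * (population$birth_date - anchor)
  p <- pmin(pmax(p, 0), 1)
  p[elite] <- pmin(p[elite] * model$elite_inclusion_multiplier, 1)
  included <- stats::runif(n) < p
  sampled <- population[included, , drop = FALSE]
  m <- nrow(sampled)

  n_dup <- 0L
  if (m > 0L && model$duplicate_rate > 0) {
    dup <- stats::runif(m) < model$duplicate_rate
    n_dup <- sum(dup)
    if (n_dup > 0L) {
      copies <- sampled[dup, , drop = FALSE]
      copies$person_id <- sub("^P", "D", copies$person_id)
      copies$birth_place <- perturb_place(copies$birth_place)
      copies$death_place <- perturb_place(copies$death_place)
      sampled <- rbind(sampled, copies)
    }
  }
  k <- nrow(sampled)
  n_age_err <- 0L
  if (k > 0L && model$age_error_rate > 0) {
    err <- stats::runif(k) < model$age_error_rate
    n_age_err <- sum(err)
    sampled$death_date[err] <- sampled$birth_date[err] +
      stats::runif(n_age_err, 101, 110)
  }
  n_coarse <- 0L
  if (k > 0L && model$missing_exact_date_rate > 0) {
    co <- stats::runif(k) < model$missing_exact_date_rate
    n_coarse <- sum(co)
    sampled$birth_date[co] <- floor(sampled$birth_date[co])
    sampled$birth_precision[co] <- "year"
    sampled$death_date[co] <- floor(sampled$death_date[co])
    sampled$death_precision[co] <- "year"
  }
  rownames(sampled) <- NULL
  truth <- list(
    anchor = anchor,
    included_ids = population$person_id[included],
    coverage_realized = m / n,
    inclusion_general = mean(p[!elite]),
    inclusion_elite = if (any(elite)) mean(p[elite]) else NA_real_,
    expected_coverage = mean(p),
    expected_oversampling = if (any(elite))
      mean(p[elite]) / mean(p) else NA_real_,
    n_duplicates_injected = n_dup,
    n_age_errors_injected = n_age_err,
    n_year_only_injected = n_coarse)
  list(records = sampled, truth = truth)
}

#' Generate a scholar roster from the elite stratum
#'
#' Scholars enter observation at their first academic appointment.  Each
#' elite member draws an appointment age from `appointment_age_fn`,
#' independently of their lifespan.  Under the default
#' `selection = "thin"`, elites whose drawn appointment age is not below
#' their death age never become scholars and are excluded (counted in the
#' `n_dropped` attribute).  This is exactly the left-truncation mechanism
#' the wLT estimator assumes — entry is independent of lifespan in the
#' source population, and observation is conditioned on surviving to
#' entry.  `selection = "redraw"` instead retries infeasible draws up to
#' `max_retries` times (which makes entry ages *dependent* on lifespan:
#' short-lived scholars are then overrepresented, so wLT estimates from
#' such a roster carry a selection bias; provided for sensitivity
#' checks).  With `strict = TRUE` exhaustion of the retry cap is an
#' error.
#'
#' @param population Result of [generate_population()] or a records data
#'   frame with an `elite` column.
#' @param appointment_age_fn Function of `n` returning `n` appointment
#'   ages in years (default uniform on \[30, 45\]).
#' @param seed Integer seed.
#' @param selection `"thin"` (drop infeasible draws; independent
#'   truncation) or `"redraw"` (retry them).
#' @param max_retries Retry cap per person under `"redraw"`.
#' @param strict Error when the retry cap is exhausted instead of
#'   dropping.
#' @return Data frame with one row per scholar: `scholar_id`, truth-link
#'   `person_id`, birth/death year + month + place, `appointment_year`,
#'   and `entry_age`.  Attribute `n_dropped` counts excluded elites.
#' @export
generate_scholar_roster <- function(population,
                                    appointment_age_fn = function(n)
                                      stats::runif(n, 30, 45),
                                    seed = 1,
                                    selection = c("thin", "redraw"),
                                    max_retries = 100L,
                                    strict = FALSE) {
  selection <- match.arg(selection)
  if (is.list(population) && !is.data.frame(population) &&
      !is.null(population$records))
    population <- population$records
  elite <- population[isTRUE_vec(population$elite), , drop = FALSE]
  if (nrow(elite) == 0L)
    stop("population contains no elite members", call. = FALSE)
  set.seed(seed)
  death_age <- elite$death_date - elite$birth_date
  entry <- appointment_age_fn(nrow(elite))
  unresolved <- entry >= death_age
  if (selection == "redraw") {
    tries <- 1L
    while (any(unresolved) && tries < max_retries) {
      entry[unresolved] <- appointment_age_fn(sum(unresolved))
      unresolved <- entry >= death_age
      tries <- tries + 1L
    }
    if (any(unresolved) && strict)
      stop(sprintf(
        "appointment age exceeded death age for %d elite(s) after %d retries",
        sum(unresolved), max_retries), call. = FALSE)
  }
  keep <- !unresolved
  elite <- elite[keep, , drop = FALSE]
  entry <- entry[keep]
  roster <- data.frame(
    scholar_id = sub("^P", "S", elite$person_id),
    person_id = elite$person_id,
    birth_year = floor(elite$birth_date),
    birth_month = month_of_frac(elite$birth_date, elite$birth_precision),
    birth_place = elite$birth_place,
    death_year = floor(elite$death_date),
    death_month = month_of_frac(elite$death_date, elite$death_precision),
    death_place = elite$death_place,
    appointment_year = floor(elite$birth_date + entry),
    entry_age = entry,
    stringsAsFactors = FALSE)
  rownames(roster) <- NULL
  attr(roster, "n_dropped") <- sum(unresolved)
  roster
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Historical population-size point estimates from a synthetic population
#'
#' Counts persons alive (mid-year convention) at each requested year,
#' emulating the sparse historical population-size anchors that force
#' interpolation downstream.
#'
#' @param records Records data frame with exact or year-precision dates.
#' @param sample_years Years at which to count.
#' @return Data frame with columns `year` and `count`.
#' @export
generate_population_size_series <- function(records, sample_years) {
  records <- impute_exact_dates(records)
  counts <- vapply(sample_years, function(y)
    sum(records$birth_imp <= y + 0.5 & records$death_imp > y + 0.5,
        na.rm = TRUE), numeric(1))
  data.frame(year = sample_years, count = counts)
}

#' Write genealogy records as delimited text
#'
#' Dates are serialized as ISO-8601 dates (day precision), `YYYY-MM`
#' (month precision), or bare years; the layout round-trips losslessly
#' through [read_records()].
#'
#' @param records Records data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    person_id = records$person_id,
    sex = records$sex,
    birth_date = frac_to_date_string(records$birth_date,
                                     records$birth_precision),
    death_date = frac_to_date_string(records$death_date,
                                     records$death_precision),
    birth_place = records$birth_place,
    death_place = records$death_place,
    stringsAsFactors = FALSE)
  if (!is.null(records$elite)) out$elite <- records$elite
  if (!is.null(records$entry_age)) out$entry_age <- records$entry_age
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a scholar roster as delimited text
#' @param roster Roster data frame from [generate_scholar_roster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a population-size point series as delimited text
#' @param series Data frame with `year` and `count`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
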