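# Independent oracles and shared fixtures for the test suite.

# Textbook Cox-de Boor recursive B-spline evaluation; independent of
# splines::splineDesign (the implementation path).
cox_de_boor <- function(x, knots, degree, i) {
  if (degree == 0)
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  t1 <- if (d1 > 0)
    (x - knots[i]) / d1 * cox_de_boor(x, knots, degree - 1, i) else 0
  t2 <- if (d2 > 0)
    (knots[i + degree + 1] - x) / d2 *
      cox_de_boor(x, knots, degree - 1, i + 1) else 0
  t1 + t2
}

# Brute-force per-person, per-cell Lexis tabulation via the single-cell
# exposure primitive (the conservation/total oracle).
brute_force_lexis <- function(records, age_edges, period_edges,
                              use_entry_age = FALSE) {
  na <- length(age_edges) - 1L
  np <- length(period_edges) - 1L
  deaths <- matrix(0L, na, np)
  exposures <- matrix(0, na, np)
  for (r in seq_len(nrow(records))) {
    rec <- records[r, , drop = FALSE]
    entry <- if (use_entry_age && !is.null(rec$entry_age))
      rec$entry_age else NULL
    for (i in seq_len(na)) for (j in seq_len(np)) {
      exposures[i, j] <- exposures[i, j] + person_cell_exposure(
        rec, age_edges[i + 0:1], period_edges[j + 0:1], entry)
    }
    reci <- genlex:::impute_exact_dates(rec)
    aad <- reci$death_imp - reci$birth_imp
    ai <- findInterval(aad, age_edges)
    pj <- findInterval(reci$death_imp, period_edges)
    if (ai >= 1 && ai <= na && aad < age_edges[na + 1] &&
        pj >= 1 && pj <= np && reci$death_imp < period_edges[np + 1])
      deaths[ai, pj] <- deaths[ai, pj] + 1L
  }
  list(deaths = deaths, exposures = exposures)
}

# Minimal exact-date records data frame.
make_records <- function(birth, death, id = sprintf("P%04d",
                                                    seq_along(birth)),
                         place = "Bergheim", entry_age = NA_real_) {
  data.frame(person_id = id, sex = "male",
             birth_date = birth, birth_precision = "day",
             death_date = death, death_precision = "day",
             birth_place = place, death_place = place,
             entry_age = entry_age, stringsAsFactors = FALSE)
}

# Wrap deaths/exposure matrices as a lexis_grid (for synthetic surfaces).
make_grid <- function(age_edges, period_edges, deaths, exposures) {
  structure(list(age_edges = age_edges, period_edges = period_edges,
                 deaths = deaths, exposures = exposures,
                 truncated = FALSE),
            class = "lexis_grid")
}

# Sample-based Gini estimator (sorted-sample formula); the Monte Carlo
# oracle for the discrete double-sum Gini.
sample_gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  (2 * sum(seq_len(n) * x) - (n + 1) * sum(x)) / (n * sum(x))
}

# Draw remaining lifespans from an abridged life table's discrete
# death-age distribution, conditional on survival to `age`.
sample_remaining <- function(lt, age, n) {
  i <- match(age, lt$age)
  rows <- seq(i, nrow(lt))
  w <- lt$dx[rows] / lt$lx[i]
  r <- lt$age[rows] - age + lt$ax[rows]
  sample(r, n, replace = TRUE, prob = w)
}
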