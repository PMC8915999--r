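test_that("population interpolation is exponential between anchors", {
  pts <- data.frame(year = c(1700, 1800, 1850),
                    count = c(1000, 4000, 6000))
  expect_equal(interpolate_population(pts, c(1700, 1800, 1850))$count,
               c(1000, 4000, 6000), tolerance = 1e-12)
  expect_equal(interpolate_population(pts, 1750)$count, 2000)
  # per-segment exponential formula oracle
  yrs <- seq(1700, 1850, by = 7)
  got <- interpolate_population(pts, yrs)$count
  oracle <- vapply(yrs, function(y) {
    if (y <= 1800) 1000 * (4000 / 1000)^((y - 1700) / 100)
    else 4000 * (6000 / 4000)^((y - 1800) / 50)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(interpolate_population(pts, 1699), "xtrapolation")
  expect_error(interpolate_population(pts[1, , drop = FALSE], 1700),
               "two population anchors")
})

test_that("coverage of a fully included sample is one everywhere", {
  pop <- generate_population(3000, birth_year_range = c(1700, 1750),
                             seed = 61)
  s <- sample_genealogy(pop, ascertainment_model(base_inclusion = 1))
  yrs <- seq(1720, 1780, by = 5)
  truth_counts <- generate_population_size_series(pop$records, yrs)
  cov <- coverage_series(s$records,
                         data.frame(year = yrs,
                                    count = truth_counts$count))
  expect_true(all(cov$coverage == 1))
  expect_false(any(cov$anomaly))
  # alive counts equal a brute-force loop
  brute <- vapply(yrs, function(y)
    sum(s$records$birth_date <= y + 0.5 & s$records$death_date > y + 0.5),
    numeric(1))
  expect_identical(cov$n_alive_sample, brute)
})

test_that("uniform 10% inclusion yields 10% coverage within binomial error", {
  pop <- generate_population(50000, birth_year_range = c(1700, 1720),
                             elite_fraction = 0, seed = 62)
  s <- sample_genealogy(pop, ascertainment_model(base_inclusion = 0.1),
                        seed = 63)
  yrs <- seq(1725, 1760, by = 5)
  pop_counts <- generate_population_size_series(pop$records, yrs)
  cov <- coverage_series(s$records, pop_counts)
  se <- sqrt(0.1 * 0.9 / cov$population_size)
  expect_true(all(abs(cov$coverage - 0.1) < 4 * se))
  expect_lt(abs(mean(cov$coverage) - 0.1), 3 * mean(se))
})

test_that("exact twins match and absent twins stay unmatched", {
  pop <- generate_population(400, elite_fraction = 0.1, seed = 64)
  roster <- generate_scholar_roster(pop, seed = 65)
  m <- match_scholars(pop$records, roster)
  expect_identical(sort(m$genealogy_id), sort(roster$person_id))
  # a roster entry with no record within tolerance stays unmatched
  ghost <- roster[1, ]
  ghost$scholar_id <- "S_GHOST"
  ghost$birth_year <- 1400; ghost$death_year <- 1460
  m2 <- match_scholars(pop$records, rbind(roster, ghost))
  expect_true("S_GHOST" %in% attr(m2, "unmatched"))
})

test_that("linkage keeps precision and recall above 0.95 under date noise", {
  pop <- generate_population(8000, elite_fraction = 0.05, seed = 66)
  roster <- generate_scholar_roster(pop, seed = 67)
  s <- sample_genealogy(pop, ascertainment_model(
    base_inclusion = 0.6, missing_exact_date_rate = 0.2), seed = 68)
  # 1% of roster vital years corrupted by +/- 1 year
  set.seed(69)
  noisy <- roster
  flip <- runif(nrow(noisy)) < 0.01
  noisy$birth_year[flip] <- noisy$birth_year[flip] +
    sample(c(-1, 1), sum(flip), replace = TRUE)
  m <- match_scholars(s$records, noisy)
  truth_pairs <- paste(roster$scholar_id, roster$person_id)
  got_pairs <- paste(m$roster_id, m$genealogy_id)
  in_sample <- roster$person_id %in% s$records$person_id
  relevant <- truth_pairs[in_sample]
  precision <- mean(got_pairs %in% truth_pairs)
  recall <- sum(got_pairs %in% relevant) / length(relevant)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("matching is symmetric on synthetic twins", {
  pop <- generate_population(300, elite_fraction = 0.15, seed = 70)
  roster <- generate_scholar_roster(pop, seed = 71)
  fwd <- match_scholars(pop$records, roster)
  # swap roles: express the roster rows as records and the records as a
  # roster, then match again
  roster_as_records <- data.frame(
    person_id = roster$scholar_id, sex = "male",
    birth_date = roster$birth_year, birth_precision = "year",
    death_date = roster$death_year, death_precision = "year",
    birth_place = roster$birth_place, death_place = roster$death_place,
    stringsAsFactors = FALSE)
  rec <- pop$records[pop$records$person_id %in% roster$person_id, ]
  records_as_roster <- data.frame(
    scholar_id = rec$person_id,
    birth_year = floor(rec$birth_date),
    birth_month = NA_integer_,
    birth_place = rec$birth_place,
    death_year = floor(rec$death_date),
    death_month = NA_integer_,
    death_place = rec$death_place,
    stringsAsFactors = FALSE)
  rev <- match_scholars(roster_as_records, records_as_roster)
  expect_setequal(paste(fwd$roster_id, fwd$genealogy_id),
                  paste(rev$genealogy_id, rev$roster_id))
})

test_that("oversampling is one for equal shares and scale-invariant", {
  pop <- generate_population(20000, elite_fraction = 0.05,
                             birth_year_range = c(1700, 1720), seed = 72)
  roster <- generate_scholar_roster(pop, seed = 73)
  s <- sample_genealogy(pop, ascertainment_model(base_inclusion = 1))
  m <- match_scholars(s$records, roster)
  periods <- data.frame(period_lo = c(1740, 1750), period_hi = c(1750, 1760))
  sp <- periods
  roster_rec <- data.frame(person_id = roster$scholar_id,
                           birth_date = roster$birth_year,
                           birth_precision = "year",
                           death_date = roster$death_year,
                           death_precision = "year",
                           stringsAsFactors = FALSE)
  yrs <- seq(1720, 1790, 5)
  pop_pts <- generate_population_size_series(pop$records, yrs)
  sp$n_scholars <- vapply(seq_len(2), function(j)
    genlex:::alive_at_midyear(genlex:::impute_exact_dates(roster_rec),
                              (sp$period_lo[j] + sp$period_hi[j]) / 2),
    numeric(1))
  ov <- oversampling_series(s$records, m, sp, pop_pts, periods)
  # full inclusion + (near-)complete linkage: shares coincide up to the
  # few scholars dropped at roster generation
  expect_true(all(abs(ov$oversampling - 1) < 0.05))
})

test_that("coverage is invariant to jointly duplicating both sides", {
  pop <- generate_population(2000, birth_year_range = c(1700, 1730),
                             seed = 76)
  s <- sample_genealogy(pop, ascertainment_model(base_inclusion = 0.4),
                        seed = 77)
  yrs <- seq(1730, 1770, 10)
  pop_counts <- generate_population_size_series(pop$records, yrs)
  cov1 <- coverage_series(s$records, pop_counts)
  doubled <- rbind(s$records, transform(s$records,
                                        person_id = paste0(person_id, "b")))
  pop2 <- pop_counts; pop2$count <- pop2$count * 2
  cov2 <- coverage_series(doubled, pop2)
  expect_equal(cov2$coverage, cov1$coverage, tolerance = 1e-12)
})

test_that("uniform sampling leaves elites unenriched at scale", {
  pop <- generate_population(1e5, elite_fraction = 0.05,
                             birth_year_range = c(1700, 1720), seed = 74)
  s <- sample_genealogy(pop, ascertainment_model(base_inclusion = 0.3),
                        seed = 75)
  elite_ids <- pop$truth$scholar_ids
  share_sample <- mean(s$records$person_id %in% elite_ids)
  share_pop <- length(elite_ids) / 1e5
  ov <- share_sample / share_pop
  se <- sqrt((1 - share_pop) / (share_pop * nrow(s$records)))
  expect_lt(abs(ov - 1), 3 * se)
})

test_that("resemblance correlation matches hand-checked extremes", {
  e30_elite <- c(40, 40, 40)
  e30_sample <- c(37, 38, 39)       # resemblance -3, -2, -1
  expect_equal(resemblance_correlation(e30_sample, e30_elite,
                                       driver = c(3, 2, 1)), -1)
  expect_equal(resemblance_correlation(e30_sample, e30_elite,
                                       driver = c(-3, -2, -1)), 1)
  expect_warning(
    got <- resemblance_correlation(c(40, 40, 40), e30_elite,
                                   driver = c(1, 2, 3)),
    "zero variance")
  expect_true(is.na(got))
  expect_error(resemblance_correlation(c(1, 2), c(1, 2), c(1, 2)),
               "3 aligned periods")
})
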