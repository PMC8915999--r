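fixture_path <- function() {
  system.file("extdata", "cleaning_fixture_synthetic.csv",
              package = "genlex")
}

test_that("well-formed files parse with no rejects", {
  got <- read_records(fixture_path())
  expect_identical(nrow(got$records), 10L)
  expect_identical(nrow(got$rejects), 0L)
  expect_true(all(got$records$birth_precision == "day"))
})

test_that("defective rows are routed to rejects with a reason", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,sex,birth_date,death_date,birth_place,death_place",
               "A1,male,1700-01-05,1650-01-05,Celle,Celle",
               "A2,male,17xx,1720-01-05,Celle,Celle",
               "A3,male,1700-02-02,1766-03-03,Celle,Celle"), f)
  got <- read_records(f)
  expect_identical(got$records$person_id, "A3")
  expect_setequal(got$rejects$reason,
                  c("death precedes birth", "unparseable birth date"))
  # schema / empty-file error contracts
  expect_error(read_records(f, schema = c(person_id = "person_id")),
               "mandatory")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("person_id,sex,birth_date,death_date,birth_place,death_place",
             empty)
  expect_error(read_records(empty), "empty")
})

test_that("records written by the generator round-trip losslessly", {
  pop <- generate_population(200, seed = 21)
  s <- sample_genealogy(pop, ascertainment_model(
    base_inclusion = 1, missing_exact_date_rate = 0.3), seed = 22)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(s$records, f1)
  back <- read_records(f1)
  expect_identical(nrow(back$rejects), 0L)
  write_records(back$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("territory membership uses birth OR death place", {
  rec <- data.frame(
    person_id = c("a", "b", "c", "d"),
    sex = "male",
    birth_date = 1700, birth_precision = "day",
    death_date = 1760, death_precision = "day",
    birth_place = c("Bergheim", "Paris", NA, NA),
    death_place = c("Paris", "Bergheim", NA, "Paris"),
    stringsAsFactors = FALSE)
  rule <- territory_rule(places = "Bergheim")
  expect_identical(assign_territory(rec, rule),
                   c(TRUE, TRUE, FALSE, FALSE))
  # a predicate matching everything keeps all records with >= 1 place
  all_rule <- territory_rule(pattern = ".")
  expect_identical(assign_territory(rec, all_rule),
                   c(TRUE, TRUE, FALSE, TRUE))
})

test_that("the packaged 10-record fixture cleans to exactly 6 survivors", {
  recs <- read_records(fixture_path())$records
  got <- clean_records(recs)
  expect_identical(nrow(got$records), 6L)
  expect_setequal(got$records$person_id,
                  c("P01", "P03", "P07", "P08", "P09", "P10"))
  rep <- got$report
  expect_identical(rep$n_removed[rep$stage == "duplicates"], 2L)
  expect_identical(rep$n_removed[rep$stage == "age_above_max"], 1L)
  expect_identical(rep$n_removed[rep$stage == "period"], 1L)
  # full reconciliation: counts chain from input to output
  expect_identical(attr(rep, "n_input") - cumsum(rep$n_removed),
                   rep$n_remaining)
})

test_that("cleaning is idempotent and order-invariant", {
  pop <- generate_population(1500, seed = 23)
  s <- sample_genealogy(pop, ascertainment_model(
    base_inclusion = 0.8, duplicate_rate = 0.1, age_error_rate = 0.05,
    missing_exact_date_rate = 0.2), seed = 24)
  once <- clean_records(s$records)
  twice <- clean_records(once$records)
  expect_identical(once$records, twice$records)
  expect_true(all(twice$report$n_removed == 0L))
  # permuting rows changes neither the survivor set nor the report
  set.seed(25)
  perm <- s$records[sample(nrow(s$records)), ]
  got <- clean_records(perm)
  expect_setequal(got$records$person_id, once$records$person_id)
  expect_identical(as.data.frame(got$report),
                   as.data.frame(once$report))
})

test_that("report arithmetic reconciles on random defective inputs", {
  for (seed in 26:28) {
    pop <- generate_population(800, seed = seed)
    s <- sample_genealogy(pop, ascertainment_model(
      base_inclusion = 0.7, duplicate_rate = 0.08,
      age_error_rate = 0.04, missing_exact_date_rate = 0.25),
      seed = seed + 100)
    got <- clean_records(s$records, drop_inexact_dates = TRUE)
    rep <- got$report
    expect_identical(attr(rep, "n_input") - cumsum(rep$n_removed),
                     rep$n_remaining)
    expect_identical(rep$n_remaining[nrow(rep)], nrow(got$records))
    # age cap removed every injected transcription error that survived
    ages <- got$records$death_date - got$records$birth_date
    expect_true(all(ages <= 100))
  }
})
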