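#' Declarative configuration for the full analysis pipeline
#'
#' Collects every input path (or in-memory object), threshold, grid
#' specification, and seed for one reproducible pipeline run.  All
#' randomness flows from the single `seed`; per-stage substreams are
#' derived from it and named in the manifest.
#'
#' @param records Path to a records file (read via [read_records()]) or
#'   a records data frame.
#' @param roster Optional scholar roster (path or data frame); when
#'   absent, matching and oversampling outputs are disabled with a
#'   notice.
#' @param population_points Optional population-size anchors (path or
#'   data frame with `year`, `count`).
#' @param territory Optional territory predicate from [territory_rule()].
#' @param max_age,last_year,sex,drop_inexact_dates Cleaning thresholds,
#'   see [clean_records()].
#' @param right_censoring Robustness variant: deathless records
#'   contribute exposure up to `last_year`.
#' @param age_edges Life-table age-group edges (default 5-y groups 30-80
#'   with the open interval closed at 100).
#' @param fine_age_width Age cell width in years for the smoothing grid.
#' @param period_edges Calendar-period edges for tables and CIs.
#' @param spline A [pspline_spec()].
#' @param lambda_grid Optional lambda candidates for [select_lambdas()];
#'   NULL fits at the spec's lambdas.
#' @param smooth Use P-spline smoothed rates for the life tables
#'   (default TRUE); FALSE uses raw rates.
#' @param n_sims Monte Carlo replicates per period (default 1000).
#' @param seed Root seed.
#' @param out_dir Output directory for the run artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(records, roster = NULL, population_points = NULL,
                       territory = NULL, max_age = 100, last_year = 1910,
                       sex = "male", drop_inexact_dates = FALSE,
                       right_censoring = FALSE,
                       age_edges = c(seq(30, 80, by = 5), 100),
                       fine_age_width = 1,
                       period_edges = seq(1600, 1910, by = 10),
                       spline = pspline_spec(), lambda_grid = NULL,
                       smooth = TRUE, n_sims = 1000, seed = 1,
                       out_dir = tempfile("genlex_run_")) {
  structure(list(records = records, roster = roster,
                 population_points = population_points,
                 territory = territory, max_age = max_age,
                 last_year = last_year, sex = sex,
                 drop_inexact_dates = drop_inexact_dates,
                 right_censoring = right_censoring,
                 age_edges = age_edges, fine_age_width = fine_age_width,
                 period_edges = period_edges, spline = spline,
                 lambda_grid = lambda_grid, smooth = smooth,
                 n_sims = n_sims, seed = seed, out_dir = out_dir),
            class = "run_config")
}

config_echo <- function(config) {
  flat <- function(x) paste(format(x, digits = 15), collapse = " ")
  c(sprintf("max_age: %s", flat(config$max_age)),
    sprintf("last_year: %s", flat(config$last_year)),
    sprintf("sex: %s", flat(config$sex)),
    sprintf("drop_inexact_dates: %s", flat(config$drop_inexact_dates)),
    sprintf("right_censoring: %s", flat(config$right_censoring)),
    sprintf("age_edges: %s", flat(config$age_edges)),
    sprintf("fine_age_width: %s", flat(config$fine_age_width)),
    sprintf("period_edges: %s", flat(config$period_edges)),
    sprintf("spline_degree: %s", flat(config$spline$spline_degree)),
    sprintf("knot_spacing_age: %s", flat(config$spline$knot_spacing_age)),
    sprintf("knot_spacing_period: %s",
            flat(config$spline$knot_spacing_period)),
    sprintf("penalty_order: %s", flat(config$spline$penalty_order)),
    sprintf("lambda_age: %s", flat(config$spline$lambda_age)),
    sprintf("lambda_period: %s", flat(config$spline$lambda_period)),
    sprintf("lambda_grid: %s",
            if (is.null(config$lambda_grid)) "none"
            else flat(config$lambda_grid)),
    sprintf("smooth: %s", flat(config$smooth)),
    sprintf("n_sims: %s", flat(config$n_sims)),
    sprintf("seed: %s", flat(config$seed)))
}

#' Run the full pipeline: clean, tabulate, smooth, life tables, CIs,
#' representativeness
#'
#' Orchestrates the whole analysis from a single [run_config()]: reads
#' and territory-filters the records, applies the cleaning rules with an
#' auditable report, tabulates the Lexis grids (sample, and — when a
#' roster is supplied — elite grids with and without left truncation),
#' smooths the death-rate surface with 2D P-splines, builds per-period
#' abridged life tables with e30 and Gini, attaches binomial Monte Carlo
#' confidence intervals, computes the representativeness diagnostics,
#' and writes every artifact as delimited text together with a manifest
#' of MD5 checksums (two runs with identical config and seed produce
#' identical manifests).  Any stage failure aborts with the stage name
#' after writing a partial manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts
#'   (`cleaning_report`, `grid_fine`, `grid_coarse`, `surface`,
#'   `lifetables`, `ci`, `matches`, `representativeness`, `notices`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  stage <- "init"
  art <- list()
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
  }
  abort <- function(e) {
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)))
    utils::write.csv(manifest,
                     file.path(config$out_dir, "manifest_partial.csv"),
                     row.names = FALSE, quote = FALSE)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  tryCatch({
    stage <- "ingest"
    records <- config$records
    if (is.character(records)) records <- read_records(records)$records
    roster <- config$roster
    if (is.character(roster) && !is.null(roster))
      roster <- utils::read.csv(roster, stringsAsFactors = FALSE)
    pop_points <- config$population_points
    if (is.character(pop_points) && !is.null(pop_points))
      pop_points <- utils::read.csv(pop_points, stringsAsFactors = FALSE)

    stage <- "clean"
    cleaned <- clean_records(records, max_age = config$max_age,
                             last_year = config$last_year,
                             sex = config$sex,
                             drop_inexact_dates = config$drop_inexact_dates,
                             rule = config$territory)
    art$cleaning_report <- cleaned$report
    emit("cleaning_report.csv",
         function(p) write_cleaning_report(cleaned$report, p))
    sample_records <- cleaned$records

    stage <- "lexis"
    lo <- min(config$age_edges); hi <- max(config$age_edges)
    fine_ages <- seq(lo, hi, by = config$fine_age_width)
    if (utils::tail(fine_ages, 1) < hi) fine_ages <- c(fine_ages, hi)
    rc_year <- if (config$right_censoring) config$last_year else NULL
    grid_fine <- tabulate_lexis(sample_records, age_edges = fine_ages,
                                period_edges = config$period_edges,
                                right_censor_year = rc_year)
    grid_coarse <- aggregate_lexis(grid_fine,
                                   age_edges = config$age_edges)
    art$grid_fine <- grid_fine
    art$grid_coarse <- grid_coarse
    emit("lexis_sample.csv",
         function(p) write_lexis_grid(grid_coarse, p))

    stage <- "smoothing"
    surface <- NULL
    if (config$smooth) {
      spec <- config$spline
      if (!is.null(config$lambda_grid))
        spec <- select_lambdas(grid_fine, spec, config$lambda_grid)
      surface <- fit_psplines_2d(grid_fine, spec)
      art$surface <- surface
      emit("hazard_surface.csv",
           function(p) write_hazard_surface(surface, p))
    }

    stage <- "lifetable"
    np <- length(config$period_edges) - 1L
    lts <- vector("list", np)
    period_labels <- character(np)
    for (j in seq_len(np)) {
      period <- config$period_edges[j + 0:1]
      period_labels[j] <- sprintf("%d-%d", period[1], period[2])
      lts[[j]] <- tryCatch({
        mx <- if (config$smooth)
          surface_to_mx(surface, config$age_edges, period)
        else {
          agg <- aggregate_lexis(grid_coarse, period = period)
          as.numeric(agg$deaths) / pmax(as.numeric(agg$exposures), 1e-12)
        }
        mx_to_lifetable(mx, age_edges = config$age_edges)
      }, error = function(e) NULL)
    }
    have_lt <- !vapply(lts, is.null, logical(1))
    lt_stack <- do.call(rbind, lapply(which(have_lt), function(j)
      cbind(period = period_labels[j], as.data.frame(lts[[j]]))))
    art$lifetables <- lts
    names(art$lifetables) <- period_labels
    if (!is.null(lt_stack))
      emit("lifetables.csv",
           function(p) utils::write.csv(lt_stack, p, row.names = FALSE,
                                        quote = FALSE))

    stage <- "uncertainty"
    cis <- list()
    for (j in which(have_lt)) {
      period <- config$period_edges[j + 0:1]
      ci <- tryCatch(
        resample_lifetables(grid_coarse, age_edges = config$age_edges,
                            period = period, n_sims = config$n_sims,
                            seed = config$seed + j),
        error = function(e) NULL)
      if (!is.null(ci)) cis[[period_labels[j]]] <- ci
    }
    art$ci <- cis
    if (length(cis))
      emit("ci_estimates.csv",
           function(p) utils::write.csv(ci_table(cis), p,
                                        row.names = FALSE, quote = FALSE))

    stage <- "representativeness"
    if (!is.null(pop_points)) {
      span <- pop_points$year[pop_points$year >= min(pop_points$year) &
                                pop_points$year <= max(pop_points$year)]
      years <- seq(min(pop_points$year), max(pop_points$year))
      pop_interp <- interpolate_population(pop_points, years)
      cov <- coverage_series(sample_records, pop_interp)
      art$coverage <- cov
      emit("coverage.csv",
           function(p) utils::write.csv(cov, p, row.names = FALSE,
                                        quote = FALSE))
    } else {
      notices <- c(notices,
                   "population_points not provided - coverage output disabled")
    }
    if (!is.null(roster)) {
      matches <- match_scholars(sample_records, roster)
      art$matches <- matches
      emit("matches.csv",
           function(p) utils::write.csv(as.data.frame(matches), p,
                                        row.names = FALSE, quote = TRUE))
      scholar_records <- merge(
        sample_records,
        data.frame(person_id = matches$genealogy_id,
                   roster_id = matches$roster_id,
                   stringsAsFactors = FALSE),
        by = "person_id")
      ra <- roster$appointment_year - roster$birth_year
      scholar_records$entry_age <-
        ra[match(scholar_records$roster_id, roster$scholar_id)]
      # year-rounded appointment ages can nominally exceed an imputed
      # death age; clamp (zero post-entry exposure) rather than abort
      simp <- impute_exact_dates(scholar_records)
      over <- !is.na(simp$entry_age) &
        simp$entry_age > simp$death_imp - simp$birth_imp
      if (any(over)) {
        scholar_records$entry_age[over] <-
          (simp$death_imp - simp$birth_imp)[over]
        notices <- c(notices, sprintf(
          "%d scholar record(s) had appointment-year entry past the death age; entry clamped",
          sum(over)))
      }
      if (nrow(scholar_records) > 0) {
        glt <- function(use_lt) {
          g <- tabulate_lexis(scholar_records,
                              age_edges = config$age_edges,
                              period_edges = config$period_edges,
                              use_entry_age = use_lt)
          vapply(seq_len(np), function(j) {
            lt <- tryCatch(
              lexis_to_lifetable(g, period = config$period_edges[j + 0:1]),
              error = function(e) NULL)
            if (is.null(lt)) NA_real_ else remaining_e(lt, 30)
          }, numeric(1))
        }
        e30_schol_wlt <- glt(TRUE)
        e30_schol_wolt <- glt(FALSE)
        e30_sample <- vapply(seq_len(np), function(j)
          if (have_lt[j]) remaining_e(lts[[j]], 30) else NA_real_,
          numeric(1))
        rep_tab <- data.frame(period = period_labels,
                              e30_sample = e30_sample,
                              e30_scholars_wLT = e30_schol_wlt,
                              e30_scholars_woLT = e30_schol_wolt)
        if (!is.null(pop_points)) {
          sp <- data.frame(
            period_lo = config$period_edges[-(np + 1L)],
            period_hi = config$period_edges[-1L])
          roster_rec <- data.frame(
            person_id = roster$scholar_id,
            birth_date = roster$birth_year,
            birth_precision = "year",
            death_date = roster$death_year,
            death_precision = "year",
            stringsAsFactors = FALSE)
          roster_imp <- impute_exact_dates(roster_rec)
          sp$n_scholars <- vapply(seq_len(np), function(j)
            alive_at_midyear(roster_imp,
                             (sp$period_lo[j] + sp$period_hi[j]) / 2),
            numeric(1))
          ov <- oversampling_series(sample_records, matches, sp,
                                    pop_points)
          art$oversampling <- ov
          emit("oversampling.csv",
               function(p) utils::write.csv(ov, p, row.names = FALSE,
                                            quote = FALSE))
          cov_period <- vapply(seq_len(np), function(j) {
            mid <- mean(config$period_edges[j + 0:1])
            art$coverage$coverage[match(round(mid),
                                        art$coverage$year)]
          }, numeric(1))
          rep_tab$coverage <- cov_period
          rep_tab$oversampling <- ov$oversampling
          ok <- stats::complete.cases(rep_tab[, c("e30_sample",
                                                  "e30_scholars_woLT")])
          if (sum(ok) >= 3) {
            rep_tab_ok <- rep_tab[ok, , drop = FALSE]
            art$corr_coverage <- resemblance_correlation(
              rep_tab_ok$e30_sample, rep_tab_ok$e30_scholars_woLT,
              rep_tab_ok$coverage)
            art$corr_oversampling <- resemblance_correlation(
              rep_tab_ok$e30_sample, rep_tab_ok$e30_scholars_woLT,
              rep_tab_ok$oversampling)
          }
        }
        art$representativeness <- rep_tab
        emit("representativeness.csv",
             function(p) utils::write.csv(rep_tab, p, row.names = FALSE,
                                          quote = FALSE))
      }
    } else {
      notices <- c(notices,
                   "roster not provided - matching and oversampling outputs disabled")
    }

    stage <- "manifest"
    emit("config.txt",
         function(p) writeLines(config_echo(config), p))
    if (length(notices))
      emit("notices.txt", function(p) writeLines(notices, p))
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    rownames(manifest) <- NULL
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    art$manifest <- manifest
    art$notices <- notices
  }, error = abort)
  invisible(art)
}
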