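#' Monte Carlo confidence intervals by binomial resampling of deaths
#'
#' Death counts are assumed binomial within each age group: from the
#' point life table's death probabilities \eqn{\hat q_x}, per-group trial
#' counts are reconstructed as \eqn{N_x = \max(\mathrm{round}(D_x /
#' \hat q_x),\; D_x)} (which reproduces the point estimate in
#' expectation), replicate death counts \eqn{D^*_x \sim
#' \mathrm{Binomial}(N_x, \hat q_x)} are drawn, and the life table is
#' rebuilt for every replicate; e30 and the Gini coefficient of remaining
#' lifespan are recorded.  The terminal open group has \eqn{q = 1}
#' identically, so replicates keep the point estimate's terminal rate.
#' Intervals are the 2.5th/97.5th percentiles of the replicates.
#'
#' @param grid Either a `lexis_grid` (collapsed over `period`) or a
#'   numeric vector of age-group death counts.
#' @param exposures Age-group person-years (required when `grid` is a
#'   vector of counts).
#' @param age_edges Age-group edges (default 5-y groups, 80+ closed at
#'   100).
#' @param period Optional calendar interval to collapse a `lexis_grid`
#'   over.
#' @param n_sims Number of Monte Carlo replicates (default 1000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param pipeline Function mapping a replicate's `qx` vector to an
#'   `abridged_lifetable`.  The default rebuilds the table by inverting
#'   the qx-mx relation with the point estimate's ax and terminal mx.
#' @param age Conditioning age for e30/Gini (default 30).
#' @return A list of class `ci_pair` with elements `e30` and `gini`,
#'   each a `ci_estimate` (point, mean_of_sims, lower95, upper95,
#'   n_sims, seed), plus the point life table.
#' @export
resample_lifetables <- function(grid, exposures = NULL,
                                age_edges = c(seq(30, 80, 5), 100),
                                period = NULL, n_sims = 1000, seed = 1,
                                pipeline = NULL, age = 30) {
  if (inherits(grid, "lexis_grid")) {
    agg <- aggregate_lexis(grid,
                           age_edges = if (identical(grid$age_edges,
                                                     age_edges)) NULL
                           else age_edges,
                           period = if (is.null(period))
                             range(grid$period_edges) else period)
    deaths <- as.numeric(agg$deaths)
    exposures <- as.numeric(agg$exposures)
    age_edges <- agg$age_edges
  } else {
    deaths <- as.numeric(grid)
    if (is.null(exposures))
      stop("exposures required when passing raw death counts",
           call. = FALSE)
  }
  k <- length(deaths)
  stopifnot(length(exposures) == k, length(age_edges) == k + 1L)
  if (any(exposures <= 0))
    stop("zero exposure in age group(s) ",
         paste(age_edges[-(k + 1L)][exposures <= 0], collapse = ", "),
         call. = FALSE)
  mx_hat <- deaths / exposures
  lt0 <- mx_to_lifetable(mx_hat, age_edges = age_edges)
  qx_hat <- lt0$qx
  n <- lt0$n
  ax <- lt0$ax

  # q = 0 groups carry no death information; their trial count falls back
  # to the approximate person count entering the group (exposure / width)
  Nx <- ifelse(qx_hat > 0, pmax(round(deaths / qx_hat), deaths),
               round(exposures / n))
  interior <- seq_len(k - 1L)
  if (any(Nx[interior] == 0))
    stop("zero binomial trial count in age group(s) ",
         paste(age_edges[interior][Nx[interior] == 0], collapse = ", "),
         call. = FALSE)

  if (is.null(pipeline)) {
    pipeline <- function(qstar) {
      m <- qstar / (n - (n - ax) * qstar)
      m[k] <- mx_hat[k]
      mx_to_lifetable(m, age_edges = age_edges, ax = ax)
    }
  }

  set.seed(seed)
  e30s <- numeric(n_sims)
  ginis <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    dstar <- stats::rbinom(k - 1L, Nx[interior], qx_hat[interior])
    qstar <- c(dstar / Nx[interior], 1)
    lt <- pipeline(qstar)
    e30s[s] <- remaining_e(lt, age)
    ginis[s] <- gini_remaining(lt, age)
  }
  mk <- function(point, sims) {
    structure(list(point = point, mean_of_sims = mean(sims),
                   lower95 = unname(stats::quantile(sims, 0.025)),
                   upper95 = unname(stats::quantile(sims, 0.975)),
                   n_sims = n_sims, seed = seed, sims = sims),
              class = "ci_estimate")
  }
  structure(list(e30 = mk(remaining_e(lt0, age), e30s),
                 gini = mk(gini_remaining(lt0, age), ginis),
                 lifetable = lt0),
            class = "ci_pair")
}

#' @export
print.ci_estimate <- function(x, ...) {
  cat(sprintf("<ci_estimate> point %.4f, sims mean %.4f, 95%% CI [%.4f, %.4f] (%d replicates)\n",
              x$point, x$mean_of_sims, x$lower95, x$upper95, x$n_sims))
  invisible(x)
}

#' Flatten CI estimates to a table
#'
#' @param ci_list Named list of `ci_pair` objects (e.g. one per period).
#' @return Data frame with columns `period`, `measure`, `point`, `mean`,
#'   `lower95`, `upper95`, `n_sims`, `seed` — the data behind
#'   ribbon-style uncertainty plots.
#' @export
ci_table <- function(ci_list) {
  rows <- lapply(names(ci_list), function(nm) {
    p <- ci_list[[nm]]
    do.call(rbind, lapply(c("e30", "gini"), function(meas) {
      ci <- p[[meas]]
      data.frame(period = nm, measure = meas, point = ci$point,
                 mean = ci$mean_of_sims, lower95 = ci$lower95,
                 upper95 = ci$upper95, n_sims = ci$n_sims,
                 seed = ci$seed, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
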