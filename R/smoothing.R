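#' P-spline smoothing specification
#'
#' Settings for two-dimensional P-spline smoothing of the death-rate
#' surface: equally spaced B-spline bases in age and calendar time with
#' difference penalties on the coefficients.  Defaults follow standard
#' mortality-smoothing practice: cubic splines, knots every 5 years in
#' age and 10 years in period, second-order penalties.
#'
#' @param spline_degree B-spline degree (default 3, cubic).
#' @param knot_spacing_age Knot spacing in years of age (default 5).
#' @param knot_spacing_period Knot spacing in calendar years (default 10).
#' @param penalty_order Order of the difference penalty (default 2; its
#'   null space is then affine, so the infinite-smoothing limit is a
#'   plane in log-rate).
#' @param lambda_age Non-negative smoothing weight in the age direction.
#' @param lambda_period Non-negative smoothing weight in the period
#'   direction.
#' @return An object of class `pspline_spec`.
#' @export
pspline_spec <- function(spline_degree = 3, knot_spacing_age = 5,
                         knot_spacing_period = 10, penalty_order = 2,
                         lambda_age = 100, lambda_period = 100) {
  stopifnot(spline_degree >= 0, knot_spacing_age > 0,
            knot_spacing_period > 0, penalty_order >= 1,
            lambda_age >= 0, lambda_period >= 0)
  structure(list(spline_degree = spline_degree,
                 knot_spacing_age = knot_spacing_age,
                 knot_spacing_period = knot_spacing_period,
                 penalty_order = penalty_order,
                 lambda_age = lambda_age, lambda_period = lambda_period),
            class = "pspline_spec")
}

#' Equally spaced B-spline basis
#'
#' Evaluates an equally spaced B-spline basis (knots extended beyond the
#' data range) at the given grid points.  Rows sum to one (partition of
#' unity).
#'
#' @param grid Strictly increasing evaluation points.
#' @param spacing Knot spacing (> 0), in the units of `grid`.
#' @param degree Spline degree (0 gives an indicator basis).
#' @param penalty_order Used only to verify that enough basis functions
#'   exist to support a difference penalty of this order.
#' @return Matrix with `length(grid)` rows, one column per basis function.
#' @export
bspline_basis <- function(grid, spacing, degree = 3, penalty_order = 2) {
  stopifnot(all(diff(grid) > 0), spacing > 0, degree >= 0)
  lo <- min(grid); hi <- max(grid)
  inner <- seq(lo, hi + spacing * 0.9999, by = spacing)
  knots <- c(lo - spacing * (degree:1), inner,
             utils::tail(inner, 1) + spacing * (1:(degree + 1)))
  if (degree == 0) knots <- inner_knots0(lo, hi, spacing)
  nb <- length(knots) - degree - 1L
  if (nb < penalty_order + 1L)
    stop("fewer basis functions (", nb, ") than penalty_order + 1",
         call. = FALSE)
  B <- splines::splineDesign(knots, grid, ord = degree + 1L,
                             outer.ok = TRUE)
  attr(B, "knots") <- knots
  B
}

inner_knots0 <- function(lo, hi, spacing) {
  k <- seq(lo, hi + spacing * 0.9999, by = spacing)
  if (utils::tail(k, 1) <= hi) k <- c(k, utils::tail(k, 1) + spacing)
  k
}

diff_penalty <- function(nb, order) {
  D <- diff(diag(nb), differences = order)
  crossprod(D)
}

#' Fit a two-dimensional P-spline hazard surface
#'
#' Maximizes the penalized Poisson log-likelihood
#' \deqn{D_{ij} \sim \mathrm{Poisson}\left(E_{ij}\, e^{(B_p \otimes B_a)\theta}\right)}
#' over a Lexis grid of death counts \eqn{D} and person-year exposures
#' \eqn{E}, with Kronecker-product B-spline bases and difference
#' penalties of the configured order in each dimension, via penalized
#' iteratively reweighted least squares with step-halving (the penalized
#' log-likelihood is non-decreasing across iterations).  Cells with zero
#' exposure get zero weight; their fitted values are pure penalty
#' interpolation.  A ridge floor of 1e-6 stabilizes the normal
#' equations.
#'
#' @param grid A `lexis_grid` (typically at fine, e.g. 1-year, cells).
#' @param spec A [pspline_spec()].
#' @return An object of class `hazard_surface`: grid midpoints
#'   `age_grid` / `period_grid`, the fitted `log_rate` matrix, the
#'   exposures, `effective_dimension` (trace of the hat matrix),
#'   `deviance`, `bic`, `converged`, the iteration trace of the
#'   penalized log-likelihood, and the spec.
#' @export
fit_psplines_2d <- function(grid, spec = pspline_spec()) {
  stopifnot(inherits(grid, "lexis_grid"), inherits(spec, "pspline_spec"))
  D <- as.numeric(grid$deaths)
  E <- as.numeric(grid$exposures)
  if (all(E == 0)) stop("all exposures are zero", call. = FALSE)
  if (sum(D) > sum(E) * 2 + 10)
    stop("death counts implausibly exceed exposures", call. = FALSE)
  am <- (grid$age_edges[-1] + grid$age_edges[-length(grid$age_edges)]) / 2
  pm <- (grid$period_edges[-1] +
           grid$period_edges[-length(grid$period_edges)]) / 2
  Ba <- bspline_basis(am, spec$knot_spacing_age, spec$spline_degree,
                      spec$penalty_order)
  Bp <- if (length(pm) > 1L)
    bspline_basis(pm, spec$knot_spacing_period, spec$spline_degree,
                  spec$penalty_order)
  else matrix(1, 1, 1)
  ka <- ncol(Ba); kp <- ncol(Bp)
  B <- kronecker(Bp, Ba)                       # cells ordered age-fastest
  Pa <- diff_penalty(ka, min(spec$penalty_order, ka - 1L))
  Pp <- if (kp > 1L) diff_penalty(kp, min(spec$penalty_order, kp - 1L))
  else matrix(0, 1, 1)
  P <- spec$lambda_age * kronecker(diag(kp), Pa) +
    spec$lambda_period * kronecker(Pp, diag(ka))
  ridge <- diag(1e-6, ka * kp)

  pos <- E > 0
  off <- ifelse(pos, log(pmax(E, 1e-12)), 0)
  eta0 <- log((D + 0.5) / (E + 1))
  # initialize coefficients by penalized least squares on the crude rates
  A0 <- crossprod(B[pos, , drop = FALSE]) + P + ridge
  theta <- solve(A0, crossprod(B[pos, , drop = FALSE], eta0[pos]))

  pen_ll <- function(theta) {
    eta <- drop(B %*% theta)
    mu <- E * exp(eta)
    sum((D * (off + eta) - mu)[pos]) - 0.5 * drop(crossprod(theta, P %*% theta))
  }
  ll_trace <- pen_ll(theta)
  converged <- FALSE
  for (it in seq_len(200L)) {
    eta <- drop(B %*% theta)
    mu <- E * exp(eta)
    w <- ifelse(pos, mu, 0)
    z <- eta + ifelse(pos & mu > 0, (D - mu) / pmax(mu, 1e-12), 0)
    BW <- B * w
    A <- crossprod(BW, B) + P + ridge
    theta_new <- solve(A, crossprod(BW, z))
    step <- theta_new - theta
    ll_old <- ll_trace[length(ll_trace)]
    h <- 1
    repeat {
      cand <- theta + h * step
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      h <- h / 2
      if (h < 1e-8) { cand <- theta; ll_new <- ll_old; break }
    }
    delta <- max(abs(cand - theta))
    theta <- cand
    ll_trace <- c(ll_trace, ll_new)
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  eta <- drop(B %*% theta)
  mu <- E * exp(eta)
  w <- ifelse(pos, mu, 0)
  BW <- B * w
  BtWB <- crossprod(BW, B)
  A <- BtWB + P + ridge
  ed <- sum(diag(solve(A, BtWB)))
  dev_terms <- ifelse(D > 0, D * log(D / pmax(mu, 1e-300)), 0) - (D - mu)
  deviance <- 2 * sum(dev_terms[pos])
  bic <- deviance + log(sum(pos)) * ed
  structure(list(age_grid = am, period_grid = pm,
                 log_rate = matrix(eta, length(am), length(pm)),
                 exposures = grid$exposures,
                 effective_dimension = ed, deviance = deviance,
                 bic = bic, converged = converged,
                 loglik_trace = ll_trace, spec = spec,
                 n_iter = length(ll_trace) - 1L),
            class = "hazard_surface")
}

#' @export
print.hazard_surface <- function(x, ...) {
  cat(sprintf(
    "<hazard_surface> %d x %d grid; ED = %.1f, BIC = %.1f, %sconverged in %d iteration(s)\n",
    length(x$age_grid), length(x$period_grid), x$effective_dimension,
    x$bic, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Select smoothing weights by BIC grid search
#'
#' Fits the surface at every (lambda_age, lambda_period) pair of the
#' grid and returns the spec minimizing
#' `BIC = deviance + log(n positive-exposure cells) * effective dimension`.
#' Ties are broken toward larger (smoother) lambdas; non-converged fits
#' are excluded.
#'
#' @param grid A `lexis_grid`.
#' @param spec A [pspline_spec()] providing all non-lambda settings.
#' @param lambda_grid Numeric vector of candidate lambda values; all
#'   pairs are searched.  A two-column matrix/data frame of explicit
#'   pairs is also accepted.
#' @return The input spec with the selected lambdas; attributes
#'   `bic_table` (all candidates) are attached.
#' @export
select_lambdas <- function(grid, spec = pspline_spec(), lambda_grid) {
  if (is.null(dim(lambda_grid)))
    cand <- expand.grid(lambda_age = lambda_grid,
                        lambda_period = lambda_grid)
  else cand <- as.data.frame(lambda_grid)[, 1:2]
  names(cand) <- c("lambda_age", "lambda_period")
  if (nrow(cand) == 0L) stop("empty lambda grid", call. = FALSE)
  cand$bic <- NA_real_
  cand$converged <- FALSE
  for (i in seq_len(nrow(cand))) {
    s <- spec
    s$lambda_age <- cand$lambda_age[i]
    s$lambda_period <- cand$lambda_period[i]
    fit <- fit_psplines_2d(grid, s)
    cand$bic[i] <- fit$bic
    cand$converged[i] <- fit$converged
  }
  ok <- cand[cand$converged, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no converged candidate in the lambda grid", call. = FALSE)
  best_bic <- min(ok$bic)
  ties <- ok[ok$bic <= best_bic + 1e-9, , drop = FALSE]
  ties <- ties[order(-ties$lambda_age, -ties$lambda_period), , drop = FALSE]
  spec$lambda_age <- ties$lambda_age[1]
  spec$lambda_period <- ties$lambda_period[1]
  attr(spec, "bic_table") <- cand
  spec
}

#' Aggregate a hazard surface to age-group death rates
#'
#' Exposure-weighted average of the fitted rates over the fine cells
#' falling in each requested age group and in the requested period.
#'
#' @param surface A `hazard_surface`.
#' @param age_edges Coarse age-group edges.
#' @param period Length-2 calendar interval.
#' @return Numeric vector of group death rates (one per age group).
#' @export
surface_to_mx <- function(surface, age_edges = c(seq(30, 80, 5), 100),
                          period) {
  stopifnot(length(period) == 2L, period[1] < period[2])
  am <- surface$age_grid; pm <- surface$period_grid
  half_a <- if (length(am) > 1) diff(am[1:2]) / 2 else 0.5
  half_p <- if (length(pm) > 1) diff(pm[1:2]) / 2 else 0.5
  if (min(age_edges) < min(am) - half_a - 1e-9 ||
      max(age_edges) > max(am) + half_a + 1e-9 ||
      period[1] < min(pm) - half_p - 1e-9 ||
      period[2] > max(pm) + half_p + 1e-9)
    stop("requested ages/period outside the fitted surface", call. = FALSE)
  jj <- which(pm >= period[1] & pm < period[2])
  if (!length(jj)) stop("no surface columns inside the period",
                        call. = FALSE)
  rates <- exp(surface$log_rate[, jj, drop = FALSE])
  w <- surface$exposures[, jj, drop = FALSE]
  gi <- findInterval(am, age_edges)
  k <- length(age_edges) - 1L
  out <- numeric(k)
  for (g in seq_len(k)) {
    rows <- which(gi == g & am < age_edges[k + 1L])
    wg <- w[rows, , drop = FALSE]
    if (sum(wg) <= 0)
      stop("zero total exposure weight in age group [", age_edges[g],
           ", ", age_edges[g + 1L], ")", call. = FALSE)
    out[g] <- sum(wg * rates[rows, , drop = FALSE]) / sum(wg)
  }
  out
}

#' Write a hazard surface as long-format delimited text
#' @param surface A `hazard_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hazard_surface <- function(surface, path) {
  out <- data.frame(
    age = rep(surface$age_grid, length(surface$period_grid)),
    period = rep(surface$period_grid, each = length(surface$age_grid)),
    log_rate = as.numeric(surface$log_rate))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
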