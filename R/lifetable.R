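#' Abridged period life table from age-group death rates
#'
#' Standard abridged life-table chain on 5-year (or arbitrary) half-open
#' age groups with a terminal open interval.  Interior conversion uses
#' \deqn{q_x = n m_x / (1 + (n - a_x) m_x)} capped at 1 (with a warning),
#' with \eqn{a_x = n/2} by default; the terminal group has \eqn{q = 1},
#' \eqn{L = l / m}, \eqn{a = 1/m}.  Radix 100,000.
#'
#' @param mx Age-group death rates (deaths per person-year); the last
#'   element is the terminal open-interval rate and must be positive.
#' @param age_edges Age-group edges; `length(mx) + 1` values, the last
#'   edge closing the open interval for bookkeeping only.
#' @param ax Average person-years lived in the interval by those dying in
#'   it; default `n/2` for interior groups (terminal `1/mx`).
#' @param radix Life-table radix (default 100,000).
#' @return A data frame of class `abridged_lifetable` with columns
#'   `age`, `n`, `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @examples
#' lt <- mx_to_lifetable(rep(0.02, 11), c(seq(30, 80, 5), 100))
#' remaining_e(lt, 30)
#' gini_remaining(lt, 30)
#' @export
mx_to_lifetable <- function(mx, age_edges = c(seq(30, 80, by = 5), 100),
                            ax = NULL, radix = 1e5) {
  k <- length(mx)
  stopifnot(length(age_edges) == k + 1L, all(diff(age_edges) > 0))
  if (any(is.na(mx)) || any(mx < 0))
    stop("mx must be non-negative and non-missing", call. = FALSE)
  if (mx[k] <= 0)
    stop("terminal open-interval mx must be positive", call. = FALSE)
  n <- diff(age_edges)
  if (is.null(ax)) ax <- n / 2
  ax <- rep_len(ax, k)
  ax[k] <- 1 / mx[k]
  qx <- n * mx / (1 + (n - ax) * mx)
  if (any(qx[-k] > 1)) {
    warning("qx exceeded 1 in ", sum(qx[-k] > 1),
            " group(s); capped", call. = FALSE)
    qx <- pmin(qx, 1)
  }
  qx[k] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- n * (lx - dx) + ax * dx
  Lx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx
  out <- data.frame(age = age_edges[-(k + 1L)], n = n, mx = mx, ax = ax,
                    qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("abridged_lifetable", "data.frame")
  attr(out, "open_age") <- age_edges[k]
  out
}

#' Life table directly from a Lexis grid period
#'
#' Convenience wrapper: aggregates one period of a Lexis grid to the
#' requested age groups and builds the life table from the raw rates
#' `deaths / exposure`.
#'
#' @param grid A `lexis_grid`.
#' @param period Length-2 calendar interval to collapse (default: the
#'   grid's full period span).
#' @param age_edges Coarse age edges (must subset the grid's edges).
#' @param ... Passed to [mx_to_lifetable()].
#' @return An `abridged_lifetable`.
#' @export
lexis_to_lifetable <- function(grid, period = NULL, age_edges = NULL, ...) {
  if (is.null(period))
    period <- range(grid$period_edges)
  agg <- aggregate_lexis(grid, age_edges = age_edges, period = period)
  if (any(agg$exposures == 0))
    stop("zero exposure in age group(s) ",
         paste(agg$age_edges[-length(agg$age_edges)][agg$exposures == 0],
               collapse = ", "), call. = FALSE)
  mx_to_lifetable(as.numeric(agg$deaths / agg$exposures),
                  age_edges = agg$age_edges, ...)
}

#' Remaining life expectancy at an age-group boundary
#'
#' @param lt An `abridged_lifetable`.
#' @param age Conditioning age in years; must be one of the table's
#'   group boundaries.
#' @return \eqn{e(x) = T(x) / l(x)} in years.
#' @export
remaining_e <- function(lt, age = 30) {
  i <- match(age, lt$age)
  if (is.na(i))
    stop("age ", age, " is not an age-group boundary of this table",
         call. = FALSE)
  lt$Tx[i] / lt$lx[i]
}

#' Gini coefficient of remaining lifespan
#'
#' Lifespan inequality conditional on survival to `age`, defined as
#' \deqn{G = \frac{E|X_1 - X_2|}{2\,E X}}
#' for two independent remaining lifespans \eqn{X} under the life-table
#' distribution: death occurs in group \eqn{i} with probability
#' \eqn{d_i / l(\mathrm{age})} at remaining age \eqn{x_i - \mathrm{age} +
#' a_i}.  Computed by the exact double sum over age groups; 0 means
#' perfectly equal ages at death.
#'
#' @inheritParams remaining_e
#' @return Gini coefficient in \[0, 1).
#' @export
gini_remaining <- function(lt, age = 30) {
  i <- match(age, lt$age)
  if (is.na(i))
    stop("age ", age, " is not an age-group boundary of this table",
         call. = FALSE)
  if (lt$lx[i] <= 0)
    stop("no survivors at age ", age, call. = FALSE)
  rows <- seq(i, nrow(lt))
  if (length(rows) == 1L) return(0)
  w <- lt$dx[rows] / lt$lx[i]
  r <- lt$age[rows] - age + lt$ax[rows]
  mean_r <- sum(w * r)
  sum(outer(w, w) * abs(outer(r, r, "-"))) / (2 * mean_r)
}

#' Write an abridged life table as delimited text
#' @param lt An `abridged_lifetable` (or a stacked data frame of them).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an abridged life table written by [write_lifetable()]
#'
#' Also reads benchmark tables in the same 5-year abridged layout
#' (columns `age`, `n`, and `mx` or `qx`); when only `qx` is present the
#' chain is rebuilt from `qx` with the default `ax` rule.
#'
#' @param path Input file path.
#' @return An `abridged_lifetable`.
#' @export
read_lifetable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("age" %in% names(x)))
    stop("life-table file lacks an 'age' column", call. = FALSE)
  if (all(c("mx", "n") %in% names(x))) {
    edges <- c(x$age, x$age[length(x$age)] + x$n[length(x$n)])
    return(mx_to_lifetable(x$mx, age_edges = edges))
  }
  if (all(c("qx", "n") %in% names(x))) {
    n <- x$n; qx <- pmin(x$qx, 1); k <- length(qx)
    ax <- n / 2
    mx <- qx / (n - (n - ax) * qx)
    mx[k] <- if (qx[k] >= 1 && k > 1) mx[k - 1] * 1.5 else mx[k]
    edges <- c(x$age, x$age[k] + n[k])
    return(mx_to_lifetable(mx, age_edges = edges))
  }
  stop("life-table file needs columns (age, n, mx) or (age, n, qx)",
       call. = FALSE)
}
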