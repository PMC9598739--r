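# Intrinsic rate of natural increase from abbreviated life tables.
#
# The population growth rate r solves sum_x exp(-r (x + 0.5)) l_x m_x = 1.
# The left-hand side is continuous and strictly decreasing in r whenever
# some reproduction occurred, so the root is unique; it is located by
# bracketed bisection (expanding the bracket when needed) refined to a
# much tighter internal precision than the reported tolerance.

#' Euler-Lotka left-hand side
#'
#' Evaluates `sum_x exp(-r (x + 0.5)) * l_x * m_x` over the ages of a life
#' table. The mid-interval offset `x + 0.5` credits births to the middle of
#' the daily census interval.
#'
#' @param r Candidate intrinsic rate of increase (day^-1).
#' @param table A `life_table` (columns `x`, `l_x`, `m_x`).
#' @return The value of the sum (dimensionless).
#' @export
#' @examples
#' lt <- data.frame(x = 0:2, l_x = c(1, 1, 1), m_x = c(0, 2, 0))
#' euler_lotka_lhs(log(2) / 1.5, lt)  # exactly 1
euler_lotka_lhs <- function(r, table) {
  stopifnot(all(c("x", "l_x", "m_x") %in% names(table)))
  w <- table$l_x * table$m_x
  pos <- w > 0  # skip zero terms so huge exp() factors cannot yield Inf * 0
  sum(exp(-r * (table$x[pos] + 0.5)) * w[pos])
}

#' Solve the Euler-Lotka equation for r
#'
#' Finds the unique rate at which the Euler-Lotka sum equals one. Negative
#' rates are permitted; the bracket starts at [-5, 5] day^-1 and doubles
#' outward if the root lies outside.
#'
#' @param table A `life_table`.
#' @param tol Tolerance on `|lhs(r) - 1|` for the reported root. The
#'   internal bisection runs to an interval width of 1e-12 regardless.
#' @return The intrinsic rate of natural increase (day^-1).
#' @export
#' @examples
#' lt <- data.frame(x = 0:2, l_x = 1, m_x = c(0, 2, 0))
#' solve_r(lt)  # log(2) / 1.5
solve_r <- function(table, tol = 1e-4) {
  total <- sum(table$l_x * table$m_x)
  if (total <= 0)
    stop("solve_r: no reproduction in this life table; use solve_fallback()")
  f <- function(r) euler_lotka_lhs(r, table) - 1
  lo <- -5; hi <- 5
  while (f(lo) < 0) { lo <- lo * 2; if (lo < -1e4) break }
  while (f(hi) > 0) { hi <- hi * 2; if (hi > 1e4) break }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) >= tol)
    warning("solve_r: |Euler-Lotka sum - 1| = ", abs(f(root)),
            " exceeds tol = ", tol)
  root
}

#' Fallback growth rate for treatments without reproduction
#'
#' When no offspring were produced, the average rate is computed from the
#' start and end cohort sizes as `(ln(Nt + 0.01) / ln(N0 + 0.01)) / t`,
#' evaluated exactly in this log-ratio form. The 0.01 offset keeps the
#' logarithm finite when every animal died. Note the ratio-of-logarithms
#' form returns `1/t`, not 0, for a constant population; see the package
#' vignette for discussion.
#'
#' @param n_final Number of animals alive at the end (`Nt`).
#' @param n_initial Number of animals at day 0 (`N0`, >= 1).
#' @param duration Experiment duration in days (>= 1).
#' @return The fallback rate (day^-1).
#' @export
#' @examples
#' solve_fallback(0, 12, 19)  # all twelve females dead
solve_fallback <- function(n_final, n_initial, duration) {
  if (n_initial < 1 || duration < 1)
    stop("solve_fallback: need n_initial >= 1 and duration >= 1")
  if (n_initial + 0.01 <= 1)
    stop("solve_fallback: log(n_initial + 0.01) must be positive")
  (log(n_final + 0.01) / log(n_initial + 0.01)) / duration
}

#' Generic leave-one-out jackknife
#'
#' Computes pseudo-values `theta_i = n * theta_hat - (n - 1) * theta_(-i)`,
#' their mean (the jackknife point estimate) and the jackknife standard
#' error `sqrt(sum((theta_i - mean)^2) / (n (n - 1)))`. For a linear
#' statistic such as the sample mean this reproduces the classical
#' `s / sqrt(n)` exactly.
#'
#' @param x A vector or list of observations (or indices into a data set).
#' @param statistic Function mapping a subset of `x` to a scalar.
#' @return A list: `estimate` (mean of pseudo-values), `se`, `theta_hat`
#'   (full-sample statistic), `pseudo_values`.
#' @export
#' @examples
#' jk <- jackknife(rnorm(20), mean)
#' all.equal(jk$se, sd(rnorm(20)) / sqrt(20))  # identity holds per sample
jackknife <- function(x, statistic) {
  n <- length(x)
  if (n < 2L) stop("jackknife: need at least two observations")
  theta_hat <- statistic(x)
  loo <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  pseudo <- n * theta_hat - (n - 1) * loo
  est <- mean(pseudo)
  list(estimate = est,
       se = sqrt(sum((pseudo - est)^2) / (n * (n - 1))),
       theta_hat = theta_hat,
       pseudo_values = pseudo)
}

# r for a subset of individuals: Euler-Lotka when any offspring were
# produced, fallback otherwise. Returns the rate and the method used.
r_for_subset <- function(records, ids, tol) {
  sub <- records
  keep <- records$individuals$id %in% ids
  sub$individuals <- records$individuals[keep, , drop = FALSE]
  sub$clutches <- records$clutches[records$clutches$id %in% ids, ,
                                   drop = FALSE]
  lt <- build_life_table(sub)
  if (sum(lt$l_x * lt$m_x) > 0) {
    list(r = solve_r(lt, tol), method = "euler_lotka")
  } else {
    n0 <- nrow(sub$individuals)
    nt <- sum(sub$individuals$censored)
    list(r = solve_fallback(nt, n0, records$horizon), method = "fallback")
  }
}

#' Jackknifed intrinsic rate of increase for one treatment
#'
#' Solves the Euler-Lotka equation on the full cohort and on every
#' leave-one-out cohort, forms pseudo-values, and reports their mean and
#' jackknife standard error. Cohorts (full or leave-one-out) without any
#' offspring fall back to the log-ratio formula of [solve_fallback()]; if
#' that happens for leave-one-out subsets while the full cohort reproduced,
#' the estimate is still returned, with per-pseudo-value method flags and a
#' warning.
#'
#' @param records A `daphnia_records` object for a single treatment.
#' @param tol Euler-Lotka tolerance passed to [solve_r()].
#' @return An object of class `demographic_estimate`: `r_hat` (mean of
#'   pseudo-values, day^-1), `se`, `n`, `method` (`"euler_lotka"` or
#'   `"fallback"` for the full cohort), `theta_hat` (full-sample rate),
#'   `pseudo_values`, `pseudo_methods`.
#' @export
jackknife_r <- function(records, tol = 1e-4) {
  ids <- records$individuals$id
  n <- length(ids)
  if (n < 2L) stop("jackknife_r: need at least two individuals")
  full <- r_for_subset(records, ids, tol)
  loo <- lapply(seq_len(n), function(i) r_for_subset(records, ids[-i], tol))
  loo_r <- vapply(loo, `[[`, numeric(1), "r")
  loo_m <- vapply(loo, `[[`, character(1), "method")
  if (full$method == "euler_lotka" && any(loo_m == "fallback"))
    warning("jackknife_r: some leave-one-out cohorts had no reproduction; ",
            "fallback rates used for those pseudo-values")
  pseudo <- n * full$r - (n - 1) * loo_r
  est <- mean(pseudo)
  out <- list(r_hat = est,
              se = sqrt(sum((pseudo - est)^2) / (n * (n - 1))),
              n = n,
              method = full$method,
              theta_hat = full$r,
              pseudo_values = pseudo,
              pseudo_methods = loo_m)
  class(out) <- "demographic_estimate"
  out
}

#' @export
print.demographic_estimate <- function(x, ...) {
  cat(sprintf("r = %.4f +/- %.4f d^-1 (jackknife, n = %d, %s)\n",
              x$r_hat, x$se, x$n, x$method))
  invisible(x)
}

#' Per-treatment demography table
#'
#' Applies [jackknife_r()] to every treatment present in the records.
#'
#' @param records A `daphnia_records` object (any number of treatments).
#' @param tol Euler-Lotka tolerance.
#' @return A `data.frame` with one row per treatment: `ca`, `food`, `temp`,
#'   `n`, `r_hat`, `se`, `theta_hat`, `method`.
#' @export
demography_table <- function(records, tol = 1e-4) {
  ind <- records$individuals
  key <- unique(ind[, c("ca", "food", "temp")])
  rows <- lapply(seq_len(nrow(key)), function(k) {
    sub <- filter_records(records, ca = key$ca[k], food = key$food[k],
                          temp = key$temp[k])
    est <- suppressWarnings(jackknife_r(sub, tol))
    cbind(key[k, , drop = FALSE],
          data.frame(n = est$n, r_hat = est$r_hat, se = est$se,
                     theta_hat = est$theta_hat, method = est$method))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$temp, out$food, out$ca), , drop = FALSE]
}
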