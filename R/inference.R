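# Discrete-time survival regression and permutation inference.
#
# Survival times measured in whole days are modelled by expanding each
# animal into one row per day at risk ("person-period" form) and fitting a
# binomial GLM with a complementary log-log link, the discrete-time
# counterpart of a grouped proportional-hazards model. Treatment effects on
# reproduction output and on the growth rate are tested by null-model
# residual permutation (Freedman-Lane), since those responses violate the
# normality and homoscedasticity assumptions of ordinary F tests.

#' Expand individual records into person-period form
#'
#' One row per individual per day at risk: the event indicator is 1 on the
#' day of death and 0 otherwise; censored animals contribute `horizon` rows
#' of zeros.
#'
#' @param records A `daphnia_records` object.
#' @param horizon Number of daily intervals (defaults to the records'
#'   horizon).
#' @return A `data.frame` with columns `id`, `interval` (1..horizon),
#'   `event` (0/1), `ca`, `food`, `temp`, `box`.
#' @export
expand_person_period <- function(records, horizon = records$horizon) {
  ind <- records$individuals
  if (any(ind$death_day > horizon))
    stop("expand_person_period: death_day beyond the horizon")
  n_rows <- ifelse(ind$censored, horizon, ind$death_day)
  idx <- rep(seq_len(nrow(ind)), n_rows)
  interval <- unlist(lapply(n_rows, seq_len), use.names = FALSE)
  data.frame(
    id = ind$id[idx], interval = interval,
    event = as.integer(!ind$censored[idx] & interval == ind$death_day[idx]),
    ca = ind$ca[idx], food = ind$food[idx], temp = ind$temp[idx],
    box = ind$box[idx], stringsAsFactors = FALSE)
}

#' Discrete-time hazard regression with a cloglog link
#'
#' Maximum-likelihood fit of `P(event) = 1 - exp(-exp(eta))` on
#' person-period data, with `eta` linear in the requested terms. Continuous
#' predictors enter untransformed. Complete-separation patterns are flagged
#' rather than raised.
#'
#' @param pp A person-period `data.frame` (see [expand_person_period()]).
#' @param terms Character vector of model terms, e.g.
#'   `c("ca", "food", "temp", "interval", "ca:food")`.
#' @return An object of class `hazard_fit`: `coefficients` (`data.frame`
#'   with `term`, `estimate`, `se`, `z`), `loglik`, `n_rows`, `n_events`,
#'   `link = "cloglog"`, `separation`, and the underlying `glm`.
#' @export
fit_cloglog_hazard <- function(pp,
                               terms = c("ca", "food", "temp", "interval",
                                         "ca:food")) {
  if (sum(pp$event) < 1L) stop("fit_cloglog_hazard: no events in the data")
  fml <- stats::reformulate(terms, response = "event")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = pp, family = stats::binomial(link = "cloglog")),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("fit_cloglog_hazard: design matrix is rank deficient (aliased term)")
  # complete separation drives fitted hazards to the boundary without
  # necessarily raising glm's own warning under this link
  p_hat <- stats::fitted(fit)
  if (any(p_hat > 1 - 1e-10) || any(p_hat < 1e-10)) separation <- TRUE
  if (separation)
    warning("fit_cloglog_hazard: possible separation; estimates unreliable")
  sm <- summary(fit)$coefficients
  out <- list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], z = sm[, 3],
                              row.names = NULL, stringsAsFactors = FALSE),
    loglik = as.numeric(stats::logLik(fit)),
    n_rows = nrow(pp), n_events = sum(pp$event),
    link = "cloglog", separation = separation, glm = fit)
  class(out) <- "hazard_fit"
  out
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("Discrete-time hazard model (cloglog link), ", x$n_rows,
      " person-days, ", x$n_events, " deaths\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 3)), row.names = FALSE)
  if (x$separation) cat("  [separation flagged]\n")
  invisible(x)
}

#' Likelihood-ratio screen for the enclosure ("box") effect
#'
#' Compares the fixed-effects hazard model against the same model augmented
#' with box indicator terms: a fixed-effects stand-in for a random box
#' intercept. The statistic is twice the log-likelihood difference; the
#' degrees of freedom are the number of independent box contrasts actually
#' added (boxes nested within temperature contribute fewer than
#' `n_boxes - 1` when temperature is already in the model).
#'
#' @param pp Person-period `data.frame` with a `box` column.
#' @param terms Fixed-effect terms shared by both models.
#' @return A list: `statistic`, `df`, `p_value`, `n_boxes`.
#' @export
lrt_box_screen <- function(pp,
                           terms = c("ca", "food", "temp", "interval",
                                     "ca:food")) {
  boxes <- unique(pp$box)
  if (length(boxes) < 2L) stop("lrt_box_screen: need >= 2 boxes")
  pp$box <- factor(pp$box)
  fam <- stats::binomial(link = "cloglog")
  base <- suppressWarnings(stats::glm(
    stats::reformulate(terms, response = "event"), data = pp, family = fam))
  aug <- suppressWarnings(stats::glm(
    stats::reformulate(c(terms, "box"), response = "event"), data = pp,
    family = fam))
  stat <- max(0, 2 * as.numeric(stats::logLik(aug) - stats::logLik(base)))
  df <- aug$rank - base$rank
  if (df < 1L) stop("lrt_box_screen: box factor adds no estimable contrast")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_boxes = length(boxes))
}

#' Null-model permutation test for a fixed effect
#'
#' Tests one term of a linear model for `response` by residual permutation:
#' the observed statistic is the Gaussian likelihood-ratio chi-square
#' between the full model and the model without the term; each permutation
#' shuffles the residuals of the null fit, adds them back onto the null
#' fitted values, and recomputes the same statistic (Freedman-Lane scheme).
#' The reported p-value uses the add-one estimator
#' `(1 + #\{stat_b >= stat_obs\}) / (1 + B)` and is therefore never zero.
#'
#' @param response Numeric response vector (e.g. reproduction output, or
#'   jackknife pseudo-values of r).
#' @param data `data.frame` of covariates.
#' @param formula Model formula; the left-hand side is ignored, the
#'   right-hand side defines the full design.
#' @param term Term label to drop for the null model (e.g. `"ca:food"`).
#' @param B Number of permutations.
#' @param seed RNG seed for the permutation draws.
#' @return An object of class `perm_test`: `term`, `statistic`, `df`, `B`,
#'   `p_perm`, `seed`.
#' @export
#' @examples
#' d <- data.frame(x = rep(0:1, each = 10))
#' y <- rnorm(20)
#' permutation_test_fixed_effect(y, d, y ~ x, term = "x", B = 199, seed = 1)
permutation_test_fixed_effect <- function(response, data, formula, term,
                                          B = 3000L, seed = 1L) {
  if (B < 1L) stop("permutation_test_fixed_effect: B must be >= 1")
  n <- length(response)
  stopifnot(nrow(data) == n)
  full_terms <- attr(stats::terms(formula, data = data), "term.labels")
  if (!term %in% full_terms)
    stop("permutation_test_fixed_effect: term '", term,
         "' is not part of the full design")
  rhs_full <- stats::reformulate(full_terms)
  null_terms <- setdiff(full_terms, term)
  rhs_null <- if (length(null_terms)) stats::reformulate(null_terms)
  else ~ 1
  x1 <- stats::model.matrix(rhs_full, data)
  x0 <- stats::model.matrix(rhs_null, data)
  q1 <- qr(x1); q0 <- qr(x0)
  if (q1$rank < ncol(x1))
    stop("permutation_test_fixed_effect: term aliased with other columns")
  df <- ncol(x1) - ncol(x0)
  qm1 <- qr.Q(q1); qm0 <- qr.Q(q0)
  scale2 <- sum(response^2) + 1
  rss <- function(y, qm) {
    r <- colSums(y * y) - colSums(crossprod(qm, y)^2)
    pmax(r, 0)
  }
  lr_stat <- function(rss0, rss1) {
    ifelse(rss0 <= scale2 * 1e-12, 0,
           ifelse(rss1 <= scale2 * 1e-12, Inf, n * log(rss0 / rss1)))
  }
  ym <- matrix(response, ncol = 1)
  stat_obs <- lr_stat(rss(ym, qm0), rss(ym, qm1))
  fitted0 <- qm0 %*% crossprod(qm0, response)
  resid0 <- response - as.vector(fitted0)
  set.seed(seed)
  perm <- replicate(B, sample.int(n))
  yb <- as.vector(fitted0) + matrix(resid0[perm], nrow = n)
  stat_b <- lr_stat(rss(yb, qm0), rss(yb, qm1))
  out <- list(term = term, statistic = stat_obs, df = df, B = B,
              p_perm = (1 + sum(stat_b >= stat_obs)) / (1 + B),
              seed = seed)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test for '%s': chi-square = %.4g (df %d), B = %d, p = %.5g\n",
              x$term, x$statistic, x$df, x$B, x$p_perm))
  invisible(x)
}

#' Ordinary least-squares trait model
#'
#' Linear model for a development or reproductive trait against calcium
#' (log-transformed by default), food and temperature, reported with Wald z
#' statistics. This covers the fixed-effect structure of the trait analyses;
#' random enclosure intercepts are screened separately (see
#' [lrt_box_screen()]).
#'
#' @param traits Trait table from [extract_traits()].
#' @param response Column name of the trait to model.
#' @param terms Model terms; `ca` refers to log-calcium when `log_ca` is
#'   `TRUE`.
#' @param log_ca Log-transform the calcium covariate.
#' @param log_response Log-transform the response (used for age at
#'   maturity).
#' @return A `data.frame` with `term`, `estimate`, `se`, `z`, `p`.
#' @export
fit_trait_model <- function(traits, response,
                            terms = c("ca", "food", "temp"),
                            log_ca = TRUE, log_response = FALSE) {
  d <- traits
  if (log_ca) d$ca <- log(d$ca)
  d$.y <- d[[response]]
  if (log_response) d$.y <- log(d$.y)
  d <- d[is.finite(d$.y), , drop = FALSE]
  fit <- stats::lm(stats::reformulate(terms, response = ".y"), data = d)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             z = sm[, 1] / sm[, 2],
             p = 2 * stats::pnorm(abs(sm[, 1] / sm[, 2]), lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}
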