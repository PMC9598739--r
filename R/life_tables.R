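# Abbreviated life tables and individual life-history traits.

#' Build an abbreviated life table for one treatment
#'
#' Ages run from 0 (cohort start, neonates < 24 h) to the horizon, with
#' survival evaluated at the end of each day. `l_x` is the proportion of the
#' initial females alive at day `x`; `m_x` is the mean number of neonates
#' released on day `x` per female alive at day `x` (so that `l_x * m_x` is
#' the expected per-initial-female birth schedule entering the Euler-Lotka
#' sum). Animals censored at the horizon count as alive throughout.
#'
#' @param records A `daphnia_records` object whose individuals all share one
#'   treatment.
#' @param mx_denominator `"alive"` (default) divides day-x births by the
#'   number of females alive at day x; `"initial"` divides by the starting
#'   cohort size.
#' @return An object of class `life_table`: a `data.frame` with columns
#'   `x` (age, days), `n_alive`, `l_x`, `births`, `m_x`, plus attributes
#'   `n0`, `horizon` and the treatment covariates.
#' @export
#' @examples
#' rec <- simulate_experiment(default_sim_config(seed = 1, n_replicates = 6,
#'   treatments = treatment(ca = 1.74, food = 2, temp = 17.5)))
#' lt <- build_life_table(rec)
#' head(lt)
build_life_table <- function(records, mx_denominator = c("alive", "initial")) {
  mx_denominator <- match.arg(mx_denominator)
  ind <- records$individuals
  if (nrow(ind) == 0L) stop("build_life_table: empty record set")
  if (nrow(unique(ind[, c("ca", "food", "temp")])) != 1L)
    stop("build_life_table: records mix treatments; subset first")
  horizon <- records$horizon
  x <- 0:horizon
  # alive at end of day x: death recorded on a later day, or censored
  death <- ifelse(ind$censored, Inf, ind$death_day)
  n_alive <- vapply(x, function(d) sum(death > d), integer(1))
  births <- integer(length(x))
  cl <- records$clutches
  if (!is.null(cl) && nrow(cl)) {
    agg <- tapply(cl$count, cl$day, sum)
    births[as.integer(names(agg)) + 1L] <- as.integer(agg)
  }
  denom <- if (mx_denominator == "alive") n_alive
  else rep(nrow(ind), length(x))
  m_x <- ifelse(denom > 0, births / denom, 0)
  lt <- data.frame(x = x, n_alive = n_alive, l_x = n_alive / nrow(ind),
                   births = births, m_x = m_x)
  attr(lt, "n0") <- nrow(ind)
  attr(lt, "horizon") <- horizon
  attr(lt, "treatment") <- ind[1L, c("ca", "food", "temp")]
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Individual life-history traits
#'
#' Computes, for every individual, the traits scored in the daily census:
#' age at maturity (first egg day), juvenile moulting rate (accumulated
#' moults up to maturity divided by days to maturity), total reproduction
#' output, mean brood size, lifespan (censored at the horizon) and day-19
#' body size.
#'
#' @param records A `daphnia_records` object.
#' @return A `data.frame` with one row per individual: `id`, treatment
#'   covariates, `age_at_maturity` (days, `NA` if no egg was produced),
#'   `moulting_rate` (moults d^-1), `reproduction_output` (total neonates),
#'   `brood_size` (mean neonates per clutch, `NA` without clutches),
#'   `lifespan` (days, capped at the horizon), `censored`, `body_size` (um).
#' @export
extract_traits <- function(records) {
  ind <- records$individuals
  horizon <- records$horizon
  cl <- records$clutches
  mo <- records$moults
  ro <- if (nrow(cl)) tapply(cl$count, cl$id, sum) else NULL
  nb <- if (nrow(cl)) tapply(cl$count, cl$id, length) else NULL
  if (nrow(cl) && nrow(mo)) {
    fm <- tapply(mo$day, mo$id, min)
    fc <- tapply(cl$day, cl$id, min)
    shared <- intersect(names(fm), names(fc))
    bad <- shared[fc[shared] < fm[shared]]
    if (length(bad))
      warning("clutch recorded before any moult for: ",
              paste(bad, collapse = ", "))
  }
  moults_to_mat <- vapply(seq_len(nrow(ind)), function(i) {
    if (is.na(ind$maturity_day[i])) return(NA_integer_)
    if (!nrow(mo)) return(0L)
    sum(mo$id == ind$id[i] & mo$day <= ind$maturity_day[i])
  }, integer(1))
  out <- data.frame(
    id = ind$id, ca = ind$ca, food = ind$food, temp = ind$temp,
    box = ind$box,
    age_at_maturity = ind$maturity_day,
    moulting_rate = moults_to_mat / ind$maturity_day,
    reproduction_output = 0L,
    brood_size = NA_real_,
    lifespan = pmin(ind$death_day, horizon),
    censored = ind$censored,
    body_size = ind$body_size,
    stringsAsFactors = FALSE)
  if (!is.null(ro)) {
    m <- match(out$id, names(ro))
    out$reproduction_output[!is.na(m)] <- as.integer(ro[m[!is.na(m)]])
    out$brood_size[!is.na(m)] <- ro[m[!is.na(m)]] / nb[m[!is.na(m)]]
  }
  out
}

#' Calcium survival-threshold bracket
#'
#' The survival threshold is the Ca concentration below which at least 50%
#' of the cohort dies over the experimental period and no reproduction is
#' possible. A Ca level *passes* when endpoint survival is at least 50%
#' (ties count as surviving) and at least one female reproduced; the
#' threshold is bracketed between the highest failing level below the lowest
#' passing level and that passing level. Sentinels 0 and `Inf` are used when
#' the criterion is not crossed inside the gradient. If levels above the
#' lowest passing level fail again, the innermost bracket is returned and
#' flagged ambiguous.
#'
#' @param summaries A `data.frame` with one row per Ca level (at fixed food
#'   and temperature): columns `ca`, `survival` (endpoint fraction alive)
#'   and `reproduced` (logical, any offspring at that level).
#' @return A list of class `threshold_bracket`: `lower`, `upper` (mg Ca
#'   L^-1), `criterion = "survival"`, `ambiguous`.
#' @export
#' @examples
#' survival_threshold_bracket(data.frame(
#'   ca = c(0.25, 0.41, 1.02, 1.74),
#'   survival = c(0, 0.58, 0.75, 0.83),
#'   reproduced = c(FALSE, TRUE, TRUE, TRUE)))
survival_threshold_bracket <- function(summaries) {
  stopifnot(all(c("ca", "survival", "reproduced") %in% names(summaries)))
  if (nrow(summaries) < 2L)
    stop("survival_threshold_bracket: need >= 2 Ca levels")
  s <- summaries[order(summaries$ca), , drop = FALSE]
  pass <- s$survival >= 0.5 & s$reproduced
  out <- list(criterion = "survival", ambiguous = FALSE)
  if (all(pass)) {
    out$lower <- 0; out$upper <- s$ca[1L]
  } else if (!any(pass)) {
    out$lower <- s$ca[nrow(s)]; out$upper <- Inf
  } else {
    first_pass <- which(pass)[1L]
    fail_below <- which(!pass & seq_len(nrow(s)) < first_pass)
    out$lower <- if (length(fail_below)) s$ca[max(fail_below)] else 0
    out$upper <- s$ca[first_pass]
    if (any(!pass[seq_len(nrow(s)) > first_pass])) out$ambiguous <- TRUE
  }
  class(out) <- "threshold_bracket"
  out
}

#' @export
print.threshold_bracket <- function(x, ...) {
  cat("Ca ", x$criterion, " threshold bracket: (", x$lower, ", ", x$upper,
      ") mg Ca L^-1", if (x$ambiguous) "  [ambiguous crossing]", "\n",
      sep = "")
  invisible(x)
}

#' Calcium reproductive saturation point
#'
#' The smallest Ca level whose per-individual reproduction output does not
#' differ significantly from every higher Ca level, judged by two-sample
#' residual-permutation tests (see [permutation_test_fixed_effect()]).
#'
#' @param outputs A `data.frame` with columns `ca` and `reproduction_output`
#'   (one row per individual).
#' @param alpha Significance level for the pairwise comparisons.
#' @param B Number of permutations per comparison.
#' @param seed RNG seed for the permutation draws.
#' @return A list: `ca` (the saturation level, `NA` if none), `pairwise`
#'   (`data.frame` of comparisons with permutation p-values), `note`.
#' @export
reproduction_saturation_point <- function(outputs, alpha = 0.05, B = 999L,
                                          seed = 1L) {
  stopifnot(all(c("ca", "reproduction_output") %in% names(outputs)))
  levels_ca <- sort(unique(outputs$ca))
  if (length(levels_ca) < 2L)
    stop("reproduction_saturation_point: need >= 2 Ca levels")
  if (all(outputs$reproduction_output == 0))
    return(list(ca = NA_real_, pairwise = NULL,
                note = "no reproduction at any Ca level"))
  pairs <- list(); k <- 0L
  p_of <- function(lo, hi) {
    sub <- outputs[outputs$ca %in% c(lo, hi), , drop = FALSE]
    dat <- data.frame(group = factor(sub$ca == hi))
    pt <- permutation_test_fixed_effect(
      sub$reproduction_output, dat, reproduction_output ~ group,
      term = "group", B = B, seed = seed + k)
    pt$p_perm
  }
  for (i in seq_along(levels_ca)[-length(levels_ca)]) {
    ok <- TRUE
    for (j in seq(i + 1L, length(levels_ca))) {
      k <- k + 1L
      p <- p_of(levels_ca[i], levels_ca[j])
      pairs[[k]] <- data.frame(ca_low = levels_ca[i], ca_high = levels_ca[j],
                               p_perm = p)
      if (p <= alpha) { ok <- FALSE; break }
    }
    if (ok)
      return(list(ca = levels_ca[i], pairwise = do.call(rbind, pairs),
                  note = NULL))
  }
  list(ca = NA_real_, pairwise = do.call(rbind, pairs),
       note = "every level differs from some higher level")
}
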