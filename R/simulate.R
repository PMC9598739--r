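# Individual-based generator of Daphnia life-history records.
#
# Each simulated animal lives through daily census intervals: death is drawn
# from a discrete-time hazard on the complementary log-log scale, maturity
# (first egg day) from a normal around a treatment-dependent mean, clutches
# are released at each adult moult after maturity with zero-truncated Poisson
# counts, and body size is recorded only for animals alive at the horizon.

#' Treatment descriptor
#'
#' A treatment is a combination of calcium concentration, food (carbon)
#' concentration and water temperature, optionally tagged with an enclosure
#' ("box") label.
#'
#' @param ca Calcium concentration (mg Ca L^-1), must be positive.
#' @param food Carbon concentration (mg C L^-1), must be positive.
#' @param temp Water temperature (degrees C).
#' @param box_id Optional enclosure label (character).
#'
#' @return A one-row `data.frame` with columns `ca`, `food`, `temp`, `box_id`.
#' @export
#' @examples
#' treatment(ca = 1.74, food = 2, temp = 17.5)
treatment <- function(ca, food, temp, box_id = NA_character_) {
  stopifnot(is.numeric(ca), is.numeric(food), is.numeric(temp))
  if (any(ca <= 0)) stop("treatment: `ca` must be > 0")
  if (any(food <= 0)) stop("treatment: `food` must be > 0")
  data.frame(ca = ca, food = food, temp = temp, box_id = box_id,
             stringsAsFactors = FALSE)
}

#' Full factorial treatment grid of the default design
#'
#' Four measured calcium levels crossed with two food levels and two
#' temperatures: the 4 x 2 x 2 layout of the experiment the simulator
#' emulates.
#'
#' @param ca Calcium levels (mg Ca L^-1).
#' @param food Food levels (mg C L^-1).
#' @param temp Temperatures (degrees C).
#' @return A `data.frame` of 16 treatments (columns `ca`, `food`, `temp`).
#' @export
treatment_grid <- function(ca = c(0.25, 0.41, 1.02, 1.74),
                           food = c(0.2, 2.0),
                           temp = c(17.5, 21)) {
  g <- expand.grid(ca = ca, food = food, temp = temp,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$temp, g$food, g$ca), , drop = FALSE]
}

#' Default simulation configuration
#'
#' The defaults define the study conditions the package is calibrated to:
#' 4 Ca levels (0.25, 0.41, 1.02, 1.74 mg Ca L^-1) x 2 food (0.2, 2.0
#' mg C L^-1) x 2 temperatures (17.5, 21 C), 12 replicates per treatment
#' (192 animals), followed daily to a 19-day endpoint. The daily hazard
#' combines a cloglog-linear baseline (intercept, ca, food, temp, ca x food,
#' interval slope) with an optional calcium-deficiency stress term whose
#' amplitude falls and whose critical Ca rises with temperature; brood-size
#' means saturate in Ca near 1 mg Ca L^-1 (3.85 neonates per clutch at
#' 0.25 mg Ca L^-1 and high food at 17.5 C, 7.67 at 1.74); maturity is
#' delayed at low Ca and low food and advanced by warming; adults release a
#' clutch at every adult moult (every 3 d at 17.5 C, 2 d at 21 C).
#'
#' @param seed Integer RNG seed stored in the configuration.
#' @param n_replicates Animals per treatment.
#' @param horizon_days Experiment endpoint (days).
#' @param treatments Treatment table (`data.frame` with `ca`, `food`, `temp`).
#' @param hazard,maturity,brood,moult,size Optional component overrides;
#'   each replaces the corresponding element of the default list wholesale.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- default_sim_config(seed = 1)
#' cfg$n_replicates
default_sim_config <- function(seed = 20260L,
                               n_replicates = 12L,
                               horizon_days = 19L,
                               treatments = treatment_grid(),
                               hazard = NULL, maturity = NULL,
                               brood = NULL, moult = NULL, size = NULL) {
  config <- list(
    treatments = treatments,
    n_replicates = as.integer(n_replicates),
    horizon_days = as.integer(horizon_days),
    hazard = hazard %||% list(
      coefs = c(intercept = -6.279, ca = 0, food = -1.128,
                temp = 0.21, ca_food = 0, interval = -0.017),
      # Ca-deficiency stress: added to the linear predictor below a critical
      # Ca that shifts upward with temperature; amplitude grows with food
      # (starved animals die of energy limitation at any Ca) and shrinks
      # slightly with warming (warmer animals tolerate low Ca better).
      stress = list(amp = 4.6, amp_temp = -0.714,
                    food_w0 = 0.6, food_w1 = 0.2,
                    ca_crit = 0.33, crit_temp = 0.068, width = 0.03),
      box_sd = 0,
      temp_ref = 17.5
    ),
    maturity = list(base = 7.3, temp_slope = 0.43,
                    ca_delay = 10.05, ca_scale = 0.25,
                    food_delay = 6.7, food_scale = 0.68,
                    temp_ref = 17.5, temp_max = 21, sd = 1),
    brood = list(max = 7.67, ca_scale = 0.41, ca_sat = 1.0,
                 food_half = 0.5, food_ref = 2,
                 temp_slope = 0.0451, temp_ref = 17.5, min_mean = 1.05),
    moult = list(adult_ref = 3, adult_warm = 2,
                 juv_ref = 1.8, juv_temp_slope = 0.114,
                 juv_ca_amp = 0.15, juv_ca_scale = 0.5, temp_ref = 17.5),
    size = list(intercept = 1350, ca_amp = 250, ca_scale = 0.6,
                food_slope = 80, temp_slope = 25, sd = 60,
                temp_ref = 17.5),
    seed = as.integer(seed)
  )
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a simulation configuration
#'
#' @param config A `sim_config` list.
#' @return The configuration, invisibly, or an error.
#' @export
validate_sim_config <- function(config) {
  tr <- config$treatments
  if (is.null(tr) || nrow(tr) == 0L)
    stop("sim_config: empty treatment list")
  if (any(tr$ca <= 0) || any(tr$food <= 0))
    stop("sim_config: treatment `ca` and `food` must be > 0")
  if (any(tr$temp < 0 | tr$temp > 40))
    stop("sim_config: treatment `temp` outside the simulated range (0-40 C)")
  if (config$n_replicates < 1L) stop("sim_config: n_replicates must be >= 1")
  if (config$horizon_days < 1L) stop("sim_config: horizon_days must be >= 1")
  cf <- config$hazard$coefs
  needed <- c("intercept", "ca", "food", "temp", "ca_food", "interval")
  if (!all(needed %in% names(cf)))
    stop("sim_config: hazard$coefs must contain ",
         paste(needed, collapse = ", "))
  bad <- names(cf)[is.na(cf) | cf == Inf]
  if (length(bad))
    stop("sim_config: non-finite hazard coefficient: ", bad[[1]])
  vpar <- c(config$maturity$sd, config$size$sd, config$hazard$box_sd)
  if (any(vpar < 0)) stop("sim_config: variance parameters must be >= 0")
  invisible(config)
}

# Linear predictor of the daily hazard for one treatment; vector over
# intervals t = 1..horizon. `-Inf` coefficients are allowed (zero hazard).
hazard_eta <- function(ca, food, temp, t, hazard, box_effect = 0) {
  cf <- hazard$coefs
  eta <- cf[["intercept"]] + cf[["ca"]] * ca + cf[["food"]] * food +
    cf[["temp"]] * temp + cf[["ca_food"]] * ca * food +
    cf[["interval"]] * t + box_effect
  st <- hazard$stress
  if (!is.null(st)) {
    dT <- temp - (hazard$temp_ref %||% 17.5)
    amp <- max(0, st$amp + st$amp_temp * dT) * (st$food_w0 + st$food_w1 * food)
    crit <- st$ca_crit + st$crit_temp * dT
    eta <- eta + amp * stats::plogis((crit - ca) / st$width)
  }
  if (any(is.nan(eta) | eta == Inf))
    stop("hazard linear predictor is non-finite for treatment (ca=", ca,
         ", food=", food, ", temp=", temp, ")")
  eta
}

# Expected age at first egg (days).
maturity_mean <- function(ca, food, temp, m) {
  ca_delay <- m$ca_delay *
    max(0, (m$temp_max - temp)) / (m$temp_max - m$temp_ref)
  m$base - m$temp_slope * (temp - m$temp_ref) +
    ca_delay * exp(-ca / m$ca_scale) +
    m$food_delay * exp(-food / m$food_scale)
}

# Mean neonates per clutch: rises with Ca up to a hard reproductive
# saturation point (`ca_sat`, default 1 mg Ca L^-1) and is scaled by food
# and temperature multipliers.
brood_mean <- function(ca, food, temp, b) {
  ca_part <- min(1, (1 - exp(-ca / b$ca_scale)) /
                   (1 - exp(-b$ca_sat / b$ca_scale)))
  mu <- b$max * ca_part *
    (food / (food + b$food_half)) / (b$food_ref / (b$food_ref + b$food_half)) *
    (1 + b$temp_slope * (temp - b$temp_ref))
  max(b$min_mean, mu)
}

# Adult inter-clutch (instar) interval in whole days.
adult_interval <- function(temp, mo) {
  frac <- min(1, max(0, (temp - mo$temp_ref) / 3.5))
  round(mo$adult_ref + frac * (mo$adult_warm - mo$adult_ref))
}

juvenile_interval <- function(ca, temp, mo) {
  (mo$juv_ref - mo$juv_temp_slope * (temp - mo$temp_ref)) *
    (1 + mo$juv_ca_amp * exp(-ca / mo$juv_ca_scale))
}

# Zero-truncated Poisson sampler with a prescribed mean (> 1).
# Solves mean = lambda / (1 - exp(-lambda)) for lambda, then samples by
# inversion restricted to x >= 1.
rztpois <- function(n, mean) {
  if (mean <= 1) stop("rztpois: mean must exceed 1")
  f <- function(l) l / (1 - exp(-l)) - mean
  lambda <- stats::uniroot(f, c(1e-8, mean + 10), tol = 1e-12)$root
  u <- stats::runif(n, stats::dpois(0L, lambda), 1)
  stats::qpois(u, lambda)
}

# Simulate all replicates of a single treatment. `box` is a vector of
# per-individual enclosure labels; `box_effects` a named vector of hazard
# intercept shifts shared across treatments. Returns list of data.frames.
simulate_treatment_block <- function(ca, food, temp, box, n, config,
                                     id_prefix, box_effects = NULL) {
  horizon <- config$horizon_days
  box <- rep_len(box, n)
  box_eff <- if (!is.null(box_effects)) unname(box_effects[box]) else
    rep(0, n)
  eta0 <- hazard_eta(ca, food, temp, seq_len(horizon), config$hazard, 0)
  # hazard matrix: intervals x individuals (box shifts act on the cloglog
  # scale, so they multiply the cumulative hazard)
  h <- 1 - exp(-exp(outer(eta0, box_eff, `+`)))

  # death day: first interval whose uniform falls below the daily hazard
  u <- matrix(stats::runif(horizon * n), nrow = horizon)
  death_day <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (t in seq_len(horizon)) {
    died <- alive & (u[t, ] < h[t, ])
    death_day[died] <- t
    alive <- alive & !died
  }
  censored <- is.na(death_day)
  death_day[censored] <- horizon

  mat_mu <- maturity_mean(ca, food, temp, config$maturity)
  mat_draw <- pmax(2L, as.integer(round(
    stats::rnorm(n, mat_mu, config$maturity$sd))))
  # first egg requires being alive through that day
  matured <- mat_draw <= horizon & (censored | mat_draw < death_day)
  maturity_day <- ifelse(matured, mat_draw, NA_integer_)

  aint <- adult_interval(temp, config$moult)
  jint <- juvenile_interval(ca, temp, config$moult)
  bmu <- brood_mean(ca, food, temp, config$brood)

  ids <- sprintf("%s_%02d", id_prefix, seq_len(n))
  clutches <- list(); moults <- list()
  for (i in seq_len(n)) {
    last_day <- if (censored[i]) horizon else death_day[i] - 1L
    if (matured[i]) {
      jm <- seq(jint, maturity_day[i], by = jint)
      jm <- as.integer(floor(jm[jm <= min(maturity_day[i], last_day)]))
      cd <- if (maturity_day[i] + aint > horizon) integer() else
        as.integer(seq(maturity_day[i] + aint, horizon, by = aint))
      cd <- cd[cd <= last_day]
      if (length(cd))
        clutches[[ids[i]]] <- data.frame(
          id = ids[i], day = cd, count = rztpois(length(cd), bmu),
          stringsAsFactors = FALSE)
      md <- c(jm, cd)
    } else {
      jm <- seq(jint, horizon, by = jint)
      md <- as.integer(floor(jm[jm <= last_day]))
    }
    if (length(md))
      moults[[ids[i]]] <- data.frame(id = ids[i], day = md,
                                     stringsAsFactors = FALSE)
  }

  sz <- config$size
  size_mu <- sz$intercept + sz$ca_amp * (1 - exp(-ca / sz$ca_scale)) +
    sz$food_slope * food + sz$temp_slope * (temp - sz$temp_ref)
  body_size <- ifelse(censored, stats::rnorm(n, size_mu, sz$sd), NA_real_)

  list(
    individuals = data.frame(
      id = ids, ca = ca, food = food, temp = temp, box = box,
      death_day = death_day, censored = censored,
      maturity_day = maturity_day, body_size = body_size,
      stringsAsFactors = FALSE),
    clutches = do.call(rbind, unname(clutches)),
    moults = do.call(rbind, unname(moults))
  )
}

#' Simulate a complete life-table experiment
#'
#' Draws `n_replicates` individual histories for every treatment of the
#' configuration. The RNG seed stored in the configuration fully determines
#' the output.
#'
#' @param config A `sim_config` (see [default_sim_config()]).
#' @return An object of class `daphnia_records`: a list with elements
#'   `individuals` (one row per animal: treatment covariates, `death_day`,
#'   `censored`, `maturity_day`, `body_size`), `clutches` (`id`, `day`,
#'   `count` of neonates), `moults` (`id`, `day`), plus `horizon` and the
#'   generating `config`.
#' @export
#' @examples
#' rec <- simulate_experiment(default_sim_config(seed = 42, n_replicates = 2))
#' nrow(rec$individuals)
simulate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  tr <- config$treatments
  # three enclosures per temperature; vials randomised among them, so box
  # membership is not confounded with the factorial treatments
  temps <- sort(unique(tr$temp))
  box_names <- paste0("B", seq_len(3 * length(temps)))
  box_effects <- stats::setNames(
    if (config$hazard$box_sd > 0)
      stats::rnorm(length(box_names), 0, config$hazard$box_sd)
    else rep(0, length(box_names)), box_names)
  blocks <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    boxes_k <- if (!is.null(tr$box_id) && !is.na(tr$box_id[k]))
      tr$box_id[k]
    else sample(box_names[3 * (match(tr$temp[k], temps) - 1) + 1:3],
                config$n_replicates, replace = TRUE)
    blocks[[k]] <- simulate_treatment_block(
      tr$ca[k], tr$food[k], tr$temp[k], boxes_k,
      config$n_replicates, config, sprintf("T%02d", k), box_effects)
  }
  out <- list(
    individuals = do.call(rbind, lapply(blocks, `[[`, "individuals")),
    clutches = do.call(rbind, lapply(blocks, `[[`, "clutches")),
    moults = do.call(rbind, lapply(blocks, `[[`, "moults")),
    horizon = config$horizon_days,
    config = config
  )
  if (is.null(out$clutches))
    out$clutches <- data.frame(id = character(), day = integer(),
                               count = integer(), stringsAsFactors = FALSE)
  if (is.null(out$moults))
    out$moults <- data.frame(id = character(), day = integer(),
                             stringsAsFactors = FALSE)
  rownames(out$individuals) <- NULL
  rownames(out$clutches) <- NULL
  rownames(out$moults) <- NULL
  class(out) <- "daphnia_records"
  out
}

#' Simulate a single individual
#'
#' Convenience wrapper around the experiment simulator for one animal in one
#' treatment.
#'
#' @param treatment One-row treatment `data.frame` (see [treatment()]).
#' @param config A `sim_config`; its treatment table is ignored.
#' @param seed Optional seed; when given, two calls with the same seed and
#'   treatment return identical records.
#' @return A `daphnia_records` object holding one individual.
#' @export
simulate_individual <- function(treatment, config, seed = NULL) {
  stopifnot(nrow(treatment) == 1L)
  cfg <- config
  cfg$treatments <- treatment
  cfg$n_replicates <- 1L
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  simulate_experiment(cfg)
}

#' @export
print.daphnia_records <- function(x, ...) {
  cat("<daphnia_records> ", nrow(x$individuals), " individuals, ",
      nrow(x$clutches), " clutches, horizon ", x$horizon, " d\n", sep = "")
  invisible(x)
}

#' Subset records to one or more treatments
#'
#' @param records A `daphnia_records` object.
#' @param ca,food,temp Optional values to filter on (exact match).
#' @return A `daphnia_records` object with the matching individuals.
#' @export
filter_records <- function(records, ca = NULL, food = NULL, temp = NULL) {
  ind <- records$individuals
  keep <- rep(TRUE, nrow(ind))
  if (!is.null(ca)) keep <- keep & ind$ca %in% ca
  if (!is.null(food)) keep <- keep & ind$food %in% food
  if (!is.null(temp)) keep <- keep & ind$temp %in% temp
  ids <- ind$id[keep]
  out <- records
  out$individuals <- ind[keep, , drop = FALSE]
  out$clutches <- records$clutches[records$clutches$id %in% ids, , drop = FALSE]
  out$moults <- records$moults[records$moults$id %in% ids, , drop = FALSE]
  rownames(out$individuals) <- rownames(out$clutches) <-
    rownames(out$moults) <- NULL
  out
}

#' Long-format daily events table
#'
#' One row per individual per day survived, with indicators for moulting and
#' the clutch size released that day. This is the on-disk exchange format of
#' the pipeline.
#'
#' @param records A `daphnia_records` object.
#' @return A `data.frame` with columns `id`, `day`, `ca` (mg Ca L^-1),
#'   `food` (mg C L^-1), `temp` (C), `box`, `alive` (0/1 at end of day),
#'   `moult` (0/1), `first_egg` (0/1, day of maturity), `clutch_size`
#'   (neonates released).
#' @export
events_table <- function(records) {
  ind <- records$individuals
  horizon <- records$horizon
  n_days <- ifelse(ind$censored, horizon, ind$death_day)
  idx <- rep(seq_len(nrow(ind)), n_days)
  day <- unlist(lapply(n_days, seq_len), use.names = FALSE)
  ev <- data.frame(
    id = ind$id[idx], day = day,
    ca = ind$ca[idx], food = ind$food[idx], temp = ind$temp[idx],
    box = ind$box[idx],
    alive = as.integer(ind$censored[idx] | day < ind$death_day[idx]),
    moult = 0L,
    first_egg = as.integer(!is.na(ind$maturity_day[idx]) &
                             day == ind$maturity_day[idx]),
    clutch_size = 0L, stringsAsFactors = FALSE)
  key <- paste(ev$id, ev$day)
  if (nrow(records$moults))
    ev$moult[key %in% paste(records$moults$id, records$moults$day)] <- 1L
  if (nrow(records$clutches)) {
    ck <- paste(records$clutches$id, records$clutches$day)
    m <- match(key, ck)
    ev$clutch_size[!is.na(m)] <- records$clutches$count[m[!is.na(m)]]
  }
  ev
}

#' Rebuild a records object from a daily events table
#'
#' Inverse of [events_table()]; used when reading pipeline CSV output back.
#'
#' @param events A `data.frame` in the layout written by [events_table()].
#' @param horizon Experiment endpoint in days.
#' @param body_size Optional named vector of day-`horizon` body sizes.
#' @return A `daphnia_records` object.
#' @export
records_from_events <- function(events, horizon = max(events$day),
                                body_size = NULL) {
  sp <- split(events, events$id)
  ind <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$day), , drop = FALSE]
    last <- d[nrow(d), ]
    censored <- last$alive == 1L && last$day == horizon
    mat <- if ("first_egg" %in% names(d) && any(d$first_egg == 1L))
      min(d$day[d$first_egg == 1L])
    else suppressWarnings(min(d$day[d$clutch_size > 0]))
    data.frame(id = last$id, ca = last$ca, food = last$food,
               temp = last$temp, box = last$box,
               death_day = last$day, censored = censored,
               maturity_day = if (is.finite(mat)) mat else NA_integer_,
               body_size = if (!is.null(body_size) && last$id %in%
                               names(body_size)) body_size[[last$id]]
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(ind) <- NULL
  cl <- events[events$clutch_size > 0, c("id", "day", "clutch_size")]
  names(cl) <- c("id", "day", "count")
  mo <- events[events$moult == 1L, c("id", "day")]
  rownames(cl) <- rownames(mo) <- NULL
  out <- list(individuals = ind, clutches = cl, moults = mo,
              horizon = horizon, config = NULL)
  class(out) <- "daphnia_records"
  out
}
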