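# Shared fixtures and independent oracles, built in code.

# Hand-build a records object: `death_days` integer vector, `censored`
# logical, `clutches` a data.frame (id, day, count) or NULL, `moults`
# likewise (id, day).
make_records <- function(death_days, censored, clutches = NULL,
                         moults = NULL, ca = 1.02, food = 2, temp = 17.5,
                         horizon = 19L, maturity = NULL) {
  n <- length(death_days)
  ids <- sprintf("A%02d", seq_len(n))
  ind <- data.frame(
    id = ids, ca = rep_len(ca, n), food = rep_len(food, n),
    temp = rep_len(temp, n), box = rep_len("B1", n),
    death_day = as.integer(death_days), censored = censored,
    maturity_day = if (is.null(maturity)) rep(NA_integer_, n)
    else as.integer(maturity),
    body_size = ifelse(censored, 1800, NA_real_),
    stringsAsFactors = FALSE)
  empty_cl <- data.frame(id = character(), day = integer(),
                         count = integer(), stringsAsFactors = FALSE)
  empty_mo <- data.frame(id = character(), day = integer(),
                         stringsAsFactors = FALSE)
  out <- list(individuals = ind,
              clutches = if (is.null(clutches)) empty_cl else clutches,
              moults = if (is.null(moults)) empty_mo else moults,
              horizon = as.integer(horizon), config = NULL)
  class(out) <- "daphnia_records"
  out
}

# Independent high-precision bisection for the Euler-Lotka root, with its
# own evaluation of the renewal sum.
oracle_euler_lotka <- function(x, l, m, lo = -50, hi = 50, tol = 1e-10) {
  g <- function(r) {
    w <- l * m
    keep <- w > 0
    sum(exp(-r * (x[keep] + 0.5)) * w[keep]) - 1
  }
  stopifnot(g(lo) > 0, g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random small life table with some reproduction (used for solver
# property tests); returns a data.frame compatible with euler_lotka_lhs.
random_life_table <- function(max_age = 12) {
  n <- sample(4:max_age, 1)
  l <- cumprod(c(1, runif(n, 0.7, 1)))
  m <- rpois(n + 1, lambda = 1.2) * rbinom(n + 1, 1, 0.5)
  m[1] <- 0
  if (all(l * m == 0)) m[sample(2:(n + 1), 1)] <- 2
  data.frame(x = 0:n, l_x = l, m_x = m)
}

# A tiny linear-hazard configuration (no Ca-stress term) with known
# coefficients, for parameter-recovery tests against the fitted GLM.
linear_hazard_config <- function(seed, n_replicates,
                                 coefs = c(intercept = -4.2, ca = -0.35,
                                           food = 0.18, temp = 0.1,
                                           ca_food = -0.25,
                                           interval = -0.02)) {
  cfg <- default_sim_config(seed = seed, n_replicates = n_replicates)
  cfg$hazard$coefs <- coefs
  cfg$hazard$stress <- NULL
  cfg
}
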