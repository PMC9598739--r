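# Person-period expansion, cloglog hazard regression, box screen and
# permutation tests.

test_that("person-period expansion writes one row per day at risk", {
  rec <- make_records(3L, FALSE)
  pp <- expand_person_period(rec)
  expect_equal(nrow(pp), 3L)
  expect_equal(pp$event, c(0L, 0L, 1L))
  expect_equal(pp$interval, 1:3)

  cens <- make_records(19L, TRUE)
  ppc <- expand_person_period(cens)
  expect_equal(nrow(ppc), 19L)
  expect_true(all(ppc$event == 0L))

  bad <- make_records(25L, FALSE)
  expect_error(expand_person_period(bad), "beyond the horizon")
})

test_that("row counts conserve animal-days on simulated data", {
  rec <- simulate_experiment(default_sim_config(seed = 9))
  pp <- expand_person_period(rec)
  ind <- rec$individuals
  expect_equal(nrow(pp),
               sum(pmin(ifelse(ind$censored, Inf, ind$death_day), 19)))
  expect_equal(sum(pp$event), sum(!ind$censored))
})

test_that("expansion matches the survival package's survSplit", {
  library(survival)
  rec <- simulate_experiment(default_sim_config(seed = 14,
                                                n_replicates = 6))
  ind <- rec$individuals
  ind$status <- 1L - as.integer(ind$censored)
  sp <- survSplit(Surv(death_day, status) ~ id, data = ind,
                  cut = 0:18, episode = "interval")
  pp <- expand_person_period(rec)
  expect_equal(nrow(pp), nrow(sp))
  ev_sp <- tapply(sp$status, sp$id, sum)
  ev_pp <- tapply(pp$event, pp$id, sum)
  expect_equal(ev_pp[order(names(ev_pp))], ev_sp[order(names(ev_sp))])
})

test_that("intercept-only cloglog fit equals the closed-form link inverse", {
  n <- 1000L; k <- 632L                     # event fraction close to 1-1/e
  pp <- data.frame(id = "x", interval = 1L,
                   event = c(rep(1L, k), rep(0L, n - k)),
                   ca = 1, food = 1, temp = 1, box = "B1")
  fit <- fit_cloglog_hazard(pp, terms = "1")
  expect_equal(fit$coefficients$estimate[1], log(-log(1 - k / n)),
               tolerance = 1e-7)
  expect_error(fit_cloglog_hazard(transform(pp, event = 0L), "1"),
               "no events")
})

test_that("hazard coefficients recover generator truth (quick check)", {
  truth <- c(intercept = -4.2, ca = -0.35, food = 0.18, temp = 0.1,
             ca_food = -0.25, interval = -0.02)
  hits <- 0L; total <- 0L
  for (i in 1:10) {
    cfg <- linear_hazard_config(seed = 600 + i, n_replicates = 40)
    pp <- expand_person_period(simulate_experiment(cfg))
    fit <- fit_cloglog_hazard(pp)
    cf <- fit$coefficients
    est <- cf$estimate
    names(est) <- cf$term
    se <- cf$se
    names(se) <- cf$term
    map <- c(`(Intercept)` = "intercept", ca = "ca", food = "food",
             temp = "temp", interval = "interval", `ca:food` = "ca_food")
    for (term in names(map)) {
      total <- total + 1L
      if (abs(est[term] - truth[map[term]]) <= 2 * se[term])
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.8)   # ~95% nominal at n = 640 per replicate
})

test_that("an aliased term and separation are caught", {
  rec <- simulate_experiment(default_sim_config(seed = 6,
                                                n_replicates = 4))
  pp <- expand_person_period(rec)
  pp$ca2 <- pp$ca
  expect_error(fit_cloglog_hazard(pp, c("ca", "ca2")), "rank deficient")
  # a covariate pattern predicting the event perfectly separates the fit
  pp2 <- data.frame(id = "a", interval = 1L,
                    event = rep(c(0L, 1L), each = 12),
                    ca = rep(c(0, 1), each = 12), food = 1, temp = 1,
                    box = "B1")
  expect_warning(fit2 <- fit_cloglog_hazard(pp2, "ca"), "separation")
  expect_true(fit2$separation)
})

test_that("relabelled duplicate boxes add nothing to the likelihood", {
  rec <- simulate_experiment(default_sim_config(seed = 12,
                                                n_replicates = 6))
  pp <- expand_person_period(rec)
  pp$box <- "B1"
  dup <- pp
  dup$box <- "B2"
  both <- rbind(pp, dup)
  out <- lrt_box_screen(both)
  expect_lt(out$statistic, 1e-6)
  expect_error(lrt_box_screen(pp), ">= 2 boxes")
})

test_that("the box screen is calibrated under a null box effect", {
  pvals <- numeric(120)
  for (i in 1:120) {
    cfg <- default_sim_config(seed = 7000 + i, n_replicates = 12)
    pp <- expand_person_period(simulate_experiment(cfg))
    pvals[i] <- lrt_box_screen(pp)$p_value
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the box screen detects large injected box effects", {
  detected <- 0L
  for (i in 1:15) {
    cfg <- default_sim_config(seed = 8000 + i, n_replicates = 12)
    cfg$hazard$box_sd <- 1.5
    pp <- expand_person_period(simulate_experiment(cfg))
    if (lrt_box_screen(pp)$p_value < 0.001) detected <- detected + 1L
  }
  expect_gte(detected, 14L)
})

test_that("a perfectly explanatory term attains the minimal p-value", {
  d <- data.frame(x = rep(c(0, 1, 2), each = 8), z = rnorm(24))
  y <- d$x
  pt <- permutation_test_fixed_effect(y, d, y ~ x + z, term = "x",
                                      B = 199, seed = 5)
  expect_equal(pt$p_perm, 1 / 200)
  expect_true(is.infinite(pt$statistic))
})

test_that("aliased and absent terms are rejected", {
  d <- data.frame(x = rep(0:1, 10))
  d$w <- d$x
  y <- rnorm(20)
  expect_error(permutation_test_fixed_effect(y, d, y ~ x + w, term = "w"),
               "aliased")
  expect_error(permutation_test_fixed_effect(y, d, y ~ x, term = "q"),
               "not part of the full design")
})

test_that("permutation p-values are valid under the null (quick check)", {
  set.seed(99)
  d <- data.frame(x = rep(c(0.25, 0.41, 1.02, 1.74), each = 12),
                  g = rep(0:1, 24))
  rejections <- 0L
  for (i in 1:200) {
    y <- rnorm(48)
    pt <- permutation_test_fixed_effect(y, d, y ~ x + g, term = "x",
                                        B = 199, seed = 2000 + i)
    if (pt$p_perm <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("trait models recover the factorial effect directions", {
  rec <- simulate_experiment(default_sim_config(seed = 20,
                                                n_replicates = 25))
  tr <- extract_traits(rec)
  mat <- fit_trait_model(tr, "age_at_maturity", log_response = TRUE)
  expect_lt(mat$estimate[mat$term == "food"], 0)   # food advances maturity
  expect_lt(mat$estimate[mat$term == "temp"], 0)   # warming advances it
  size <- fit_trait_model(tr, "body_size")
  expect_gt(size$estimate[size$term == "food"], 0)
})
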