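# Life tables, traits and descriptive Ca thresholds.

test_that("a cohort dying on day 1 gives the degenerate life table", {
  rec <- make_records(rep(1L, 12), rep(FALSE, 12))
  lt <- build_life_table(rec)
  expect_equal(lt$l_x[lt$x == 0], 1)
  expect_true(all(lt$l_x[lt$x >= 1] == 0))
  expect_true(all(lt$m_x == 0))
})

test_that("hand-counted two-individual example is reproduced exactly", {
  cl <- data.frame(id = "A02", day = 7L, count = 4L,
                   stringsAsFactors = FALSE)
  rec <- make_records(c(3L, 19L), c(FALSE, TRUE), clutches = cl,
                      maturity = c(NA, 6L))
  lt <- build_life_table(rec)
  expect_equal(lt$l_x[lt$x == 7], 0.5)
  expect_equal(lt$m_x[lt$x == 7], 4)
  expect_equal(lt$l_x[lt$x == 2], 1)
  expect_equal(lt$l_x[lt$x == 3], 0.5)
  # per-initial-female denominator option
  lt2 <- build_life_table(rec, mx_denominator = "initial")
  expect_equal(lt2$m_x[lt2$x == 7], 2)
})

test_that("life table construction rejects bad input", {
  rec <- make_records(c(3L, 19L), c(FALSE, TRUE))
  rec$individuals$ca <- c(0.25, 1.74)
  expect_error(build_life_table(rec), "mix treatments")
  empty <- make_records(integer(), logical())
  expect_error(build_life_table(empty), "empty record set")
})

test_that("synthetic high-food cohorts give monotone l_x with l_19 > 0.5", {
  cfg <- default_sim_config(seed = 8, n_replicates = 12,
                            treatments = treatment(1.74, 2, 17.5))
  lt <- build_life_table(simulate_experiment(cfg))
  expect_true(all(diff(lt$l_x) <= 0))
  expect_gt(lt$l_x[lt$x == 19], 0.5)
  expect_true(all(lt$l_x >= 0 & lt$l_x <= 1))
})

test_that("l_x equals the Kaplan-Meier estimate at integer days", {
  library(survival)
  rec <- simulate_experiment(default_sim_config(
    seed = 17, n_replicates = 30, treatments = treatment(0.41, 2, 21)))
  lt <- build_life_table(rec)
  ind <- rec$individuals
  km <- survfit(Surv(death_day, 1L - as.integer(censored)) ~ 1, data = ind)
  km_at <- summary(km, times = lt$x, extend = TRUE)$surv
  expect_equal(lt$l_x, km_at, tolerance = 1e-12)
})

test_that("animal-days and births are conserved in the life table", {
  for (seed in 1:5) {
    cfg <- default_sim_config(seed = 300 + seed, n_replicates = 15,
                              treatments = treatment(1.02, 2, 21))
    rec <- simulate_experiment(cfg)
    lt <- build_life_table(rec)
    ind <- rec$individuals
    expect_equal(sum(lt$n_alive[lt$x < rec$horizon]),
                 sum(ifelse(ind$censored, rec$horizon, ind$death_day)))
    expect_equal(sum(lt$m_x * lt$n_alive), sum(rec$clutches$count))
    expect_equal(sum(lt$births), sum(rec$clutches$count))
  }
})

test_that("traits are computed exactly as defined", {
  cl <- data.frame(id = c("A01", "A01"), day = c(7L, 10L),
                   count = c(3L, 5L), stringsAsFactors = FALSE)
  mo <- data.frame(id = rep("A01", 4), day = c(2L, 4L, 6L, 8L),
                   stringsAsFactors = FALSE)
  rec <- make_records(19L, TRUE, clutches = cl, moults = mo, maturity = 8L)
  tr <- extract_traits(rec)
  expect_equal(tr$moulting_rate, 0.5)        # 4 moults / 8 days
  expect_equal(tr$reproduction_output, 8L)
  expect_equal(tr$brood_size, 4)
  expect_equal(tr$age_at_maturity, 8L)

  rec2 <- make_records(5L, FALSE)
  tr2 <- extract_traits(rec2)
  expect_true(is.na(tr2$age_at_maturity))
  expect_equal(tr2$reproduction_output, 0L)
  expect_true(is.na(tr2$brood_size))
  expect_equal(tr2$lifespan, 5L)
})

test_that("a clutch recorded before any moult triggers a warning", {
  cl <- data.frame(id = "A01", day = 3L, count = 2L, stringsAsFactors = FALSE)
  mo <- data.frame(id = "A01", day = 5L, stringsAsFactors = FALSE)
  rec <- make_records(19L, TRUE, clutches = cl, moults = mo, maturity = 3L)
  expect_warning(extract_traits(rec), "clutch recorded before any moult")
})

test_that("generator maturity day round-trips through trait extraction", {
  rec <- simulate_experiment(default_sim_config(seed = 23,
                                                n_replicates = 30))
  tr <- extract_traits(rec)
  expect_identical(tr$age_at_maturity, rec$individuals$maturity_day)
  ev <- events_table(rec)
  rt <- records_from_events(ev, horizon = rec$horizon)
  tr_rt <- extract_traits(rt)
  m <- match(tr$id, tr_rt$id)
  expect_identical(tr_rt$age_at_maturity[m], tr$age_at_maturity)
  expect_identical(tr_rt$reproduction_output[m], tr$reproduction_output)
})

test_that("survival-threshold brackets follow the 50%-and-reproduction rule", {
  b <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41), survival = c(0, 0.58),
    reproduced = c(FALSE, TRUE)))
  expect_equal(c(b$lower, b$upper), c(0.25, 0.41))

  b2 <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41, 1.02), survival = c(0, 0.2, 0.7),
    reproduced = c(FALSE, FALSE, TRUE)))
  expect_equal(c(b2$lower, b2$upper), c(0.41, 1.02))

  b3 <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41), survival = c(0.6, 0.9), reproduced = c(TRUE, TRUE)))
  expect_equal(c(b3$lower, b3$upper), c(0, 0.25))

  b4 <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41), survival = c(0.2, 0.3), reproduced = c(TRUE, TRUE)))
  expect_equal(c(b4$lower, b4$upper), c(0.41, Inf))

  # exactly 50% survival counts as surviving
  b5 <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41), survival = c(0, 0.5), reproduced = c(FALSE, TRUE)))
  expect_equal(b5$upper, 0.41)

  # non-monotone crossing: innermost bracket, flagged
  b6 <- survival_threshold_bracket(data.frame(
    ca = c(0.25, 0.41, 1.02), survival = c(0, 0.7, 0.1),
    reproduced = c(FALSE, TRUE, TRUE)))
  expect_equal(c(b6$lower, b6$upper), c(0.25, 0.41))
  expect_true(b6$ambiguous)
})

test_that("reproduction saturation point behaves at the edges", {
  same <- data.frame(ca = rep(c(0.25, 0.41, 1.02), each = 10),
                     reproduction_output = rep(5L, 30))
  expect_equal(reproduction_saturation_point(same, seed = 2)$ca, 0.25)

  rising <- data.frame(ca = rep(c(0.25, 0.41, 1.02), each = 15),
                       reproduction_output = rep(c(0L, 40L, 90L), each = 15))
  out <- reproduction_saturation_point(rising, seed = 3)
  expect_true(is.na(out$ca))

  zeros <- data.frame(ca = rep(c(0.25, 0.41), each = 5),
                      reproduction_output = 0L)
  z <- reproduction_saturation_point(zeros, seed = 4)
  expect_true(is.na(z$ca))
  expect_match(z$note, "no reproduction")
})

test_that("synthetic high-food data saturate at the 1.02 mg Ca level", {
  cfg <- default_sim_config(seed = 17, n_replicates = 40,
                            treatments = treatment_grid(food = 2,
                                                        temp = 17.5))
  tr <- extract_traits(simulate_experiment(cfg))
  sat <- reproduction_saturation_point(
    tr[, c("ca", "reproduction_output")], B = 999, seed = 17)
  expect_equal(sat$ca, 1.02)
})
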