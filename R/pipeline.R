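# One-shot analysis pipeline: simulate -> life tables -> demography ->
# threshold Monod fits -> hazard regression -> permutation tests, with CSV
# output mirroring the stage chain of the factorial life-table analysis.

PIPELINE_STAGES <- c("simulate", "lifetable", "demography", "monod",
                     "hazard", "permtest")

# TRUE when `outer` is a strictly higher-order interaction containing all
# variables of `inner` (e.g. "ca:food:temp" contains "ca:food").
contains_term <- function(outer, inner) {
  vo <- strsplit(outer, ":", fixed = TRUE)[[1]]
  vi <- strsplit(inner, ":", fixed = TRUE)[[1]]
  length(vo) > length(vi) && all(vi %in% vo)
}

#' Run the full life-table analysis pipeline
#'
#' Executes the requested stages in order on synthetic (or supplied)
#' records. Stages form a prefix-closed chain: each consumes the previous
#' stage's output. Monod fits are attempted per temperature at the highest
#' food level only; groups whose growth rates are all negative are skipped
#' with an explanatory note rather than an error. Every random stage derives
#' its seed from the configuration seed, recorded in the output metadata.
#'
#' @param config A `sim_config`; its seed drives all randomness.
#' @param records Optional pre-existing `daphnia_records` (skips the
#'   simulate stage).
#' @param stages Character vector of stages to run (a prefix of
#'   `simulate, lifetable, demography, monod, hazard, permtest`).
#' @param out_dir Optional directory; when given, each stage writes CSV/JSON
#'   files (`events.csv`, `traits.csv`, `life_tables.csv`,
#'   `demography.csv`, `thresholds.csv`, `monod.json`, `hazard.csv`,
#'   `permtests.csv`, `report.txt`, `metadata.json`, `schema.json`).
#' @param B Permutations for the permutation-test stage.
#' @param tol Euler-Lotka tolerance.
#' @return A list (class `pipeline_result`) with one element per executed
#'   stage plus `seed` and `log`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_sim_config(seed = 7), B = 199)
#' res$demography
#' }
run_pipeline <- function(config = default_sim_config(), records = NULL,
                         stages = PIPELINE_STAGES, out_dir = NULL,
                         B = 3000L, tol = 1e-4) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  ord <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  need <- PIPELINE_STAGES[seq_len(max(match(ord, PIPELINE_STAGES)))]
  missing_up <- setdiff(setdiff(need, ord), "simulate")
  if (length(missing_up))
    stop("run_pipeline: missing upstream stage '", missing_up[[1]], "'")
  if (!"simulate" %in% ord && is.null(records))
    stop("run_pipeline: missing upstream output for stage '", ord[[1]],
         "': supply `records` or include the simulate stage")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  res <- list(seed = config$seed, log = character())
  note <- function(...) res$log <<- c(res$log, paste0(...))

  if ("simulate" %in% ord) {
    records <- simulate_experiment(config)
    note("simulate: ", nrow(records$individuals), " individuals, ",
         nrow(records$clutches), " clutches")
  }
  res$records <- records
  traits <- extract_traits(records)
  res$traits <- traits
  emit("events.csv", events_table(records))
  emit("traits.csv", traits)

  key <- unique(records$individuals[, c("ca", "food", "temp")])
  key <- key[order(key$temp, key$food, key$ca), , drop = FALSE]

  if ("lifetable" %in% ord) {
    lts <- lapply(seq_len(nrow(key)), function(k) {
      sub <- filter_records(records, key$ca[k], key$food[k], key$temp[k])
      lt <- build_life_table(sub)
      cbind(key[k, , drop = FALSE][rep(1, nrow(lt)), ], lt)
    })
    res$life_tables <- do.call(rbind, lts)
    rownames(res$life_tables) <- NULL
    emit("life_tables.csv", res$life_tables)
    note("lifetable: ", nrow(key), " treatment tables")
  }

  if ("demography" %in% ord) {
    res$demography <- demography_table(records, tol)
    emit("demography.csv", res$demography)
    note("demography: ", nrow(res$demography), " r estimates")
  }

  if ("monod" %in% ord) {
    dem <- res$demography
    hf <- max(key$food)
    # survival / reproduction thresholds per food x temperature group
    thr <- list(); fits <- list()
    for (tmp in sort(unique(key$temp))) {
      for (fd in sort(unique(key$food))) {
        grp <- traits[traits$temp == tmp & traits$food == fd, , drop = FALSE]
        summ <- do.call(rbind, lapply(sort(unique(grp$ca)), function(cc) {
          g <- grp[grp$ca == cc, , drop = FALSE]
          data.frame(ca = cc, survival = mean(g$censored),
                     reproduced = any(g$reproduction_output > 0))
        }))
        br <- survival_threshold_bracket(summ)
        thr[[length(thr) + 1L]] <- data.frame(
          temp = tmp, food = fd, lower = br$lower, upper = br$upper,
          ambiguous = br$ambiguous)
      }
      pts <- dem[dem$temp == tmp & dem$food == hf, c("ca", "r_hat")]
      names(pts) <- c("ca", "r")
      fit <- fit_monod_threshold(pts)
      fits[[as.character(tmp)]] <- fit
      note("monod @", tmp, " C (food ", hf, "): ",
           if (fit$refused) fit$reason
           else sprintf("Ca_ZPG = %.3f", fit$ca_zpg))
      lf_pts <- dem[dem$temp == tmp & dem$food == min(key$food), ]
      if (all(lf_pts$r_hat < 0))
        note("monod @", tmp, " C (food ", min(key$food),
             "): skipped, all growth rates negative")
    }
    res$thresholds <- do.call(rbind, thr)
    res$monod <- fits
    emit("thresholds.csv", res$thresholds)
    if (!is.null(out_dir)) {
      mm <- lapply(fits, function(f)
        f[c("r_max", "ca_zpg", "k_s", "se", "ci_ca_zpg", "rss",
            "converged", "refused", "reason")])
      jsonlite::write_json(mm, file.path(out_dir, "monod.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }

  if ("hazard" %in% ord) {
    pp <- expand_person_period(records)
    res$hazard <- fit_cloglog_hazard(pp)
    res$box_screen <- lrt_box_screen(pp)
    emit("hazard.csv", res$hazard$coefficients)
    note("hazard: ", res$hazard$n_rows, " person-days, ",
         res$hazard$n_events, " deaths",
         if (res$hazard$separation) " [separation flagged]" else "")
  }

  if ("permtest" %in% ord) {
    terms_ro <- c("ca", "food", "temp", "ca:food", "food:temp",
                  "ca:food:temp")
    all_terms <- c("ca", "food", "temp", "ca:food", "ca:temp", "food:temp",
                   "ca:food:temp")
    d <- traits
    d$ca <- log(d$ca)
    # marginality: a term is tested in the model that excludes any
    # higher-order term containing it
    tests <- lapply(seq_along(terms_ro), function(i) {
      keep <- all_terms[!vapply(all_terms, contains_term, logical(1),
                                inner = terms_ro[i])]
      fml <- stats::reformulate(c(keep, terms_ro[i]),
                                response = "reproduction_output")
      permutation_test_fixed_effect(
        traits$reproduction_output, d, fml, term = terms_ro[i],
        B = B, seed = (config$seed %% 100000L) + 1000L + i)
    })
    res$permtests <- data.frame(
      response = "reproduction_output",
      term = terms_ro,
      statistic = vapply(tests, `[[`, numeric(1), "statistic"),
      B = B,
      p_perm = vapply(tests, `[[`, numeric(1), "p_perm"))
    emit("permtests.csv", res$permtests)
    note("permtest: ", length(terms_ro), " terms, B = ", B)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, stages = ord,
           n_individuals = nrow(records$individuals),
           horizon = records$horizon),
      file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(pipeline_schema(),
                         file.path(out_dir, "schema.json"),
                         auto_unbox = TRUE)
    writeLines(pipeline_report(res), file.path(out_dir, "report.txt"))
  }
  class(res) <- "pipeline_result"
  res
}

# Column documentation emitted alongside pipeline CSV output.
pipeline_schema <- function() {
  list(
    events.csv = list(
      id = "individual label", day = "census day (1..horizon)",
      ca = "calcium, mg Ca L^-1", food = "carbon, mg C L^-1",
      temp = "temperature, C", box = "enclosure",
      alive = "0/1 at end of day", moult = "0/1",
      first_egg = "0/1, maturity day", clutch_size = "neonates released"),
    traits.csv = list(
      age_at_maturity = "days (NA if never matured)",
      moulting_rate = "juvenile moults per day",
      reproduction_output = "total neonates",
      brood_size = "mean neonates per clutch",
      lifespan = "days, capped at horizon", censored = "alive at horizon",
      body_size = "length at day 19, um"),
    life_tables.csv = list(
      x = "age, days", n_alive = "females alive at end of day x",
      l_x = "survivorship", births = "neonates released on day x",
      m_x = "births per living female"),
    demography.csv = list(
      r_hat = "jackknife mean growth rate, day^-1",
      se = "jackknife SE", theta_hat = "full-sample rate",
      method = "euler_lotka or fallback"),
    thresholds.csv = list(
      lower = "highest failing Ca below the bracket, mg Ca L^-1 (0 = edge)",
      upper = "lowest Ca with >= 50% survival and reproduction (Inf = edge)"))
}

# Plain-text summary echoing the qualitative structure of the analysis.
pipeline_report <- function(res) {
  out <- c("Daphnia calcium life-table pipeline", paste("seed:", res$seed),
           "", res$log, "")
  if (!is.null(res$thresholds)) {
    out <- c(out, "Survival-threshold brackets (mg Ca L^-1):",
             utils::capture.output(print(res$thresholds,
                                         row.names = FALSE)), "")
  }
  if (!is.null(res$hazard)) {
    cf <- res$hazard$coefficients
    cxf <- cf[cf$term == "ca:food", ]
    if (nrow(cxf))
      out <- c(out, sprintf(
        "Ca x food hazard interaction: %.3f (z = %.2f, %s)",
        cxf$estimate, cxf$z,
        if (cxf$estimate < 0) "low Ca more lethal at high food"
        else "low Ca more lethal at low food"), "")
  }
  if (!is.null(res$permtests)) {
    out <- c(out, "Permutation tests (reproduction output):",
             utils::capture.output(print(res$permtests,
                                         row.names = FALSE)))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
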