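## End-to-end orchestration: simulate (optional) -> classify -> derive ->
## trend models per trait -> partial budget -> sensitivity, with every
## intermediate table written out and a manifest recording the seed,
## configuration and file hashes so a run is fully regenerable.

#' Run the full analysis pipeline
#'
#' Executes the whole chain on either real event/herd CSV files or a
#' synthetic population, writing intermediate tables, fitted-model
#' summaries, the budget report and the scenario/Monte-Carlo sensitivity
#' tables into `out_dir`, plus a JSON manifest with the seed, row counts,
#' per-stage timing and MD5 hashes of every output file.
#'
#' @param config either a path to a YAML file or a list with entries:
#'   `events`/`herds` (paths to CSVs) or `sim` (arguments for
#'   [sim_config()]) — exactly one of the two modes; optional `cutoffs`
#'   (data frame or NULL to use [default_cutoffs()]), `max_years`,
#'   `model` (list: `factors`, `interaction`, `log_offset`), `budget`
#'   (arguments for [budget_inputs()]), `sensitivity` (list: `n_draws`,
#'   `perturbation`), and `seed`.
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  has_paths <- !is.null(config$events) || !is.null(config$herds)
  has_sim <- !is.null(config$sim)
  if (has_paths == has_sim) {
    stop("config must provide exactly one of: events/herds paths, or sim")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  log_lines <- character(0)
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
      log_lines <<- c(log_lines, msg)
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop(msg, call. = FALSE)
    })
    log_lines <<- c(log_lines,
                    sprintf("[%7.2fs] %s done (%.2fs)",
                            proc.time()[["elapsed"]] - t_start, name,
                            proc.time()[["elapsed"]] - t0))
    res
  }

  if (has_sim) {
    sim_args <- config$sim
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim <- stage("simulate", simulate_events(cfg))
    events <- sim$events
    meta <- sim$herds
    write_events(events, file.path(out_dir, "events.csv"))
    write_herds(meta, file.path(out_dir, "herds.csv"))
    utils::write.csv(sim$truth$expectations,
                     file.path(out_dir, "truth.csv"), row.names = FALSE)
  } else {
    events <- stage("read_events", read_events(config$events))
    meta <- stage("read_herds", read_herds(config$herds))
  }
  log_lines <- c(log_lines, sprintf("events: %d rows, %d herds",
                                    nrow(events),
                                    length(unique(events$herd_id))))

  report <- stage("validate", validate_events(events, meta))
  if (nrow(report) > 0L) {
    utils::write.csv(report, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("validation: %d finding(s), see validation.csv",
                           nrow(report)))
  }

  profiles <- stage("classify", classify_adoption(events))
  utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  max_years <- if (!is.null(config$max_years)) config$max_years else 10L
  fmap <- stage("followup", select_followup(profiles, max_years))

  traits <- stage("derive", derive_traits(events, fmap, profiles))
  cutoffs <- if (!is.null(config$cutoffs)) {
    as.data.frame(config$cutoffs)
  } else {
    default_cutoffs()
  }
  trimmed <- stage("cutoffs", apply_cutoffs(traits, cutoffs))
  traits <- trimmed$table
  if (nrow(trimmed$removed) > 0L) {
    utils::write.csv(trimmed$removed, file.path(out_dir, "removed.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)

  ## trend models per trait; nuisance factors with a single observed level
  ## are dropped with a log note rather than aborting the run
  herds_df <- merge(profiles[, c("herd_id", "level")], meta, by = "herd_id")
  model_cfg <- config$model
  req_factors <- if (!is.null(model_cfg$factors)) model_cfg$factors else
    c("zone", "breed", "herd_size", "period")
  interaction <- if (!is.null(model_cfg$interaction)) {
    isTRUE(model_cfg$interaction)
  } else TRUE
  log_offset <- if (!is.null(model_cfg$log_offset)) {
    model_cfg$log_offset
  } else 0.5
  fits <- list()
  means_tables <- list()
  for (tr in intersect(TRAITS, unique(traits$trait))) {
    fit <- stage(paste0("trend_", tr),
                 herd_trend(traits, herds_df, tr, factors = req_factors,
                            interaction = interaction,
                            log_offset = log_offset, drop_single = TRUE))
    if (length(fit$design$dropped_factors) > 0L) {
      log_lines <- c(log_lines, sprintf(
        "trend_%s: dropped single-level factor(s): %s", tr,
        paste(fit$design$dropped_factors, collapse = ", ")))
    }
    fits[[tr]] <- fit
    mm <- marginal_means(fit)
    means_tables[[tr]] <- mm
    utils::write.csv(as.data.frame(mm),
                     file.path(out_dir, sprintf("means_%s.csv", tr)),
                     row.names = FALSE)
    jsonlite::write_json(list(
      trait = tr, family = fit$family, converged = fit$converged,
      loglik = fit$loglik, coefficients = as.list(coef(fit)),
      sigma2_between = fit$sigma2_between,
      sigma2_within = fit$sigma2_within, rho = fit$rho,
      wald_fixed = fit$wald_fixed, wald_random = fit$wald_random),
      file.path(out_dir, sprintf("fit_%s.json", tr)),
      auto_unbox = TRUE, digits = NA)
  }
  if (length(fits) > 0L) {
    utils::write.csv(effect_table(fits),
                     file.path(out_dir, "effects.csv"), row.names = FALSE)
  }

  ## partial budget: annual changes from the fitted marginal means when
  ## available, otherwise the configured/base values
  budget_args <- if (!is.null(config$budget)) config$budget else list()
  if (!is.null(budget_args$traits)) {
    budget_args$traits <- as.data.frame(budget_args$traits)
  }
  inputs <- do.call(budget_inputs, budget_args)
  for (tr in c("DO", "DMY")) {
    if (!is.null(means_tables[[tr]]) &&
        "MEDIUM" %in% means_tables[[tr]]$adoption_level) {
      sl <- tryCatch(annual_change_from_means(means_tables[[tr]]),
                     error = function(e) NULL)
      if (!is.null(sl)) {
        inputs$traits$annual_change[inputs$traits$trait == tr] <- sl
        log_lines <- c(log_lines, sprintf(
          "budget: %s annual change from marginal means: %.4f", tr, sl))
      }
    }
  }
  budget <- stage("budget", budget_evaluate(inputs))
  jsonlite::write_json(list(
    cost_lines = as.list(budget$cost_lines),
    delta_cost = budget$delta_cost,
    income_by_trait = as.list(budget$income_by_trait),
    delta_income = budget$delta_income,
    gross_margin = budget$gross_margin,
    marginal_return_rate = budget$marginal_return_rate,
    break_even_herd_size = break_even_herd_size(inputs)),
    file.path(out_dir, "budget.json"), auto_unbox = TRUE, digits = NA)

  sens_cfg <- config$sensitivity
  perturbation <- if (!is.null(sens_cfg$perturbation)) {
    sens_cfg$perturbation
  } else 0.10
  n_draws <- if (!is.null(sens_cfg$n_draws)) sens_cfg$n_draws else 10000
  scen <- stage("scenarios", scenario_table(inputs, perturbation))
  utils::write.csv(as.data.frame(scen),
                   file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  mc <- stage("monte_carlo", monte_carlo(inputs, n_draws = n_draws,
                                         seed = seed))
  utils::write.csv(mc$correlations,
                   file.path(out_dir, "mc_correlations.csv"),
                   row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  ## run.log carries wall-clock timings, so it is not part of the
  ## reproducibility hash set
  files <- setdiff(list.files(out_dir), c("manifest.json", "run.log"))
  manifest <- list(
    seed = seed,
    config = config,
    created = "run",
    n_events = nrow(events),
    n_herds = length(unique(events$herd_id)),
    n_trait_rows = nrow(traits),
    traits_fitted = names(fits),
    gross_margin = budget$gross_margin,
    marginal_return_rate = budget$marginal_return_rate,
    files = as.list(tools::md5sum(file.path(out_dir, sort(files))))
  )
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## Published reference cells for the facsimile report.
TABLE4_EXPECTED <- list(income_DO = 1097, income_DMY = 10013,
                        delta_income = 11110, gross_margin = 6890,
                        mrr = 163.3, break_even = 17)
TABLE5_EXPECTED <- data.frame(
  varied_input = rep(c("dmy_change", "do_change", "herd_size",
                       "entry_cost", "collection_cost"), each = 2),
  direction = rep(c("-10%", "+10%"), 5),
  gm = c(5889, 7892, 7000, 6781, 6061, 7719, 7078, 6703, 6984, 6796),
  mrr = c(139.6, 187.0, 165.9, 160.7, 153.9, 171.5, 175.6, 152.1,
          169.3, 157.6),
  stringsAsFactors = FALSE)

#' Reproduce the published budget tables
#'
#' Recomputes the base partial budget, the +/-10% scenario table and the
#' break-even herd size from the packaged default inputs and compares each
#' cell against the published reference values, flagging any cell that
#' deviates beyond tolerance (±$10 on currency, ±0.5 percentage points on
#' rates). The hardware+software scenario row is reported but not
#' compared (its published cells are internally inconsistent).
#'
#' @param inputs base inputs (default [budget_inputs()]).
#' @param tol_currency,tol_rate comparison tolerances.
#' @return A list with `budget` (the base evaluation), `scenarios`, the
#'   `break_even` size, and `flags`: a data frame of all compared cells
#'   with expected/actual values and an `ok` column.
#' @export
reproduce_tables <- function(inputs = budget_inputs(), tol_currency = 10,
                             tol_rate = 0.5) {
  budget <- budget_evaluate(inputs)
  scen <- scenario_table(inputs)
  be <- break_even_herd_size(inputs)
  flags <- list()
  add <- function(cell, expected, actual, tol) {
    flags[[length(flags) + 1L]] <<- data.frame(
      cell = cell, expected = expected, actual = actual,
      ok = is.finite(actual) && abs(actual - expected) <= tol,
      stringsAsFactors = FALSE)
  }
  add("income_DO", TABLE4_EXPECTED$income_DO,
      unname(budget$income_by_trait["DO"]), tol_currency)
  add("income_DMY", TABLE4_EXPECTED$income_DMY,
      unname(budget$income_by_trait["DMY"]), tol_currency)
  add("delta_income", TABLE4_EXPECTED$delta_income, budget$delta_income,
      tol_currency)
  add("gross_margin", TABLE4_EXPECTED$gross_margin, budget$gross_margin,
      tol_currency)
  add("mrr", TABLE4_EXPECTED$mrr, budget$marginal_return_rate, tol_rate)
  add("break_even", TABLE4_EXPECTED$break_even, as.numeric(be), 0)
  for (i in seq_len(nrow(TABLE5_EXPECTED))) {
    e <- TABLE5_EXPECTED[i, ]
    row <- scen[scen$varied_input == e$varied_input &
                  scen$direction == e$direction, ]
    add(paste0("scenario_", e$varied_input, "_", e$direction, "_gm"),
        e$gm, row$gross_margin, tol_currency)
    add(paste0("scenario_", e$varied_input, "_", e$direction, "_mrr"),
        e$mrr, row$mrr, tol_rate)
  }
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  list(budget = budget, scenarios = scen, break_even = be, flags = flags)
}
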