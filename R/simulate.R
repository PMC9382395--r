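#' Define a simulation scenario
#'
#' One cell of the factorial Monte Carlo design: training set size, number of
#' predictors, event fraction, replication count, and the common test set
#' size. The generating mechanism for the cell is calibrated to `cstat`.
#'
#' @param n_train Training set size (the study grid uses 2500 and 5000).
#' @param p Number of predictors (grid: 3, 6, 12, 24).
#' @param event_fraction Marginal event fraction in (0, 0.5] (grid: 0.3, 0.1,
#'   0.01).
#' @param n_reps Number of Monte Carlo replicates (full study: 2000).
#' @param n_test Size of the scenario's single fixed test set (full study:
#'   100000).
#' @param cstat Target c-statistic of the generating mechanism.
#' @param base_seed Integer base seed; all randomness in the scenario derives
#'   from it.
#' @param scenario_id Integer id used in seed derivation; defaults to the
#'   cell's position in the canonical 24-cell grid when it lies on the grid.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_train, p, event_fraction, n_reps = 2000,
                            n_test = 100000, cstat = 0.75, base_seed = 1,
                            scenario_id = NULL) {
  stopifnot(event_fraction > 0, event_fraction <= 0.5, n_reps >= 1,
            n_test >= n_train)
  if (is.null(scenario_id)) scenario_id <- canonical_scenario_id(n_train, p, event_fraction)
  structure(list(n_train = as.integer(n_train), p = as.integer(p),
                 event_fraction = event_fraction, n_reps = as.integer(n_reps),
                 n_test = as.integer(n_test), cstat = cstat,
                 base_seed = as.integer(base_seed),
                 scenario_id = as.integer(scenario_id)),
            class = "scenario_config")
}

canonical_scenario_id <- function(n_train, p, event_fraction) {
  i_n <- match(n_train, c(2500L, 5000L))
  i_p <- match(p, c(3L, 6L, 12L, 24L))
  i_e <- match(event_fraction, c(0.3, 0.1, 0.01))
  if (anyNA(c(i_n, i_p, i_e)))
    return(as.integer((n_train + 7L * p + round(1e4 * event_fraction)) %% 9973L) + 24L)
  (i_n - 1L) * 12L + (i_p - 1L) * 3L + i_e
}

#' @rdname scenario_config
#' @param n_train_values,p_values,event_fractions Factor levels of the grid;
#'   the defaults reproduce the full 24-scenario factorial design.
#' @param ... Passed on to `scenario_config()`.
#' @export
scenario_grid <- function(n_train_values = c(2500, 5000),
                          p_values = c(3, 6, 12, 24),
                          event_fractions = c(0.3, 0.1, 0.01), ...) {
  cells <- expand.grid(event_fraction = event_fractions, p = p_values,
                       n_train = n_train_values)
  lapply(seq_len(nrow(cells)), function(i)
    scenario_config(cells$n_train[i], cells$p[i], cells$event_fraction[i], ...))
}

# Deterministic per-(scenario, replicate) seed stream; replicate 0 is the
# scenario's fixed test set. Stays below 2^31 and is exact in doubles.
derive_seed <- function(base_seed, scenario_id, replicate) {
  ((base_seed %% 1000003) * 1873 + scenario_id * 131071 + replicate * 8191) %%
    2147483629 + 1
}

# fixed-schema metric row used by the engine (ef_threshold = NULL skips the
# event-fraction threshold columns)
evaluate_record <- function(probs, y, ef_threshold = NULL) {
  cs <- calibration_slope(probs, y)
  row <- list(auroc = auroc(probs, y),
              cal_intercept = calibration_intercept(probs, y),
              cal_slope = unname(cs["slope"]))
  cm <- classification_metrics(probs, y, 0.5)
  row$acc_t50 <- cm$accuracy; row$sens_t50 <- cm$sensitivity
  row$spec_t50 <- cm$specificity
  row$nb_t50 <- (cm$tp - 0.5 / 0.5 * cm$fp) / cm$n
  if (!is.null(ef_threshold)) {
    cm <- classification_metrics(probs, y, ef_threshold)
    row$acc_tef <- cm$accuracy; row$sens_tef <- cm$sensitivity
    row$spec_tef <- cm$specificity
    row$nb_tef <- (cm$tp - ef_threshold / (1 - ef_threshold) * cm$fp) / cm$n
  } else {
    row$acc_tef <- NA_real_; row$sens_tef <- NA_real_
    row$spec_tef <- NA_real_; row$nb_tef <- NA_real_
  }
  row
}

METRIC_COLS <- c("auroc", "cal_intercept", "cal_slope",
                 "acc_t50", "sens_t50", "spec_t50", "nb_t50",
                 "acc_tef", "sens_tef", "spec_tef", "nb_tef")

empty_metrics <- stats::setNames(as.list(rep(NA_real_, length(METRIC_COLS))),
                                 METRIC_COLS)

#' Run one Monte Carlo replicate of a scenario
#'
#' Generates a fresh training dataset, builds the requested training variants
#' (uncorrected, RUS, ROS, SMOTE), fits the requested models on each, applies
#' intercept recalibration (on the original imbalanced training data) to the
#' models trained on corrected data, and evaluates everything on the
#' scenario's fixed test set. With all four corrections and both models this
#' yields 14 performance records: 8 fitted models plus 6 recalibrated ones.
#'
#' Classification metrics are computed at threshold 0.5 for every model and
#' additionally at a threshold equal to the true event fraction for models
#' trained on uncorrected data. Fit failures are recorded (with `error` set)
#' and the remaining models are still evaluated.
#'
#' @param config A [scenario_config()].
#' @param replicate Replicate number (1-based).
#' @param coefs Generator coefficients for the scenario
#'   ([calibrate_generator()]).
#' @param test The scenario's fixed test set ([imb_data]).
#' @param corrections Subset of `c("none", "rus", "ros", "smote")`.
#' @param models Subset of `c("slr", "ridge")`.
#' @param recalibrate Recalibrate models trained on corrected data?
#' @param k SMOTE neighbor count.
#' @return A data frame with one row per performance record.
#' @export
run_replicate <- function(config, replicate, coefs, test,
                          corrections = c("none", "rus", "ros", "smote"),
                          models = c("slr", "ridge"), recalibrate = TRUE,
                          k = 5) {
  set.seed(derive_seed(config$base_seed, config$scenario_id, replicate))
  train <- generate_dataset(config$n_train, coefs)
  rows <- list()
  add_row <- function(correction, model, recalibrated, converged, separation,
                      error, metrics) {
    rows[[length(rows) + 1L]] <<- c(
      list(replicate = replicate, correction = correction, model = model,
           recalibrated = recalibrated, converged = converged,
           separation = separation, error = error),
      metrics)
  }

  for (correction in corrections) {
    dtrain <- tryCatch(rebalance(train, correction, k = k),
                       error = function(e) e)
    if (inherits(dtrain, "error")) {
      for (model in models)
        add_row(correction, model, FALSE, NA, NA,
                conditionMessage(dtrain), empty_metrics)
      next
    }
    ef_thr <- if (correction == "none") config$event_fraction else NULL
    for (model in models) {
      fit <- tryCatch(
        fit_logit(dtrain, penalty = if (model == "ridge") "ridge" else "none"),
        error = function(e) e)
      if (inherits(fit, "error")) {
        add_row(correction, model, FALSE, NA, NA,
                conditionMessage(fit), empty_metrics)
        if (recalibrate && correction != "none")
          add_row(correction, model, TRUE, NA, NA,
                  conditionMessage(fit), empty_metrics)
        next
      }
      lp <- predict(fit, test, type = "link")
      add_row(correction, model, FALSE, fit$converged, fit$separation, NA_character_,
              evaluate_record(clip_prob(stats::plogis(lp)), test$y, ef_thr))
      if (recalibrate && correction != "none") {
        a <- offset_intercept_mle(predict(fit, train, type = "link"), train$y)
        pr <- clip_prob(stats::plogis(lp + a))
        add_row(correction, model, TRUE, fit$converged, fit$separation,
                NA_character_, evaluate_record(pr, test$y, NULL))
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Run a full scenario and summarize it
#'
#' Calibrates the generating mechanism for the cell, simulates the scenario's
#' single fixed test set, runs `n_reps` replicates with independent derived
#' seed streams, and aggregates medians and quartiles per
#' (correction, model, recalibrated) cell. Replicates that fail are tallied
#' and excluded from the summaries.
#'
#' @inheritParams run_replicate
#' @param keep_replicates Attach the raw per-replicate records?
#' @param replicate_file Optional CSV path: records are appended as each
#'   replicate finishes, and already-present replicates are not recomputed, so
#'   interrupted runs resume.
#' @param verbose Print progress every 50 replicates?
#' @return A `scenario_summary` object: the config, generator coefficients, a
#'   long summary table (one row per cell and metric, with `median`, `q1`,
#'   `q3`, `n`, `n_separation`, `n_error`), and optionally the raw records.
#' @examples
#' \donttest{
#' cfg <- scenario_config(500, 3, 0.3, n_reps = 5, n_test = 5000, base_seed = 7)
#' s <- run_scenario(cfg, corrections = c("none", "rus"), models = "slr")
#' head(s$summary)
#' }
#' @export
run_scenario <- function(config, corrections = c("none", "rus", "ros", "smote"),
                         models = c("slr", "ridge"), recalibrate = TRUE, k = 5,
                         keep_replicates = FALSE, replicate_file = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  coefs <- calibrate_generator(config$p, config$event_fraction, config$cstat)
  test <- generate_dataset(config$n_test, coefs,
                           seed = derive_seed(config$base_seed,
                                              config$scenario_id, 0))
  done <- NULL
  if (!is.null(replicate_file) && file.exists(replicate_file)) {
    done <- utils::read.csv(replicate_file)
    done$error <- as.character(done$error)
  }
  done_ids <- if (is.null(done)) integer(0) else unique(done$replicate)

  chunks <- list()
  for (r in seq_len(config$n_reps)) {
    if (r %in% done_ids) next
    rec <- run_replicate(config, r, coefs, test, corrections, models,
                         recalibrate, k)
    chunks[[length(chunks) + 1L]] <- rec
    if (!is.null(replicate_file))
      utils::write.table(rec, replicate_file, sep = ",", append = file.exists(replicate_file),
                         col.names = !file.exists(replicate_file), row.names = FALSE)
    if (verbose && r %% 50 == 0)
      message(sprintf("scenario %d: replicate %d/%d", config$scenario_id, r,
                      config$n_reps))
  }
  records <- do.call(rbind, c(list(done), chunks))
  records <- records[records$replicate <= config$n_reps, , drop = FALSE]

  out <- structure(list(config = config, coefs = coefs,
                        summary = summarize_records(records, config),
                        n_records = nrow(records)),
                   class = "scenario_summary")
  if (keep_replicates) out$records <- records
  out
}

summarize_records <- function(records, config) {
  cells <- unique(records[c("correction", "model", "recalibrated")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$correction == cells$correction[i] &
      records$model == cells$model[i] &
      records$recalibrated == cells$recalibrated[i]
    sub <- records[sel, , drop = FALSE]
    ok <- is.na(sub$error)
    for (m in METRIC_COLS) {
      v <- sub[[m]][ok]
      v <- v[!is.na(v)]
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
           else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_id = config$scenario_id, n_train = config$n_train,
        p = config$p, event_fraction = config$event_fraction,
        correction = cells$correction[i], model = cells$model[i],
        recalibrated = cells$recalibrated[i], metric = m,
        median = q[2], q1 = q[1], q3 = q[3], n = length(v),
        n_separation = sum(sub$separation[ok], na.rm = TRUE),
        n_error = sum(!ok))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.scenario_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<scenario_summary> id %d: n_train = %d, p = %d, event fraction = %.2f\n",
              cfg$scenario_id, cfg$n_train, cfg$p, cfg$event_fraction))
  cat(sprintf("  %d replicates, test n = %d\n", cfg$n_reps, cfg$n_test))
  ci <- x$summary[x$summary$metric == "cal_intercept", ]
  print(ci[order(ci$correction, ci$model, ci$recalibrated),
           c("correction", "model", "recalibrated", "median", "q1", "q3",
             "n_separation", "n_error")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a grid of scenarios
#'
#' @param grid A list of [scenario_config()]s (see [scenario_grid()]).
#' @param ... Passed to [run_scenario()].
#' @param result_dir Optional directory: each scenario's summary table is
#'   written to `scenario_<id>.csv` and finished scenarios are skipped on
#'   rerun, so grids are resumable.
#' @return A list of `scenario_summary` objects (or, for scenarios restored
#'   from `result_dir`, their summary tables).
#' @export
run_grid <- function(grid, ..., result_dir = NULL) {
  lapply(grid, function(cfg) {
    if (!is.null(result_dir)) {
      f <- file.path(result_dir, sprintf("scenario_%d.csv", cfg$scenario_id))
      if (file.exists(f)) return(utils::read.csv(f))
      s <- run_scenario(cfg, ...)
      dir.create(result_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(s$summary, f, row.names = FALSE)
      s
    } else run_scenario(cfg, ...)
  })
}

#' Run the desk-scale reduced factorial study
#'
#' A preset subset of the full factorial design sized for a single CPU:
#' `n_train` in \{2500, 5000\} crossed with `p` in \{3, 24\} and all three
#' event fractions (12 cells), models fitted on uncorrected training data
#' (SLR and Ridge); plus, for the three `n_train = 5000, p = 3` cells, Ridge
#' models after RUS, ROS and SMOTE together with their intercept-recalibrated
#' versions. Training sets and test sets are shared between the two passes
#' through the seed-stream protocol, so the corrected models are fit on the
#' same data as the uncorrected ones.
#'
#' @param base_seed Integer base seed.
#' @param n_reps Replicates per scenario (default 200).
#' @param n_test Fixed test-set size per scenario (default 50000).
#' @param verbose Progress messages.
#' @return A list with long-format summary tables `uncorrected` (12 cells)
#'   and `corrected` (3 cells).
#' @export
run_reduced_study <- function(base_seed = 1, n_reps = 200, n_test = 50000,
                              verbose = FALSE) {
  grid <- scenario_grid(n_train_values = c(2500, 5000), p_values = c(3, 24),
                        n_reps = n_reps, n_test = n_test,
                        base_seed = base_seed)
  unc <- lapply(grid, run_scenario, corrections = "none",
                models = c("slr", "ridge"), verbose = verbose)
  corr_grid <- scenario_grid(n_train_values = 5000, p_values = 3,
                             n_reps = n_reps, n_test = n_test,
                             base_seed = base_seed)
  corr <- lapply(corr_grid, run_scenario,
                 corrections = c("rus", "ros", "smote"), models = "ridge",
                 recalibrate = TRUE, verbose = verbose)
  list(uncorrected = summarize_to_table(unc),
       corrected = summarize_to_table(corr))
}

#' Bind scenario summaries into one long results table
#'
#' @param summaries A list of `scenario_summary` objects and/or summary data
#'   frames (as produced by [run_grid()]).
#' @return A long-format data frame: scenario factors, correction, model,
#'   recalibrated flag, metric, median, quartiles and error counts.
#' @export
summarize_to_table <- function(summaries) {
  if (inherits(summaries, "scenario_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s)
    if (inherits(s, "scenario_summary")) s$summary else s))
}
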