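# Dataset IO with strict schema validation, run configuration, and
# end-to-end orchestration: schedule -> simulate (or load) -> fit -> compare
# -> validate -> behavioural stats, with a JSON manifest of seeds and file
# hashes.

DATASET_COLUMNS <- c("subject_id", "trial", "recipient", "effort_level",
                     "work_shocks", "choice", "rt_s", "force_auc", "success",
                     "delivered_shocks")

validate_dataset <- function(data) {
  abort_if(!is.data.frame(data), "dataset must be a data frame")
  missing_cols <- setdiff(DATASET_COLUMNS, names(data))
  abort_if(length(missing_cols) > 0,
           "dataset is missing columns: ", paste(missing_cols, collapse = ", "))
  fail <- function(rows, what) {
    abort_if(length(rows) > 0, "invalid dataset: ", what, " at row(s) ",
             paste(head(rows, 10), collapse = ", "),
             if (length(rows) > 10) " ..." else "")
  }
  fail(which(!data$recipient %in% c("self", "other")),
       "recipient not in {self, other}")
  fail(which(!data$choice %in% c("work", "rest", "nonresponse")),
       "choice not in {work, rest, nonresponse}")
  fail(which(!data$effort_level %in% 1:5), "effort_level outside 1..5")
  fail(which(!data$work_shocks %in% 1:5),
       "work_shocks outside 1..5 (must stay below the 6-shock rest offer)")
  fail(which(!data$delivered_shocks %in% c(1:5, 6L, 10L)),
       "delivered_shocks outside the task contingency {work_shocks, 6, 10}")
  fail(which(data$choice == "work" & is.na(data$force_auc)),
       "work choice without force_auc")
  fail(which(data$choice != "work" & !is.na(data$force_auc)),
       "force_auc present on a non-work trial")
  fail(which(data$choice == "rest" & data$delivered_shocks != 6L),
       "rest choice must deliver 6 shocks")
  fail(which(data$choice == "nonresponse" & data$delivered_shocks != 10L),
       "nonresponse must deliver the 10-shock penalty")
  ok_work <- data$choice != "work" | is.na(data$success) |
    (data$success & data$delivered_shocks == data$work_shocks) |
    (!data$success & data$delivered_shocks == 10L)
  fail(which(!ok_work), "work-trial delivered_shocks inconsistent with success")
  invisible(data)
}

#' Read / write trial-level datasets as CSV
#'
#' Plain UTF-8 comma-separated files with "." decimals, matching how
#' behavioural datasets are usually deposited. Reading applies the full
#' schema validation (column set, categorical levels, range checks, and the
#' delivered-shock contingency) and reports offending row numbers;
#' write-then-read is an identity on valid data.
#'
#' @param path CSV file path.
#' @param data A dataset data frame (see [simulate_dataset()] for the
#'   schema).
#' @return `read_dataset` returns a validated `ep_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if ("success" %in% names(raw)) raw$success <- as.logical(raw$success)
  validate_dataset(raw)
  class(raw) <- c("ep_dataset", "data.frame")
  raw
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  write.csv(data[DATASET_COLUMNS], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param n_per_recipient Trials per recipient for the generated schedule.
#' @param population An [population_config()] for the synthetic cohort
#'   (ignored when `data_csv` is given).
#' @param data_csv Optional path to an existing dataset CSV to analyse
#'   instead of simulating.
#' @param models Character vector of model names to fit (see
#'   [model_catalog()]).
#' @param sampler An [sampler_config()].
#' @param n_ppc_reps Posterior predictive replicates for the winning model.
#' @param seed Top-level seed; every random stage receives a derived,
#'   logged sub-seed.
#' @return A `ep_run_config` list.
#' @export
run_config <- function(n_per_recipient = 75,
                       population = population_config(),
                       data_csv = NULL,
                       models = c("parabolic_1k1b", "parabolic_2k1b"),
                       sampler = sampler_config(),
                       n_ppc_reps = 100,
                       seed = 1) {
  abort_if(!all(models %in% model_catalog()),
           "unknown model name(s): ",
           paste(setdiff(models, model_catalog()), collapse = ", "))
  structure(
    list(n_per_recipient = n_per_recipient, population = population,
         data_csv = data_csv, models = models, sampler = sampler,
         n_ppc_reps = n_ppc_reps, seed = as.integer(seed)),
    class = "ep_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()]; `population` and
#' `sampler` may be nested maps with the corresponding constructor
#' arguments (the population model is given by name).
#'
#' @param path YAML file path.
#' @return A `ep_run_config`.
#' @export
read_run_config <- function(path) {
  abort_if(!requireNamespace("yaml", quietly = TRUE),
           "reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  pop_args <- y$population %||% list()
  if (!is.null(pop_args$model)) pop_args$model <- model_spec(pop_args$model)
  samp_args <- y$sampler %||% list()
  run_config(
    n_per_recipient = y$n_per_recipient %||% 75,
    population = do.call(population_config, pop_args),
    data_csv = y$data_csv,
    models = y$models %||% c("parabolic_1k1b", "parabolic_2k1b"),
    sampler = do.call(sampler_config, samp_args),
    n_ppc_reps = y$n_ppc_reps %||% 100,
    seed = y$seed %||% 1)
}

# deterministic sub-seed per stage, derived from the top-level seed and
# kept below 2^31
derive_seed <- function(seed, stage) {
  (seed * 7919 + sum(utf8ToInt(stage)) * 104729) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Executes: schedule generation -> dataset simulation (or CSV load) ->
#' fitting of every requested model -> LOOIC comparison -> posterior
#' predictive check of the winning model -> behavioural summaries and
#' self-vs-other Bayes factors. All artifacts are written under `out_dir`
#' and a manifest records the package version, derived stage seeds and file
#' hashes.
#'
#' @param config A [run_config()] (or [read_run_config()] result).
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the in-memory artifacts (`schedule`, `data`,
#'   `fits`, `comparison`, `ppc`, `behavior`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  abort_if(!inherits(config, "ep_run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sapply(c("schedule", "population", "simulate", "fit", "ppc"),
                  function(s) derive_seed(config$seed, s))
  message("[schedule] generating ", 2 * config$n_per_recipient, " trials")
  schedule <- generate_schedule(config$n_per_recipient,
                                seed = seeds[["schedule"]])
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))

  if (is.null(config$data_csv)) {
    message("[simulate] cohort of ", config$population$n_subjects,
            " agents from ", config$population$model$name)
    agents <- sample_population(config$population,
                                seed = seeds[["population"]])
    data <- simulate_dataset(agents, schedule, config$population,
                             seed = seeds[["simulate"]])
    write.csv(agents, file.path(out_dir, "truth.csv"), row.names = FALSE)
  } else {
    message("[load] ", config$data_csv)
    data <- read_dataset(config$data_csv)
    agents <- NULL
  }
  write_dataset(data, file.path(out_dir, "data.csv"))

  fits <- list()
  for (m in config$models) {
    message("[fit] ", m)
    samp <- config$sampler
    samp$seed <- derive_seed(seeds[["fit"]], m)
    fit <- fit_model(data, model_spec(m), sampler = samp)
    if (!fit$converged) {
      message("[fit] warning: ", m, " max R-hat = ", round(fit$max_rhat, 3))
    }
    fits[[m]] <- fit
    post <- subject_posterior(fit)
    write.csv(post, file.path(out_dir, paste0("fit_", m, "_subjects.csv")),
              row.names = FALSE)
    diag_json <- list(model = m, max_rhat = fit$max_rhat,
                      converged = fit$converged,
                      n_nonresponse = fit$n_nonresponse,
                      group_posterior_mean = as.list(colMeans(fit$group_draws)))
    jsonlite::write_json(diag_json,
                         file.path(out_dir, paste0("fit_", m, "_diag.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  message("[compare] ", length(fits), " model(s)")
  comparison <- compare_models(fits)
  jsonlite::write_json(
    list(table = comparison$table,
         shares = as.list(comparison$shares),
         best_model_per_subject = as.list(comparison$best_model_per_subject),
         note = comparison$note),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)

  winner <- comparison$table$model[1]
  message("[validate] posterior predictive check of ", winner)
  ppc <- posterior_predictive(fits[[winner]], n_reps = config$n_ppc_reps,
                              seed = seeds[["ppc"]])
  write.csv(as.data.frame(ppc), file.path(out_dir, "ppc_cells.csv"),
            row.names = FALSE)

  message("[stats] behavioural summaries and Bayes factors")
  behavior <- summarize_behavior(data)
  wide <- behavior$per_subject
  tests <- lapply(c("work_choice_rate", "mean_rt_s", "mean_force_auc",
                    "success_rate"), function(m) {
    s <- wide[wide$recipient == "self", m][order(
      wide$subject_id[wide$recipient == "self"])]
    o <- wide[wide$recipient == "other", m][order(
      wide$subject_id[wide$recipient == "other"])]
    ok <- is.finite(s) & is.finite(o)
    bf <- jzs_paired_bf(s[ok], o[ok])
    c(list(measure = m), bf)
  })
  jsonlite::write_json(
    list(group = behavior$group, paired_tests = tests),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("effortpain")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    models = config$models,
    winner = winner,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(schedule = schedule, data = data, agents = agents,
                 fits = fits, comparison = comparison, ppc = ppc,
                 behavior = behavior, manifest = manifest))
}
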