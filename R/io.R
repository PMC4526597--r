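# File I/O and pipeline orchestration: CSV trial logs, JSON configuration,
# deterministic seed expansion, and the end-to-end analysis pipeline with a
# run manifest.

TRIALS_COLUMNS <- c("subject", "game", "trial", "phase", "stabilized",
                    "action", "transition", "second_state", "reward",
                    "devalued_game")

#' Write / read trial records as CSV
#'
#' One row per trial record; hidden rewards are written as empty fields
#' and absent second-stage states as empty strings. Reading validates the
#' schema and reports violations with file line numbers.
#'
#' @param trials trial records data frame.
#' @param path file path.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(TRIALS_COLUMNS %in% names(trials)))
  out <- trials[, TRIALS_COLUMNS]
  out$reward <- ifelse(is.na(out$reward), "", as.character(out$reward))
  out$second_state <- ifelse(is.na(out$second_state), "", out$second_state)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("no trials in ", path, call. = FALSE)
  missing_cols <- setdiff(TRIALS_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  fail <- function(cond, what) {
    if (any(cond))
      stop("invalid ", what, " at line(s) ",
           paste(utils::head(line[cond], 5), collapse = ", "), " of ", path,
           call. = FALSE)
  }
  fail(!raw$phase %in% c("training", "nofeedback", "test"), "phase label")
  fail(!raw$action %in% c("left", "right", "none"), "action label")
  fail(!raw$transition %in% c("common", "rare", "none"), "transition label")
  fail(!raw$reward %in% c("", "0", "1"), "reward value")
  fail(!raw$devalued_game %in% c("TRUE", "FALSE", "NA"), "devalued_game flag")
  fail(is.na(suppressWarnings(as.integer(raw$trial))), "trial index")
  data.frame(
    subject = utils::type.convert(raw$subject, as.is = TRUE),
    game = raw$game, trial = as.integer(raw$trial), phase = raw$phase,
    stabilized = as.logical(raw$stabilized), action = raw$action,
    transition = raw$transition,
    second_state = ifelse(raw$second_state == "", NA_character_,
                          raw$second_state),
    reward = ifelse(raw$reward == "", NA_integer_, as.integer(raw$reward)),
    devalued_game = as.logical(raw$devalued_game),
    stringsAsFactors = FALSE)
}

CONFIG_FIELDS <- c("experiment", "p_common", "walk_sd", "walk_bounds",
                   "reward_value", "response_cost", "n_training",
                   "n_stabilized", "stabilized_probs", "n_nofeedback",
                   "n_test", "response_window", "max_run_length")

#' Write / read a task configuration as JSON
#'
#' The JSON schema covers exactly the [task_config()] arguments; unknown
#' keys are rejected and the reconstructed configuration is re-validated.
#'
#' @param config a [task_config()].
#' @param path file path.
#' @return `read_config()` returns a validated `task_config`.
#' @export
write_config <- function(config, path) {
  validate_task_config(config)
  fields <- config[intersect(CONFIG_FIELDS, names(config))]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), CONFIG_FIELDS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$experiment)) stop("configuration must name an experiment",
                                    call. = FALSE)
  if (!is.null(raw$stabilized_probs) && is.null(names(raw$stabilized_probs)))
    names(raw$stabilized_probs) <- c("devalued", "valued")
  do.call(task_config, raw)
}

#' Deterministic child seeds
#'
#' Expands one master seed into per-stage seeds by a fixed counter scheme,
#' `child_seed(seed, k) = ((seed - 1 + k * 10007) mod (2^31 - 2)) + 1`,
#' so any stage can be rerun in isolation with the same stream.
#'
#' @param seed master integer seed.
#' @param stage stage counter (1, 2, ...).
#' @return Integer seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) - 1 + as.numeric(stage) * 10007) %%
                2147483646) + 1)
}

#' Run the full simulate-analyze-fit pipeline
#'
#' Executes cohort generation, subject summaries and exclusions, the
#' lagged stay design and mixed model, the index analysis, and optionally
#' a likelihood-based fit, writing every table plus a run manifest to
#' `out_dir`. Any stage failure aborts with the stage name; tables written
#' by earlier stages are preserved.
#'
#' @param config a [task_config()] or path to a config JSON.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stages use [child_seed()] streams.
#' @param n_subjects cohort size.
#' @param spec a [cohort_spec()].
#' @param engine stay-model engine, `"twostage"` or `"glmer"`.
#' @param fit `"none"`, `"mle"`, or `"hier"`.
#' @param fit_profile MCMC profile for `fit = "hier"` (`"ci"` or
#'   `"full"`).
#' @param deval_link,omission_rate passed to [generate_cohort()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, n_subjects = 90,
                         spec = cohort_spec(),
                         engine = c("twostage", "glmer"),
                         fit = c("none", "mle", "hier"),
                         fit_profile = "ci",
                         deval_link = "model", omission_rate = 0) {
  engine <- match.arg(engine)
  fit <- match.arg(fit)
  if (is.character(config)) config <- read_config(config)
  validate_task_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  cohort <- stage("simulate", {
    co <- generate_cohort(n_subjects, config, spec = spec,
                          seed = child_seed(seed, 1),
                          deval_link = deval_link,
                          omission_rate = omission_rate)
    write_trials(co$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(co$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    co
  })

  metrics <- stage("metrics", {
    summaries <- subject_summaries(cohort)
    excl <- apply_exclusions(summaries)
    utils::write.csv(summaries, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(excl$report, file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(summaries = summaries, exclusions = excl)
  })
  retained <- metrics$exclusions$retained
  deval_z <- stats::setNames(zscore(retained$deval_sensitivity),
                             retained$subject)
  kept_trials <- cohort$trials[cohort$trials$subject %in% retained$subject, ]

  stay <- stage("stay_regression", {
    design <- build_lagged_design(kept_trials)
    fit_m <- fit_mixed_stay_model(design, deval_z, engine = engine)
    utils::write.csv(fit_m$terms, file.path(out_dir, "regression.csv"),
                     row.names = FALSE)
    list(design = design, fit = fit_m)
  })

  index_model <- stage("indices", {
    idx <- per_subject_indices(
      stay$design, method = if (engine == "glmer") "ranef" else "independent")
    dl <- predict_devaluation(
      idx, stats::setNames(retained$deval_sensitivity, retained$subject))
    utils::write.csv(idx, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(dl$terms, file.path(out_dir, "deval_model.csv"),
                     row.names = FALSE)
    list(indices = idx, model = dl)
  })

  rl_fit <- stage("rl_fit", {
    res <- switch(fit,
      none = list(engine = "none"),
      mle = {
        est <- fit_mle_cohort(kept_trials, config, seed = child_seed(seed, 5))
        list(engine = "mle", estimates = est)
      },
      hier = {
        hf <- fit_hierarchical(kept_trials, deval_z, config,
                               profile = fit_profile,
                               seed = child_seed(seed, 5))
        list(engine = "hier", b_summary = hf$b_summary, group = hf$group,
             subject = hf$subject, status = hf$status)
      })
    jsonlite::write_json(res, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    res
  })

  manifest <- list(
    package = "habitlearn",
    version = as.character(utils::packageVersion("habitlearn")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[intersect(CONFIG_FIELDS, names(config))],
    config_hash = rlang::hash(config[intersect(CONFIG_FIELDS,
                                               names(config))]),
    seed = seed,
    child_seeds = stats::setNames(lapply(1:5, child_seed, seed = seed),
                                  c("simulate", "metrics", "stay_regression",
                                    "indices", "rl_fit")),
    n_subjects = n_subjects, engine = engine, fit = fit,
    deval_link = deval_link, omission_rate = omission_rate,
    outputs = list.files(out_dir),
    timings_sec = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, metrics = metrics, stay = stay,
                 indices = index_model, rl_fit = rl_fit,
                 manifest = manifest, out_dir = out_dir))
}
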