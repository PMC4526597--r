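#' Parameters of a hybrid model-based / model-free agent
#'
#' @param alpha learning rate in \[0, 1\].
#' @param beta softmax inverse temperature, >= 0.
#' @param w model-based weight in \[0, 1\]: `w = 0` is a pure model-free
#'   agent, `w = 1` pure model-based.
#' @param pi perseveration strength (stickiness bonus added to the logit of
#'   repeating the previous same-game choice; any real).
#' @param beta_resp respond/withhold inverse temperature for the Exp 1
#'   test and no-feedback phases, >= 0.
#' @param resp_bias respond/withhold offset (real).
#' @param lambda eligibility blending of the first-stage model-free update
#'   target: `lambda = 1` (default) sends the terminal reward straight to
#'   the first-stage cache; smaller values blend in the second-stage value.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha, beta, w, pi = 0, beta_resp = 60,
                         resp_bias = -3.5, lambda = 1) {
  p <- list(alpha = alpha, beta = beta, w = w, pi = pi,
            beta_resp = beta_resp, resp_bias = resp_bias, lambda = lambda)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (w < 0 || w > 1) stop("w must be in [0, 1]", call. = FALSE)
  if (beta_resp < 0) stop("beta_resp must be >= 0", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  structure(p, class = "agent_params")
}

#' Initial internal state of an agent
#'
#' Cached first-stage values `q_mf` (one row per game, columns left/right)
#' and second-stage state values `v2` start at 0.5, the midpoint of the
#' reward-probability bounds; no previous action; all outcomes valued.
#'
#' @param config a [task_config()].
#' @return An object of class `agent_state`.
#' @export
agent_state_init <- function(config) {
  sn <- state_names(config)
  structure(list(
    q_mf = matrix(0.5, config$n_games, 2,
                  dimnames = list(config$games, c("left", "right"))),
    v2 = stats::setNames(rep(0.5, length(sn)), sn),
    last_action = stats::setNames(rep(NA_character_, config$n_games),
                                  config$games),
    outcome_value = stats::setNames(rep(1, length(sn)), sn)
  ), class = "agent_state")
}

#' Devalue the outcomes of one or more second-stage states
#'
#' Sets `outcome_value` to 0 for the named states (Exp 2) or for both
#' states of the named game (Exp 1). This is the only agent-internal
#' quantity the devaluation event touches.
#'
#' @param state an [agent_state_init()] state.
#' @param config a [task_config()].
#' @param game game whose coin type is devalued, or `NULL`.
#' @param states second-stage state labels to devalue, or `NULL`.
#' @return The updated state.
#' @export
devalue <- function(state, config, game = NULL, states = NULL) {
  if (!is.null(game)) states <- c(states, paste(game, c("a", "b"), sep = "_"))
  stopifnot(all(states %in% names(state$outcome_value)))
  state$outcome_value[states] <- 0
  state
}

#' Model-free delta-rule update
#'
#' Updates the chosen action's cached first-stage value toward the update
#' target (the terminal reward when `lambda = 1`) and the visited
#' second-stage state's value toward the reward. Hidden feedback
#' (`reward = NA`) is a no-op by contract.
#'
#' @param state agent state.
#' @param game game label.
#' @param action `"left"` or `"right"`.
#' @param reward 0, 1, or `NA` (hidden).
#' @param params an [agent_params()].
#' @param second_state visited second-stage state label.
#' @return The updated state.
#' @export
mf_update <- function(state, game, action, reward, params, second_state) {
  if (is.na(reward)) return(state)
  stopifnot(reward %in% c(0, 1))
  v_old <- state$v2[[second_state]]
  target <- (1 - params$lambda) * v_old + params$lambda * reward
  state$q_mf[game, action] <- state$q_mf[game, action] +
    params$alpha * (target - state$q_mf[game, action])
  state$v2[[second_state]] <- v_old + params$alpha * (reward - v_old)
  state
}

#' Model-based action values
#'
#' Prospective values under the known transition model: each action's value
#' is the transition-probability-weighted sum of second-stage values, each
#' multiplied by its current incentive (`outcome_value`). The incentive
#' multiplication is what makes model-based values devaluation-sensitive.
#'
#' @inheritParams mf_update
#' @param config a [task_config()].
#' @return Named numeric vector `c(left = , right = )`.
#' @export
mb_values <- function(state, game, config) {
  g <- match(game, config$games)
  states <- state_names(config)[c(2 * g - 1, 2 * g)]
  uv <- state$outcome_value[states] * state$v2[states]
  p <- config$p_common
  c(left = p * uv[[1]] + (1 - p) * uv[[2]],
    right = p * uv[[2]] + (1 - p) * uv[[1]])
}

#' First-stage choice probabilities and sampling
#'
#' Net values are `w * Q_mb + (1 - w) * Q_mf`; choice follows a softmax of
#' `beta * Q_net` plus a perseveration bonus `pi` on the previous same-game
#' choice.
#'
#' @inheritParams mb_values
#' @param params an [agent_params()].
#' @return `choose_probs()`: named probabilities; `choose_action()`: a
#'   sampled action label.
#' @export
choose_probs <- function(state, params, game, config) {
  q_net <- params$w * mb_values(state, game, config) +
    (1 - params$w) * state$q_mf[game, ]
  x <- params$beta * q_net
  la <- state$last_action[[game]]
  if (!is.na(la)) x[la] <- x[la] + params$pi
  p <- exp(x - max(x))
  p / sum(p)
}

#' @rdname choose_probs
#' @export
choose_action <- function(state, params, game, config) {
  p <- choose_probs(state, params, game, config)
  sample(names(p), 1, prob = p)
}

#' Respond/withhold decision (Exp 1 test and no-feedback phases)
#'
#' The net value of engaging is the best available hybrid action value
#' converted to currency, minus the response cost; the probability of
#' responding is a logistic in that value. The model-based branch carries
#' `outcome_value`, so devaluation can zero it; the model-free branch uses
#' the cached `q_mf`, which devaluation cannot touch. This mechanism is a
#' generative convention of this package (the task only motivates it
#' conceptually); its parameters are documented in the methods vignette.
#'
#' @inheritParams choose_probs
#' @return `respond_probability()`: P(respond); `respond_decision()`:
#'   `"respond"` or `"withhold"`.
#' @export
respond_probability <- function(state, params, game, config) {
  q_net <- params$w * mb_values(state, game, config) +
    (1 - params$w) * state$q_mf[game, ]
  e <- max(q_net) * config$reward_value - config$response_cost
  stats::plogis(params$beta_resp * e + params$resp_bias)
}

#' @rdname respond_probability
#' @export
respond_decision <- function(state, params, game, config) {
  if (stats::runif(1) < respond_probability(state, params, game, config))
    "respond" else "withhold"
}

#' Simulate one subject through a full experiment run
#'
#' Plays training, no-feedback, devaluation and test phases with the
#' compiled update kernel (the same kernel the likelihood uses), then
#' simulates the coin consumption display. Learning updates are suspended
#' whenever feedback is hidden.
#'
#' @param params an [agent_params()].
#' @param config a [task_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param subject_id subject identifier written into the log.
#' @param devalued devalued game label (Exp 1) or second-stage state label
#'   (Exp 2); `NULL` picks one at random (counterbalancing).
#' @param omission_rate probability of a random lapse (missed trial) on
#'   each training trial; default 0.
#' @param deval_link `"model"` (devaluation-test behaviour produced by the
#'   agent's values, so it inherits the agent's `w`) or `"null"`
#'   (engagement is a flat per-subject probability and choices ignore
#'   devaluation; used for specificity checks).
#' @param null_respond_p engagement probability under `deval_link =
#'   "null"`.
#' @param consume_probs probability of collecting each available valued /
#'   devalued coin in the consumption display.
#' @return A data frame of trial records (columns `subject`, `game`,
#'   `trial`, `phase`, `stabilized`, `action`, `transition`,
#'   `second_state`, `reward`, `devalued_game`) with attributes
#'   `consumption` (named collected-coin counts) and `devalued` (the
#'   devalued target).
#' @export
simulate_subject <- function(params, config, seed = NULL, subject_id = 1L,
                             devalued = NULL, omission_rate = 0,
                             deval_link = c("model", "null"),
                             null_respond_p = 0.6,
                             consume_probs = c(valued = 0.55, devalued = 0.06)) {
  stopifnot(inherits(params, "agent_params"))
  validate_task_config(config)
  deval_link <- match.arg(deval_link)
  if (!is.null(seed)) set.seed(seed)
  sched <- build_phase_schedule(config)
  walks <- make_reward_walks(config)
  sn <- state_names(config)

  if (config$experiment == "exp1") {
    if (is.null(devalued)) devalued <- sample(config$games, 1)
    stopifnot(devalued %in% config$games)
    devalued_states <- sn[match(devalued, config$games) * 2 - c(1, 0)]
  } else {
    if (is.null(devalued)) devalued <- sample(sn, 1)
    stopifnot(devalued %in% sn)
    devalued_states <- devalued
  }
  dev_flag <- sn %in% devalued_states

  T_all <- nrow(sched)
  walk_full <- matrix(0.5, T_all, length(sn))
  walk_full[seq_len(config$n_training), ] <- walks
  if (config$n_stabilized > 0) {
    # the devalued-associated state carries the high stabilized probability
    rows <- which(sched$stabilized)
    walk_full[rows, dev_flag] <- config$stabilized_probs[["devalued"]]
    walk_full[rows, !dev_flag] <- config$stabilized_probs[["valued"]]
  }

  par <- c(params$alpha, params$beta, params$w, params$pi,
           params$beta_resp, params$resp_bias, params$lambda)
  phase_code <- match(sched$phase, c("training", "nofeedback", "test")) - 1L
  sim <- sim_subject_cpp(
    par, config$p_common, config$n_games, config$reward_value,
    config$response_cost, walk_full,
    match(sched$game, config$games) - 1L, phase_code,
    as.integer(sched$post_deval), as.integer(dev_flag),
    as.integer(sched$allow_withhold), omission_rate,
    deval_link == "null", null_respond_p)

  action <- rep("none", T_all)
  action[sim$action >= 0] <- c("left", "right")[sim$action[sim$action >= 0] + 1L]
  second_state <- rep(NA_character_, T_all)
  second_state[sim$sstate >= 0] <- sn[sim$sstate[sim$sstate >= 0] + 1L]
  transition <- rep("none", T_all)
  transition[sim$transition >= 0] <-
    c("common", "rare")[sim$transition[sim$transition >= 0] + 1L]
  reward <- ifelse(sim$reward >= 0, sim$reward, NA_integer_)

  if (config$experiment == "exp1") {
    dev_col <- sched$game == devalued
  } else {
    # single game: flag by the (realized or, at test, common) destination
    dest <- ifelse(action == "left", sn[1],
                   ifelse(action == "right", sn[2], NA_character_))
    dev_col <- ifelse(is.na(second_state), dest == devalued,
                      second_state == devalued)
  }

  trials <- data.frame(
    subject = subject_id, game = sched$game, trial = sched$trial,
    phase = sched$phase, stabilized = sched$stabilized, action = action,
    transition = transition, second_state = second_state,
    reward = as.integer(reward), devalued_game = as.logical(dev_col),
    stringsAsFactors = FALSE
  )
  consumption <- c(
    valued = stats::rbinom(1, 10, consume_probs[["valued"]]),
    devalued = stats::rbinom(1, 10, consume_probs[["devalued"]]))
  attr(trials, "consumption") <- consumption
  attr(trials, "devalued") <- devalued
  attr(trials, "params") <- params
  trials
}

#' Default cohort parameter distribution
#'
#' Each entry is a fixed value (length 1), a uniform range (length 2), or a
#' function of `n` returning `n` draws. Defaults give moderate subject
#' heterogeneity in learning rate, choice temperature and perseveration,
#' the full range of the model-based weight, and fixed respond/withhold
#' parameters (see the methods vignette for the rationale).
#'
#' @param ... entries overriding the defaults (`alpha`, `beta`, `w`, `pi`,
#'   `beta_resp`, `resp_bias`, `lambda`).
#' @return Named list of distribution specifications.
#' @export
cohort_spec <- function(...) {
  spec <- list(alpha = c(0.4, 0.7), beta = c(6, 10), w = c(0, 1),
               pi = c(0, 0.3), beta_resp = 60, resp_bias = -3.5, lambda = 1)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(spec)))
  spec[names(dots)] <- dots
  spec
}

draw_param <- function(spec_entry, n) {
  if (is.function(spec_entry)) return(spec_entry(n))
  if (length(spec_entry) == 1) return(rep(spec_entry, n))
  if (length(spec_entry) == 2)
    return(stats::runif(n, spec_entry[1], spec_entry[2]))
  stop("parameter spec entries must be length 1, length 2, or a function",
       call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject agent parameters from `spec`, simulates every subject
#' through the experiment, and returns the logs together with the
#' ground-truth parameter table needed by recovery tests.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param config a [task_config()].
#' @param spec a [cohort_spec()].
#' @param seed optional integer master seed; per-subject child seeds are
#'   derived from it so individual subjects can be re-simulated in
#'   isolation.
#' @param deval_link,omission_rate,null_respond_p,consume_probs passed to
#'   [simulate_subject()]; under `deval_link = "null"` each subject's flat
#'   engagement probability is drawn uniformly from
#'   `null_respond_p + c(-0.3, 0.3)`.
#' @return An object of class `cohort`: list with `trials` (all subjects'
#'   logs), `truth` (subject, parameters, devalued target, realized
#'   devaluation sensitivity), `consumption` (per-subject collected-coin
#'   counts), and `config`.
#' @export
generate_cohort <- function(n_subjects, config, spec = cohort_spec(),
                            seed = NULL, deval_link = c("model", "null"),
                            omission_rate = 0, null_respond_p = 0.6,
                            consume_probs = c(valued = 0.55, devalued = 0.06)) {
  if (n_subjects < 2) stop("n_subjects must be at least 2", call. = FALSE)
  deval_link <- match.arg(deval_link)
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  pars <- lapply(spec, draw_param, n = n_subjects)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  null_p <- stats::runif(n_subjects, max(0, null_respond_p - 0.3),
                         min(1, null_respond_p + 0.3))
  logs <- vector("list", n_subjects)
  consumption <- matrix(0L, n_subjects, 2,
                        dimnames = list(NULL, c("valued", "devalued")))
  devalued <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    p_i <- agent_params(pars$alpha[i], pars$beta[i], pars$w[i], pars$pi[i],
                        pars$beta_resp[i], pars$resp_bias[i], pars$lambda[i])
    log_i <- simulate_subject(p_i, config, seed = subj_seeds[i],
                              subject_id = i, omission_rate = omission_rate,
                              deval_link = deval_link,
                              null_respond_p = null_p[i],
                              consume_probs = consume_probs)
    consumption[i, ] <- attr(log_i, "consumption")
    devalued[i] <- attr(log_i, "devalued")
    attributes(log_i)[c("consumption", "devalued", "params")] <- NULL
    logs[[i]] <- log_i
  }
  trials <- do.call(rbind, logs)
  truth <- data.frame(subject = seq_len(n_subjects),
                      alpha = pars$alpha, beta = pars$beta, w = pars$w,
                      pi = pars$pi, beta_resp = pars$beta_resp,
                      resp_bias = pars$resp_bias, devalued = devalued,
                      stringsAsFactors = FALSE)
  truth$deval_sensitivity_true <- vapply(
    seq_len(n_subjects),
    function(i) devaluation_sensitivity(logs[[i]], config), numeric(1))
  structure(list(trials = trials, truth = truth,
                 consumption = data.frame(subject = seq_len(n_subjects),
                                          consumption),
                 config = config, deval_link = deval_link,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$truth), "subjects,",
      x$config$experiment, "design,", nrow(x$trials), "trial records\n")
  invisible(x)
}
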