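#' Task configuration for a two-step devaluation experiment
#'
#' Builds the full specification of one experiment variant of the sequential
#' two-step task with outcome devaluation. Variant `"exp1"` is the two-game
#' design (gold and silver start states, 200 training trials, a respond/
#' withhold devaluation test of 20 trials, and a coin consumption display);
#' variant `"exp2"` is the single-game design (150 drifting plus 50
#' stabilized training trials and a 10-trial forced-choice habit test).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param p_common probability that a first-stage action leads to its
#'   majority second-stage state (default 0.70).
#' @param walk_sd standard deviation of the Gaussian increments of the
#'   drifting reward probabilities (default 0.025).
#' @param walk_bounds closed reflecting bounds for the reward-probability
#'   walks, default `c(0.25, 0.75)`.
#' @param reward_value value of one coin in USD (default 0.25).
#' @param response_cost cost of making a choice in USD (default 0.01 for
#'   `"exp1"`, 0 for `"exp2"`, where responding is free and forced).
#' @param n_training total number of training trials (200 for both
#'   variants; in `"exp2"` the last `n_stabilized` of them use stabilized
#'   reward probabilities).
#' @param n_stabilized number of stabilized training trials (`"exp2"` only,
#'   default 50).
#' @param stabilized_probs stabilized reward probabilities for the
#'   devalued-associated and valued-associated second-stage states
#'   (`"exp2"` only, default `c(devalued = 0.9, valued = 0.1)`).
#' @param n_nofeedback number of no-feedback trials before devaluation
#'   (default 4).
#' @param n_test number of devaluation-test trials (20 for `"exp1"`,
#'   balanced 10/10 across games; 10 for `"exp2"`).
#' @param response_window response window in seconds (default 2.5; recorded
#'   for completeness, reaction times are not simulated).
#' @param max_run_length longest permitted run of one game in the `"exp1"`
#'   interleaving (default 4).
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(experiment = c("exp1", "exp2"),
                        p_common = 0.70,
                        walk_sd = 0.025,
                        walk_bounds = c(0.25, 0.75),
                        reward_value = 0.25,
                        response_cost = NULL,
                        n_training = 200L,
                        n_stabilized = NULL,
                        stabilized_probs = c(devalued = 0.9, valued = 0.1),
                        n_nofeedback = 4L,
                        n_test = NULL,
                        response_window = 2.5,
                        max_run_length = 4L) {
  experiment <- match.arg(experiment)
  exp1 <- experiment == "exp1"
  cfg <- structure(list(
    experiment = experiment,
    n_games = if (exp1) 2L else 1L,
    games = if (exp1) c("gold", "silver") else "single",
    p_common = p_common,
    walk_sd = walk_sd,
    walk_bounds = as.numeric(walk_bounds),
    reward_value = reward_value,
    response_cost = if (is.null(response_cost)) (if (exp1) 0.01 else 0) else response_cost,
    n_training = as.integer(n_training),
    n_stabilized = as.integer(if (is.null(n_stabilized)) (if (exp1) 0L else 50L) else n_stabilized),
    stabilized_probs = stabilized_probs,
    n_nofeedback = as.integer(n_nofeedback),
    n_test = as.integer(if (is.null(n_test)) (if (exp1) 20L else 10L) else n_test),
    response_window = response_window,
    max_run_length = as.integer(max_run_length)
  ), class = "task_config")
  validate_task_config(cfg)
  cfg
}

#' @rdname task_config
#' @param config object to validate.
#' @export
validate_task_config <- function(config) {
  stopifnot(inherits(config, "task_config"))
  with(config, {
    if (!(p_common > 0 && p_common < 1))
      stop("p_common must lie strictly inside (0, 1)", call. = FALSE)
    if (length(walk_bounds) != 2 || walk_bounds[1] >= walk_bounds[2])
      stop("walk_bounds must be an interval with lower < upper", call. = FALSE)
    if (walk_bounds[1] <= 0 || walk_bounds[2] >= 1)
      stop("walk_bounds must lie strictly inside (0, 1)", call. = FALSE)
    if (n_training < 1 || n_nofeedback < 1 || n_test < 1)
      stop("all trial counts must be positive", call. = FALSE)
    if (n_stabilized < 0 || n_stabilized >= n_training)
      stop("n_stabilized must be in [0, n_training)", call. = FALSE)
    if (experiment == "exp1") {
      if (n_test %% n_games != 0)
        stop("n_test must be balanced across games in exp1", call. = FALSE)
      if (n_training %% n_games != 0)
        stop("n_training must be divisible by the number of games", call. = FALSE)
    }
    if (experiment == "exp2" && n_stabilized > 0 &&
        (any(stabilized_probs <= 0) || any(stabilized_probs >= 1)))
      stop("stabilized_probs must lie in (0, 1)", call. = FALSE)
  })
  invisible(config)
}

#' Second-stage state labels
#'
#' Two states per game; state `<game>_a` is the common destination of the
#' left action and `<game>_b` of the right action.
#'
#' @param config a [task_config()].
#' @return Character vector of length `2 * n_games`.
#' @export
state_names <- function(config) {
  as.vector(t(outer(config$games, c("a", "b"), paste, sep = "_")))
}

# reflect a proposed value into [lo, hi], mirroring at the bounds until inside
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  out <- x
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- ifelse(out[bad] > hi, 2 * hi - out[bad], out[bad])
    out[bad] <- ifelse(out[bad] < lo, 2 * lo - out[bad], out[bad])
    # a step larger than the interval width can overshoot the far bound;
    # iterate (cannot happen at the default walk_sd, but keep it correct)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  stopifnot(all(out >= lo & out <= hi), width > 0)
  out
}

#' Drifting reward-probability walks
#'
#' One independent Gaussian random walk per second-stage state: zero-mean
#' increments with standard deviation `walk_sd`, reflected at `walk_bounds`,
#' initial values drawn uniformly within the bounds.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric matrix with `n_training` rows (one per training trial)
#'   and one column per second-stage state.
#' @export
make_reward_walks <- function(config, seed = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  n_states <- 2L * config$n_games
  n <- config$n_training
  walks <- matrix(NA_real_, n, n_states,
                  dimnames = list(NULL, state_names(config)))
  p <- stats::runif(n_states, lo, hi)
  walks[1, ] <- p
  if (n > 1) {
    for (t in 2:n) {
      p <- reflect_into(p + stats::rnorm(n_states, 0, config$walk_sd), lo, hi)
      walks[t, ] <- p
    }
  }
  walks
}

#' Sample a second-stage transition
#'
#' The chosen action leads to its majority destination with probability
#' `p_common` and to the alternative state otherwise.
#'
#' @param action `"left"` or `"right"` (withheld responses are handled at
#'   the phase level, not here).
#' @param config a [task_config()].
#' @param game game label (default the first game).
#' @return List with elements `second_state` and `transition`
#'   (`"common"`/`"rare"`).
#' @export
sample_transition <- function(action, config, game = config$games[1]) {
  if (!action %in% c("left", "right"))
    stop("action must be 'left' or 'right'", call. = FALSE)
  g <- match(game, config$games)
  if (is.na(g)) stop("unknown game: ", game, call. = FALSE)
  states <- state_names(config)[c(2 * g - 1, 2 * g)]
  dest <- if (action == "left") states[1] else states[2]
  alt <- setdiff(states, dest)
  common <- stats::runif(1) < config$p_common
  list(second_state = if (common) dest else alt,
       transition = if (common) "common" else "rare")
}

# interleave games with no run longer than max_run; sequential construction
# with forced switches, whole-sequence retry if the tail gets trapped
interleave_games <- function(n_per_game, n_games, max_run) {
  stopifnot(n_games >= 1)
  if (n_games == 1) return(rep(1L, n_per_game))
  for (attempt in 1:100) {
    remaining <- rep(n_per_game, n_games)
    out <- integer(n_per_game * n_games)
    run <- 0L; last <- 0L; ok <- TRUE
    for (t in seq_along(out)) {
      avail <- which(remaining > 0)
      if (run >= max_run) avail <- setdiff(avail, last)
      if (!length(avail)) { ok <- FALSE; break }
      g <- if (length(avail) == 1) avail else
        sample(avail, 1, prob = remaining[avail])
      out[t] <- g
      remaining[g] <- remaining[g] - 1L
      run <- if (g == last) run + 1L else 1L
      last <- g
    }
    if (ok) return(out)
  }
  stop("could not interleave games under the run-length constraint")
}

#' Build the phase/trial schedule of one experiment run
#'
#' Lays out training, no-feedback, devaluation and test phases in order.
#' Exp 1 interleaves the two games (equal counts, no run longer than
#' `max_run_length`), splits the four no-feedback trials 2/2 across games,
#' and balances the 20 test trials 10/10 in randomized order. Exp 2 runs a
#' single game whose last `n_stabilized` training trials are flagged
#' `stabilized`. The devaluation event falls between the no-feedback and
#' test phases, so `post_deval` is `TRUE` exactly on test trials.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A data frame with one row per trial: `trial`, `game`, `phase`
#'   (`training`/`nofeedback`/`test`), `stabilized`, `post_deval`,
#'   `allow_withhold`.
#' @export
build_phase_schedule <- function(config, seed = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_games
  train_games <- interleave_games(config$n_training %/% G, G,
                                  config$max_run_length)
  nf_games <- sample(rep(seq_len(G), length.out = config$n_nofeedback))
  test_games <- sample(rep(seq_len(G), each = config$n_test %/% G))
  exp1 <- config$experiment == "exp1"
  n_drift <- config$n_training - config$n_stabilized
  sched <- data.frame(
    trial = seq_len(config$n_training + config$n_nofeedback + config$n_test),
    game = config$games[c(train_games, nf_games, test_games)],
    phase = rep(c("training", "nofeedback", "test"),
                c(config$n_training, config$n_nofeedback, config$n_test)),
    stabilized = c(seq_len(config$n_training) > n_drift,
                   rep(FALSE, config$n_nofeedback + config$n_test)),
    stringsAsFactors = FALSE
  )
  sched$post_deval <- sched$phase == "test"
  # value-based withholding is only available in Exp 1's no-feedback and
  # test phases; Exp 2 forces a response on every trial
  sched$allow_withhold <- exp1 & sched$phase %in% c("nofeedback", "test")
  sched
}
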