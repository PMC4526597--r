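# Likelihood-side bindings to the compiled update kernel. The simulator and
# the likelihood share the same C++ kernel, so the likelihood replays
# internal state exactly as the generator produced it.

# derive which second-stage states are devalued from a subject's log
devalued_states_from_log <- function(trials, config) {
  sn <- state_names(config)
  if (config$experiment == "exp1") {
    g <- unique(trials$game[trials$devalued_game])
    if (length(g) == 0) return(rep(FALSE, length(sn)))  # nothing devalued
    if (length(g) > 1) stop("cannot identify a unique devalued game",
                            call. = FALSE)
    sn %in% sn[match(g, config$games) * 2 - c(1, 0)]
  } else {
    s <- unique(trials$second_state[trials$devalued_game &
                                      !is.na(trials$second_state)])
    if (length(s) == 0) return(rep(FALSE, length(sn)))
    if (length(s) > 1) stop("cannot identify a unique devalued state",
                            call. = FALSE)
    sn %in% s
  }
}

# integer encoding of one subject's log for the C++ kernel
kernel_data <- function(trials, config, include_test = FALSE) {
  sn <- state_names(config)
  action <- match(trials$action, c("left", "right")) - 1L
  action[is.na(action)] <- -1L
  sstate <- match(trials$second_state, sn) - 1L
  sstate[is.na(sstate)] <- -1L
  reward <- ifelse(is.na(trials$reward), -1L, as.integer(trials$reward))
  contrib <- action >= 0L & (trials$phase != "test" | include_test)
  list(game = match(trials$game, config$games) - 1L,
       action = action, sstate = sstate, reward = reward,
       post_deval = as.integer(trials$phase == "test"),
       devalued_state = as.integer(devalued_states_from_log(trials, config)),
       contrib = as.integer(contrib))
}

# per-subject kernel encodings for a cohort trials table
kernel_data_cohort <- function(trials, config, include_test = FALSE) {
  split_tr <- split(trials, trials$subject)
  lapply(split_tr, kernel_data, config = config, include_test = include_test)
}

#' Negative log-likelihood of the hybrid agent
#'
#' Likelihood of a subject's observed first-stage choices under the hybrid
#' model-based / model-free agent, replaying the learning updates
#' sequentially with the same compiled kernel the simulator uses. Trials
#' with hidden feedback contribute their choice likelihood but trigger no
#' value update; missed/withheld trials contribute nothing. Post-
#' devaluation test choices are excluded by default (`include_test`).
#'
#' @param params an [agent_params()] (or list with `alpha`, `beta`, `w`,
#'   `pi`, `lambda`).
#' @param trials one subject's trial records.
#' @param config a [task_config()].
#' @param include_test also score post-devaluation test choices.
#' @return Nonnegative scalar, the negative log-likelihood in nats.
#' @export
hybrid_nll <- function(params, trials, config, include_test = FALSE) {
  if (nrow(trials) == 0) stop("empty trial data", call. = FALSE)
  if (length(unique(trials$subject)) > 1)
    stop("hybrid_nll expects a single subject", call. = FALSE)
  lambda <- if (is.null(params$lambda)) 1 else params$lambda
  if (params$alpha < 0 || params$alpha > 1 || params$w < 0 ||
      params$w > 1 || params$beta < 0 || lambda < 0 || lambda > 1)
    stop("parameters out of bounds", call. = FALSE)
  kd <- kernel_data(trials, config, include_test)
  nll_cpp(c(params$alpha, params$beta, params$w, params$pi, lambda),
          config$p_common, config$n_games, kd$game, kd$action, kd$sstate,
          kd$reward, kd$post_deval, kd$devalued_state, kd$contrib)
}

# natural <-> unconstrained transforms used by the optimizer and sampler:
# logit for alpha and w, log for beta, identity for pi
theta_to_natural <- function(theta) {
  c(alpha = stats::plogis(theta[[1]]), beta = exp(theta[[2]]),
    w = stats::plogis(theta[[3]]), pi = theta[[4]])
}
natural_to_theta <- function(alpha, beta, w, pi) {
  c(stats::qlogis(pmin(pmax(alpha, 1e-6), 1 - 1e-6)),
    log(pmax(beta, 1e-6)),
    stats::qlogis(pmin(pmax(w, 1e-6), 1 - 1e-6)), pi)
}

#' Per-subject maximum-likelihood fit of the hybrid agent
#'
#' Minimizes [hybrid_nll()] on unconstrained transformed scales (logit for
#' the learning rate and the model-based weight, log for the inverse
#' temperature) with multiple random restarts; the best restart wins.
#'
#' @param trials one subject's trial records.
#' @param config a [task_config()].
#' @param n_restarts number of random restarts (>= 1; 10 by default).
#' @param seed optional integer seed for the restart draws.
#' @param lambda eligibility parameter held fixed during fitting.
#' @param include_test passed to [hybrid_nll()].
#' @param maxit optimizer iteration cap per restart.
#' @return List of class `mle_fit`: `estimate` (alpha, beta, w, pi),
#'   `nll`, `restarts` (per-restart log), `convergence`.
#' @export
fit_mle <- function(trials, config, n_restarts = 10, seed = NULL,
                    lambda = 1, include_test = FALSE, maxit = 500) {
  if (!is.null(seed)) set.seed(seed)
  kd <- kernel_data(trials, config, include_test)
  if (sum(kd$contrib) == 0) stop("no scoreable choices in data", call. = FALSE)
  obj <- function(theta) {
    nat <- theta_to_natural(theta)
    nll_cpp(c(nat[["alpha"]], min(nat[["beta"]], 1e3), nat[["w"]],
              nat[["pi"]], lambda),
            config$p_common, config$n_games, kd$game, kd$action, kd$sstate,
            kd$reward, kd$post_deval, kd$devalued_state, kd$contrib)
  }
  best <- NULL
  log_rows <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- natural_to_theta(stats::runif(1, 0.1, 0.9),
                             stats::runif(1, 1, 10),
                             stats::runif(1, 0.05, 0.95),
                             stats::rnorm(1, 0, 0.5))
    opt <- tryCatch(stats::optim(init, obj, method = "Nelder-Mead",
                                 control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (is.null(opt)) {
      log_rows[[r]] <- data.frame(restart = r, nll = NA_real_,
                                  convergence = NA_integer_)
      next
    }
    log_rows[[r]] <- data.frame(restart = r, nll = opt$value,
                                convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)
  est <- theta_to_natural(best$par)
  structure(list(estimate = est, nll = best$value,
                 restarts = do.call(rbind, log_rows),
                 convergence = best$convergence), class = "mle_fit")
}

#' Maximum-likelihood fits for every subject of a cohort
#'
#' @param trials cohort trial records (column `subject`).
#' @param config a [task_config()].
#' @param n_restarts,seed,lambda,include_test passed to [fit_mle()];
#'   per-subject child seeds are derived from `seed`.
#' @return Data frame: `subject`, `alpha`, `beta`, `w`, `pi`, `nll`.
#' @export
fit_mle_cohort <- function(trials, config, n_restarts = 10, seed = NULL,
                           lambda = 1, include_test = FALSE) {
  subjects <- sort(unique(trials$subject))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(subjects))
  rows <- lapply(seq_along(subjects), function(i) {
    f <- fit_mle(trials[trials$subject == subjects[i], ], config,
                 n_restarts = n_restarts, seed = seeds[i], lambda = lambda,
                 include_test = include_test)
    data.frame(subject = subjects[i], t(f$estimate), nll = f$nll)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
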