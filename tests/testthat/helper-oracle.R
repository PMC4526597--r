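# Independent brute-force likelihood oracle.
#
# Re-derives the hybrid agent's choice log-likelihood from first principles
# with plain R bookkeeping over the trial data frame. Deliberately shares no
# code with the package's compiled kernel: games and states are tracked in
# named lists, values recomputed longhand each trial. Conventions under
# test: values initialised at 0.5; state "<game>_a" is the left action's
# common destination; outcome values are zeroed for devalued states on
# post-devaluation (test-phase) trials; hidden feedback scores the choice
# but triggers no update; missed trials contribute nothing.
oracle_nll <- function(alpha, beta, w, pi, lambda, p_common, trials,
                       games, devalued_states, include_test = FALSE) {
  q_mf <- list()
  v2 <- list()
  last <- list()
  for (g in games) {
    q_mf[[g]] <- c(left = 0.5, right = 0.5)
    last[[g]] <- NA_character_
    v2[[paste0(g, "_a")]] <- 0.5
    v2[[paste0(g, "_b")]] <- 0.5
  }
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    if (row$action == "none") next
    g <- row$game
    post <- row$phase == "test"
    sa <- paste0(g, "_a"); sb <- paste0(g, "_b")
    u <- function(s) if (post && s %in% devalued_states) 0 else 1
    q_mb <- c(
      left  = p_common * u(sa) * v2[[sa]] + (1 - p_common) * u(sb) * v2[[sb]],
      right = p_common * u(sb) * v2[[sb]] + (1 - p_common) * u(sa) * v2[[sa]])
    q_net <- w * q_mb + (1 - w) * q_mf[[g]]
    x <- beta * q_net
    if (!is.na(last[[g]])) x[last[[g]]] <- x[last[[g]]] + pi
    p <- exp(x - max(x)); p <- p / sum(p)
    if (!post || include_test) nll <- nll - log(p[[row$action]])
    if (!is.na(row$reward)) {
      s <- row$second_state
      v_old <- v2[[s]]
      target <- (1 - lambda) * v_old + lambda * row$reward
      q_mf[[g]][row$action] <- q_mf[[g]][row$action] +
        alpha * (target - q_mf[[g]][row$action])
      v2[[s]] <- v_old + alpha * (row$reward - v_old)
    }
    last[[g]] <- row$action
  }
  nll
}

# handmade three-trial exp1 sequence used by the oracle tests
handmade_trials <- function() {
  data.frame(
    subject = 1L,
    game = c("gold", "gold", "silver"),
    trial = 1:3,
    phase = "training",
    stabilized = FALSE,
    action = c("left", "left", "right"),
    transition = c("common", "rare", "common"),
    second_state = c("gold_a", "gold_b", "silver_b"),
    reward = c(1L, 0L, 1L),
    devalued_game = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
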