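# Shared fixtures: small configurations and hand-built trial logs.

cfg_exp1 <- function(...) task_config("exp1", ...)
cfg_exp2 <- function(...) task_config("exp2", ...)

# minimal exp1 test-phase log with a given number of responses per state
test_phase_log <- function(n_valued_resp, n_devalued_resp, n_per_state = 10) {
  stopifnot(n_valued_resp <= n_per_state, n_devalued_resp <= n_per_state)
  act <- function(k) rep(c("left", "none"), c(k, n_per_state - k))
  data.frame(
    subject = 1L,
    game = rep(c("gold", "silver"), each = n_per_state),
    trial = seq_len(2 * n_per_state),
    phase = "test",
    stabilized = FALSE,
    action = c(act(n_valued_resp), act(n_devalued_resp)),
    transition = "none",
    second_state = NA_character_,
    reward = NA_integer_,
    devalued_game = rep(c(FALSE, TRUE), each = n_per_state),
    stringsAsFactors = FALSE
  )
}

# standardized devaluation sensitivity for a cohort object
cohort_deval_z <- function(cohort) {
  ss <- subject_summaries(cohort)
  stats::setNames(zscore(ss$deval_sensitivity), ss$subject)
}
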