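test_that("lagging is within game: predictors come from the previous same-game trial", {
  tr <- data.frame(
    subject = 1L,
    game = c("gold", "silver", "gold", "silver"),
    trial = 1:4, phase = "training", stabilized = FALSE,
    action = c("left", "right", "left", "left"),
    transition = c("rare", "common", "common", "common"),
    second_state = c("gold_b", "silver_b", "gold_a", "silver_a"),
    reward = c(1L, 0L, 1L, 1L),
    devalued_game = FALSE, stringsAsFactors = FALSE)
  d <- build_lagged_design(tr)
  expect_equal(nrow(d), 2)   # first trial of each game emits no row
  gold_row <- d[d$game == "gold", ]
  # third trial's predictors come from the first (gold) trial, not the second
  expect_equal(gold_row$prev_reward, 1)
  expect_equal(gold_row$prev_transition, -1)
  expect_equal(gold_row$stay, 1L)
  silver_row <- d[d$game == "silver", ]
  expect_equal(silver_row$prev_reward, -1)
  expect_equal(silver_row$stay, 0L)
})

test_that("lone trials, missed trials and non-training phases are excluded", {
  tr <- data.frame(
    subject = 1L, game = "gold", trial = 1:5,
    phase = c("training", "training", "training", "test", "test"),
    stabilized = FALSE,
    action = c("left", "none", "right", "left", "left"),
    transition = c("common", "none", "common", "none", "none"),
    second_state = c("gold_a", NA, "gold_b", NA, NA),
    reward = c(1L, NA, 0L, NA, NA),
    devalued_game = FALSE, stringsAsFactors = FALSE)
  d <- build_lagged_design(tr)
  # the missed trial is neither a target nor a lag source; test rows dropped
  expect_equal(nrow(d), 1)
  expect_equal(d$stay, 0L)           # right after left
  expect_equal(d$prev_reward, 1)     # lag source is trial 1
  # a lone trial in a game contributes nothing
  lone <- tr[1, ]
  expect_equal(nrow(build_lagged_design(lone)), 0)
  # an all-stay agent yields an all-ones stay column
  rep_tr <- tr[c(1, 3), ]; rep_tr$action <- "left"; rep_tr$trial <- 1:2
  expect_true(all(build_lagged_design(rep_tr)$stay == 1))
})

test_that("stabilized trials are excluded from the design by default", {
  cfg <- cfg_exp2()
  co <- generate_cohort(4, cfg, seed = 111)
  d_default <- build_lagged_design(co$trials)
  d_all <- build_lagged_design(co$trials, include_stabilized = TRUE)
  expect_lt(nrow(d_default), nrow(d_all))
  # 150 drifting trials per subject leave at most 149 lagged rows each
  expect_lte(nrow(d_default), 4 * 149)
})

test_that("the +/-1 coding checksum is an integer identity", {
  cfg <- cfg_exp1()
  co <- generate_cohort(6, cfg, seed = 112)
  d <- build_lagged_design(co$trials)
  concordant <- sum(d$prev_reward == d$prev_transition)
  discordant <- sum(d$prev_reward != d$prev_transition)
  expect_identical(as.integer(sum(d$prev_reward * d$prev_transition)),
                   concordant - discordant)
  expect_true(all(d$prev_reward %in% c(-1, 1)))
  expect_true(all(d$prev_transition %in% c(-1, 1)))
})

test_that("Firth-penalized logistic matches glm away from separation and stays finite under it", {
  set.seed(113)
  n <- 4000
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  eta <- x %*% c(-0.3, 0.8, 0.5)
  y <- rbinom(n, 1, plogis(eta))
  f <- firth_logistic(x, y)
  g <- glm.fit(x, y, family = binomial())
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 0.02)
  # perfectly separated data: ML diverges, Firth stays finite
  xs <- cbind(1, c(-2, -1, -0.5, 0.5, 1, 2))
  ys <- c(0, 0, 0, 1, 1, 1)
  fs <- firth_logistic(xs, ys)
  expect_true(all(is.finite(fs$coefficients)))
  expect_true(all(is.finite(fs$se)))
  expect_lt(abs(fs$coefficients[2]), 20)
})

test_that("per-subject indices carry the model-based / model-free signatures", {
  cfg <- cfg_exp1(n_training = 10000)
  tr1 <- simulate_subject(agent_params(0.5, 8, 1), cfg, seed = 121,
                          subject_id = 1L)
  tr0 <- simulate_subject(agent_params(0.5, 8, 0), cfg, seed = 122,
                          subject_id = 2L)
  d <- build_lagged_design(rbind(tr1, tr0))
  idx <- per_subject_indices(d, method = "independent")
  i1 <- idx[idx$subject == 1, ]; i0 <- idx[idx$subject == 2, ]
  # pure model-based: interaction beta positive, reward beta near zero
  expect_gt(i1$mb_index, 0.3)
  expect_lt(abs(i1$mf_index), 0.15)
  # pure model-free: reward beta positive, interaction near zero
  expect_gt(i0$mf_index, 0.3)
  expect_lt(abs(i0$mb_index), 0.15)
  # determinism
  expect_identical(idx, per_subject_indices(d, method = "independent"))
})

test_that("two-stage and hierarchical index estimates agree on well-powered cohorts", {
  # decisive choices and 500 trials per subject make both routes precise
  cfg <- cfg_exp1(n_training = 500)
  co <- generate_cohort(20, cfg,
                        spec = cohort_spec(alpha = 0.5, beta = 8, pi = 0.2),
                        seed = 123)
  d <- build_lagged_design(co$trials)
  ind <- per_subject_indices(d, method = "independent")
  ran <- per_subject_indices(d, method = "ranef")
  m <- merge(ind, ran, by = "subject", suffixes = c("_ind", "_ran"))
  expect_gte(cor(m$mb_index_ind, m$mb_index_ran, method = "spearman"), 0.8)
  expect_gte(cor(m$mf_index_ind, m$mf_index_ran, method = "spearman"), 0.8)
})

test_that("the moderated stay model recovers the generator's structure", {
  cfg <- cfg_exp1()
  co <- generate_cohort(60, cfg, seed = 124)
  dz <- cohort_deval_z(co)
  d <- build_lagged_design(co$trials)
  fit <- fit_mixed_stay_model(d, dz, engine = "twostage")
  terms <- fit$terms
  expect_equal(terms$term[8], "Reward:Transition:Devaluation")
  # mixed w cohort: reward main effect and both interactions positive
  expect_gt(terms$estimate[terms$term == "Reward"], 0)
  expect_lt(terms$p_value[terms$term == "Reward"], 0.05)
  expect_gt(terms$estimate[terms$term == "Reward:Transition"], 0)
  expect_gt(terms$estimate[terms$term == "Reward:Transition:Devaluation"], 0)
  # permuted devaluation scores: the three-way association should die
  set.seed(125)
  dz_perm <- setNames(sample(dz), names(dz))
  fitp <- fit_mixed_stay_model(d, dz_perm, engine = "twostage")
  expect_gt(fitp$terms$p_value[8], 0.01)
})

test_that("glmer and two-stage engines agree on the model's fixed-effect signs", {
  cfg <- cfg_exp1(n_training = 150)
  co <- generate_cohort(24, cfg, seed = 126)
  dz <- cohort_deval_z(co)
  d <- build_lagged_design(co$trials)
  f2 <- fit_mixed_stay_model(d, dz, engine = "twostage")
  fg <- fit_mixed_stay_model(d, dz, engine = "glmer")
  expect_equal(fg$terms$term, f2$terms$term)
  # reward effect is strongly positive under both engines
  expect_gt(fg$terms$estimate[fg$terms$term == "Reward"], 0)
  expect_lt(fg$terms$p_value[fg$terms$term == "Reward"], 0.01)
  expect_equal(sign(fg$terms$estimate[8]), sign(f2$terms$estimate[8]))
})

test_that("a pure-perseveration cohort shows only an intercept", {
  cfg <- cfg_exp1()
  spec <- cohort_spec(alpha = 0.5, beta = 0, w = c(0, 1), pi = 2)
  co <- generate_cohort(30, cfg, seed = 127)
  co_p <- generate_cohort(30, cfg, spec = spec, seed = 128)
  dz <- cohort_deval_z(co_p)
  d <- build_lagged_design(co_p$trials)
  fit <- fit_mixed_stay_model(d, dz, engine = "twostage")
  terms <- fit$terms
  expect_gt(terms$estimate[1], 0.5)        # strong stay tendency
  expect_lt(terms$p_value[1], 0.001)
  for (k in 2:8) {
    ci <- terms$estimate[k] + c(-1.96, 1.96) * terms$se[k]
    expect_true(ci[1] < 0 && ci[2] > 0)
  }
})

test_that("the index linear model detects an informative model-based index", {
  # constructed indices with a known structure: deval tracks the
  # model-based index; the model-free index is independent noise
  set.seed(129)
  n <- 80
  mb <- rnorm(n); mf <- rnorm(n)
  idx <- data.frame(subject = 1:n, intercept = 0, mf_index = mf,
                    transition = 0, mb_index = mb)
  deval <- 5 + 2 * mb + rnorm(n)
  dl <- predict_devaluation(idx, setNames(deval, 1:n))
  tm <- dl$terms
  expect_gt(tm$estimate[tm$term == "model_based"], 0)
  expect_lt(tm$p_value[tm$term == "model_based"], 0.001)
  expect_gt(tm$p_value[tm$term == "model_free"], 0.05)
  # deval independent of both indices: both CIs cover 0
  dl0 <- predict_devaluation(idx, setNames(rnorm(n), 1:n))
  for (t in c("model_based", "model_free")) {
    r <- dl0$terms[dl0$terms$term == t, ]
    expect_true(abs(r$estimate) < 1.96 * r$se)
  }
  # an independent covariate enters with its interaction and does not flip
  # the model-based coefficient
  cov <- data.frame(subject = 1:n, comprehension = rpois(n, 2))
  dl2 <- predict_devaluation(idx, setNames(deval, 1:n), covariates = cov)
  expect_true(all(c("comprehension", "model_based:comprehension") %in%
                    dl2$terms$term))
  expect_gt(dl2$terms$estimate[dl2$terms$term == "model_based"], 0)
})

test_that("on a simulated cohort the index signs mirror the generator's link", {
  cfg <- cfg_exp1()
  co <- generate_cohort(80, cfg, seed = 129)
  ss <- subject_summaries(co)
  d <- build_lagged_design(co$trials)
  idx <- per_subject_indices(d, method = "independent")
  dl <- predict_devaluation(idx, setNames(ss$deval_sensitivity, ss$subject))
  tm <- dl$terms
  # the model-based index carries the devaluation link (positive sign);
  # its marginal association is reliably positive even when the joint
  # model splits the shared signal with the collinear model-free index
  expect_gt(tm$estimate[tm$term == "model_based"], 0)
  expect_gt(cor(idx$mb_index, ss$deval_sensitivity[match(idx$subject,
                                                         ss$subject)]), 0.2)
})
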