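test_that("model-free delta rule updates the chosen action and visited state", {
  cfg <- cfg_exp1()
  st <- agent_state_init(cfg)
  st$q_mf["gold", "left"] <- 0
  p <- agent_params(alpha = 0.5, beta = 1, w = 0)
  st2 <- mf_update(st, "gold", "left", 1, p, "gold_a")
  expect_equal(st2$q_mf["gold", "left"], 0.5)
  expect_equal(st2$v2[["gold_a"]], 0.75)       # from 0.5 toward 1
  # untouched entries unchanged
  expect_equal(st2$q_mf["silver", ], st$q_mf["silver", ])
  expect_equal(st2$v2[["silver_a"]], 0.5)
  # zero learning rate: no change for any reward
  p0 <- agent_params(alpha = 0, beta = 1, w = 0)
  expect_identical(mf_update(st, "gold", "left", 1, p0, "gold_a"), st)
  expect_identical(mf_update(st, "gold", "left", 0, p0, "gold_a"), st)
  # hidden feedback is a no-op by contract
  expect_identical(mf_update(st, "gold", "left", NA, p, "gold_a"), st)
})

test_that("delta-rule values settle around the true reward probability", {
  p <- agent_params(alpha = 0.1, beta = 1, w = 0)
  cfg <- cfg_exp1()
  st <- agent_state_init(cfg)
  set.seed(31)
  vals <- numeric(10000)
  for (i in 1:10000) {
    st <- mf_update(st, "gold", "left", rbinom(1, 1, 0.65), p, "gold_a")
    vals[i] <- st$v2[["gold_a"]]
  }
  expect_equal(mean(vals[2000:10000]), 0.65, tolerance = 0.02)
})

test_that("model-based values integrate transitions with outcome values", {
  cfg <- cfg_exp1()
  st <- agent_state_init(cfg)
  st$v2[c("gold_a", "gold_b")] <- c(0.6, 0.2)
  q <- mb_values(st, "gold", cfg)
  expect_equal(unname(q), c(0.7 * 0.6 + 0.3 * 0.2, 0.7 * 0.2 + 0.3 * 0.6))
  expect_equal(unname(q), c(0.48, 0.32))
  # devaluing the richer state's coin reverses the preference
  st_dev <- st
  st_dev$outcome_value["gold_a"] <- 0
  q_dev <- mb_values(st_dev, "gold", cfg)
  expect_equal(unname(q_dev), c(0.3 * 0.2, 0.7 * 0.2))
  expect_lt(q_dev[["left"]], q_dev[["right"]])
  # symmetric transitions: equal values whenever both outcomes share value
  cfg5 <- cfg_exp1(p_common = 0.5)
  expect_equal(mb_values(st, "gold", cfg5)[["left"]],
               mb_values(st, "gold", cfg5)[["right"]])
})

test_that("softmax choice follows net value, temperature and perseveration", {
  cfg <- cfg_exp1()
  st <- agent_state_init(cfg)
  st$v2[c("gold_a", "gold_b")] <- c(0.6, 0.2)
  # beta = 0, pi = 0: flat policy
  p_flat <- choose_probs(st, agent_params(0.5, 0, 0.5), "gold", cfg)
  expect_equal(unname(p_flat), c(0.5, 0.5))
  # closed-form softmax at w = 1, beta = 10, Q_mb = (0.48, 0.32)
  p_mb <- choose_probs(st, agent_params(0.5, 10, 1), "gold", cfg)
  expect_equal(p_mb[["left"]], 1 / (1 + exp(-10 * 0.16)), tolerance = 1e-10)
  # overwhelming perseveration repeats the previous choice
  st$last_action["gold"] <- "right"
  p_per <- choose_probs(st, agent_params(0.5, 1, 0.5, pi = 50), "gold", cfg)
  expect_gt(p_per[["right"]], 0.999)
  set.seed(41)
  expect_equal(choose_action(st, agent_params(0.5, 1, 0.5, pi = 50),
                             "gold", cfg), "right")
})

test_that("respond/withhold tracks devaluation through the model-based branch", {
  cfg <- cfg_exp1()
  st <- agent_state_init(cfg)
  st$v2[] <- 0.6
  # w = 1: devaluing a game sends P(respond) toward zero when the
  # engagement rule is steep and the response cost dominates
  p1 <- agent_params(0.5, 5, w = 1, beta_resp = 200, resp_bias = 0)
  pre <- respond_probability(st, p1, "gold", cfg)
  st_dev <- devalue(st, cfg, game = "gold")
  post <- respond_probability(st_dev, p1, "gold", cfg)
  expect_gt(pre, 0.99)
  expect_lt(post, 0.15)   # E = -cost = -0.01, logistic(-2)
  # w = 0: the model-free branch cannot see devaluation at all
  p0 <- agent_params(0.5, 5, w = 0, beta_resp = 200, resp_bias = 0)
  expect_identical(respond_probability(st, p0, "gold", cfg),
                   respond_probability(st_dev, p0, "gold", cfg))
  # devaluation changes outcome_value and nothing else
  expect_identical(st_dev[c("q_mf", "v2", "last_action")],
                   st[c("q_mf", "v2", "last_action")])
})

test_that("simulated logs are reproducible and respect phase contracts", {
  cfg <- cfg_exp1()
  p <- agent_params(0.4, 4, 0.7, 0.2)
  s1 <- simulate_subject(p, cfg, seed = 51)
  s2 <- simulate_subject(p, cfg, seed = 51)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_subject(p, cfg, seed = 52)))
  # feedback is hidden outside training; no transitions either
  hidden <- s1[s1$phase != "training", ]
  expect_true(all(is.na(hidden$reward)))
  expect_true(all(hidden$transition == "none"))
  expect_true(all(is.na(hidden$second_state)))
  # training trials always respond at omission rate 0
  expect_true(all(s1$action[s1$phase == "training"] != "none"))
  # common transitions go to the action's majority destination
  tr <- s1[s1$phase == "training" & s1$transition == "common", ]
  expect_true(all(ifelse(tr$action == "left",
                         grepl("_a$", tr$second_state),
                         grepl("_b$", tr$second_state))))
  # marginal common frequency near p_common
  train <- s1[s1$phase == "training", ]
  expect_equal(mean(train$transition == "common"), 0.7,
               tolerance = 3 * sqrt(0.7 * 0.3 / nrow(train)) / 0.7)
})

test_that("training omission lapses appear at the configured rate", {
  cfg <- cfg_exp1()
  p <- agent_params(0.4, 4, 0.7)
  s <- simulate_subject(p, cfg, seed = 53, omission_rate = 0.15)
  miss <- mean(s$action[s$phase == "training"] == "none")
  expect_gt(miss, 0.08)
  expect_lt(miss, 0.25)
})

test_that("pure strategies leave their regression signatures in stay behaviour", {
  # long single runs at beta = 5, alpha = 0.5
  cfg <- cfg_exp1(n_training = 20000)
  stay_delta <- function(tr) {
    d <- build_lagged_design(tr)
    rw <- d[d$prev_reward == 1, ]
    mean(rw$stay[rw$prev_transition == 1]) -
      mean(rw$stay[rw$prev_transition == -1])
  }
  s0 <- simulate_subject(agent_params(0.5, 5, 0), cfg, seed = 61)
  s1 <- simulate_subject(agent_params(0.5, 5, 1), cfg, seed = 62)
  # model-free: reward-conditioned stay is insensitive to transition type
  expect_lt(abs(stay_delta(s0)), 0.02)
  # model-based: rewarded-rare stays less than rewarded-common (crossover)
  expect_gt(stay_delta(s1), 0.05)
})

test_that("devaluation sensitivity rises monotonically in the model-based weight", {
  cfg <- cfg_exp1()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  sens <- sapply(grid, function(w) {
    mean(sapply(1:40, function(r) {
      tr <- simulate_subject(agent_params(0.5, 5, w, 0.2), cfg,
                             seed = 700 + round(100 * w) + r)
      devaluation_sensitivity(tr, cfg)
    }))
  })
  expect_true(all(diff(sens) > -0.5))   # non-decreasing up to noise
  expect_gt(sens[5], sens[1] + 3)
  expect_lt(abs(sens[1]), 1)            # w = 0 cohort centred near 0
  expect_gt(sens[5], 6.5)               # w = 1 cohort strongly sensitive
})

test_that("cohort generation returns truth tables and respects bounds", {
  cfg <- cfg_exp1()
  expect_error(generate_cohort(1, cfg), "at least 2")
  co <- generate_cohort(20, cfg, seed = 71)
  expect_equal(nrow(co$truth), 20)
  expect_true(all(co$truth$w >= 0 & co$truth$w <= 1))
  expect_true(all(co$truth$alpha >= 0.3 & co$truth$alpha <= 0.7))
  expect_equal(sort(unique(co$trials$subject)), 1:20)
  # reproducible under the master seed
  co2 <- generate_cohort(20, cfg, seed = 71)
  expect_identical(co$trials, co2$trials)
  # null link: devaluation behaviour unrelated to w
  con <- generate_cohort(40, cfg, seed = 72, deval_link = "null")
  rho <- suppressWarnings(cor(con$truth$w, con$truth$deval_sensitivity_true,
                              method = "spearman"))
  expect_lt(abs(rho), 0.35)
})

test_that("exp2 cohorts stabilize the devalued-associated state at 0.9", {
  cfg <- cfg_exp2()
  co <- generate_cohort(6, cfg, seed = 81)
  for (s in 1:6) {
    tr <- co$trials[co$trials$subject == s, ]
    stab <- tr[tr$stabilized & tr$action != "none", ]
    dev_state <- co$truth$devalued[s]
    # empirical reward rate in the devalued-associated state is high
    rate <- mean(stab$reward[stab$second_state == dev_state])
    expect_gt(rate, 0.75)
    other <- stab$second_state != dev_state
    if (any(other)) expect_lt(mean(stab$reward[other]), 0.3)
  }
  # forced choice at test: no "none" actions
  expect_true(all(co$trials$action[co$trials$phase == "test"] != "none"))
})
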