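test_that("softmax normalization is stable, symmetric and shift invariant", {
  expect_equal(softmax_normalize(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_normalize(c(log(3), 0)), c(0.75, 0.25))
  v <- c(-2.3, 0.1, 5.7, 1e4)
  expect_equal(softmax_normalize(v), softmax_normalize(v + 123.4))
  expect_equal(sum(softmax_normalize(v)), 1)
  expect_error(softmax_normalize(c(0, NaN)), "finite")
})

test_that("floored log behaves at the boundaries and is monotone", {
  expect_lt(abs(safe_log(1)), 2e-7)  # ln(1 + e^-16)
  expect_equal(safe_log(0), -16)
  p1 <- c(0, 0.2, 0.5)
  p2 <- c(0.1, 0.4, 0.9)
  expect_true(all(safe_log(p1) <= safe_log(p2)))
  expect_error(safe_log(-0.1), "negative")
})

test_that("sensory messages are gated by rule beliefs", {
  m <- build_task_model()
  null3 <- c(0, 0, 1)
  uniform_s <- list(c(0.5, 0.5), c(0.5, 0.5), c(1, 0, 0))
  ## delay observations carry no information about any factor
  obs_delay <- list(cue = null3, vision = null3, audition = null3,
                    feedback = null3)
  msg <- likelihood_message(m, obs_delay, uniform_s, n = 2L, tau = 2L)
  expect_equal(diff(msg), 0, tolerance = 1e-12)
  ## attend-vision inferred: vision=blue drives target=blue; audition flat
  obs3 <- list(cue = null3, vision = c(1, 0, 0), audition = c(0, 1, 0),
               feedback = null3)
  s_av <- list(c(1, 0), c(0.5, 0.5), c(1, 0, 0))
  msg_av <- likelihood_message(m, obs3, s_av, n = 2L, tau = 3L)
  expect_gt(msg_av[1] - msg_av[2], 10)
  ## uncommitted rule + contradictory stimuli: no net target evidence
  msg_un <- likelihood_message(m, obs3, uniform_s, n = 2L, tau = 3L)
  expect_equal(msg_un[1], msg_un[2], tolerance = 1e-12)
  ## outcomes must be one-hot
  bad <- obs3
  bad$vision <- c(0.5, 0.5, 0)
  expect_error(likelihood_message(m, bad, s_av, n = 2L, tau = 3L), "one-hot")
})

test_that("cue observation drives and the delay maintains rule beliefs", {
  m <- build_task_model()
  s <- engine_settings()
  cond <- trial_condition("attend-audition", "blue", seed = 3L)
  tr <- run_trial(m, s, cond)
  b1 <- bma_beliefs(tr, 1L)
  expect_gt(b1$rule[2, 1], 0.99)
  b2 <- bma_beliefs(tr, 2L)
  expect_equal(b2$rule[, 2], b2$rule[, 1], tolerance = 1e-3)
  expect_gt(b2$rule[2, 2], 0.99)
})

test_that("predicted outcomes are normalized and reflect the matching rule", {
  m <- build_task_model()
  st <- init_belief_state(m)
  pred <- predict_outcomes(m, st)
  for (g in names(pred)) {
    expect_true(all(abs(colSums(pred[[g]]) - 1) < 1e-9))
  }
  ## uniform beliefs at the delay step predict null with certainty
  expect_equal(pred$vision[, 2], c(0, 0, 1))
  ## known target + picked matching choice predict correct feedback
  st$s$target[, 4] <- c(1, 0)
  st$s$choice[, 4] <- c(0, 1, 0)
  pred2 <- predict_outcomes(m, st, taus = 4L)
  expect_equal(pred2$feedback[, 4], c(1, 0, 0))
})

test_that("free energy is a bound on surprise, tight for representable posteriors", {
  ## deterministic (injective) likelihoods concentrate the posterior, which
  ## the mean-field family can represent: the bound should be tight
  st <- oracle_settings(lambda = exp(-32))
  for (seed in 1:8) {
    mod <- random_small_model(seed, sizes = 2L, n_out = 2L, det_A = TRUE)
    samp <- sample_process_obs(mod, seed + 100L)
    ex <- exact_smoothing(mod, 1L, samp$obs)
    if (!is.finite(ex$log_evidence)) next
    up <- state_update(mod, 1L, samp$obs, st)
    Fv <- free_energy(mod, up, samp$obs, 1L, st)
    expect_gte(Fv, -ex$log_evidence - 1e-9)
    expect_lt(Fv + ex$log_evidence, 1e-6)
  }
  ## for arbitrary beliefs the bound still holds
  for (seed in 9:16) {
    mod <- random_small_model(seed)
    samp <- sample_process_obs(mod, seed + 100L)
    ex <- exact_smoothing(mod, 1L, samp$obs)
    if (!is.finite(ex$log_evidence)) next
    up <- state_update(mod, 1L, samp$obs, oracle_settings())
    Fv <- free_energy(mod, up, samp$obs, 1L, oracle_settings())
    expect_gte(Fv, -ex$log_evidence - 1e-9)
  }
})

test_that("free energy vanishes at the prior under marginal messages", {
  ## with no observations and beliefs equal to the forward-propagated
  ## prior, complexity cancels exactly term by term in the marginal form
  set <- engine_settings(message_form = "marginal")
  mod <- random_small_model(21)
  st <- init_belief_state(mod)
  st$s$f1[, 1] <- mod$D$f1
  for (tau in 2:mod$horizon) {
    st$s$f1[, tau] <- as.vector(mod$B$f1[, , 1] %*% st$s$f1[, tau - 1])
  }
  expect_equal(free_energy(mod, st, list(), 1L, set), 0, tolerance = 1e-12)
})

test_that("converged beliefs track exact smoothing", {
  ## deterministic models: exact agreement
  for (seed in 1:10) {
    mod <- random_small_model(seed, det_A = TRUE, det_B = TRUE)
    samp <- sample_process_obs(mod, seed + 50L)
    ex <- exact_smoothing(mod, 1L, samp$obs)
    if (!is.finite(ex$log_evidence)) next
    up <- state_update(mod, 1L, samp$obs, oracle_settings())
    expect_lt(max(abs(up$s$f1 - ex$marginals$f1)), 1e-6)
    ## half-averaged weighting shares the deterministic fixed point
    up2 <- state_update(mod, 1L, samp$obs,
                        oracle_settings(weighting = "half-averaged"))
    expect_lt(max(abs(up2$s$f1 - ex$marginals$f1)), 1e-6)
  }
  ## stochastic chains: mean-field marginals typically agree closely
  kls <- c()
  for (seed in 1:20) {
    mod <- random_small_model(seed)
    samp <- sample_process_obs(mod, seed + 50L)
    ex <- exact_smoothing(mod, 1L, samp$obs)
    if (!is.finite(ex$log_evidence)) next
    up <- state_update(mod, 1L, samp$obs, oracle_settings())
    kls <- c(kls, max(sapply(seq_len(mod$horizon), function(tau)
      kl_div(ex$marginals$f1[, tau], up$s$f1[, tau]))))
  }
  expect_gt(length(kls), 10)
  expect_lt(median(kls), 0.05)
  ## two-factor model, deterministic: still exact
  mod2 <- random_small_model(31, sizes = c(2L, 3L), n_out = c(3L, 2L),
                             det_A = TRUE, det_B = TRUE)
  samp2 <- sample_process_obs(mod2, 77L)
  ex2 <- exact_smoothing(mod2, 1L, samp2$obs)
  up2 <- state_update(mod2, 1L, samp2$obs, oracle_settings())
  expect_lt(max(abs(up2$s$f1 - ex2$marginals$f1)), 1e-6)
  expect_lt(max(abs(up2$s$f2 - ex2$marginals$f2)), 1e-6)
})

test_that("expected free energy combines risk and ambiguity as documented", {
  ## one-hot prediction against normalized-uniform log preferences with a
  ## deterministic likelihood: each term contributes ln 3
  mod <- random_small_model(41, sizes = 3L, n_out = 3L, det_A = TRUE)
  mod$C$g1[, ] <- log(1 / 3)
  st <- init_belief_state(mod)
  for (tau in 1:3) st$s$f1[, tau] <- c(1, 0, 0)
  g_all <- expected_free_energy(mod, st, 1L, t = 2L)
  expect_equal(g_all, log(3), tolerance = 1e-4)

  ## task model after inference: picking the inferred target beats the
  ## alternative by exactly 2c in the feedback risk term
  m <- build_task_model(preference = 3)
  cond <- trial_condition(1, 1, seed = 11L)
  tr <- run_trial(m, engine_settings(), cond)
  G3 <- tr$G[3, ]
  correct_policy <- 1L + cond$target
  wrong_policy <- setdiff(2:3, correct_policy)
  expect_equal(G3[correct_policy] - G3[wrong_policy], -6, tolerance = 1e-4)

  ## medial lesion: uniform feedback likelihood equalizes G across policies
  med <- apply_lesion(m, lesion_config("medial", 1))
  trm <- run_trial(med, engine_settings(), cond)
  expect_lt(diff(range(trm$G[3, ])), 1e-9)
})

test_that("policy posterior is a softmax of negated free energies", {
  expect_equal(policy_posterior(rep(1, 3), rep(2, 3)), rep(1 / 3, 3))
  post <- policy_posterior(rep(0, 3), c(0, 6, 6))
  expect_equal(post[1], 1 / (1 + 2 * exp(-6)), tolerance = 1e-12)
  base <- policy_posterior(c(1, 2, 3), c(0.5, 0, 1))
  shifted <- policy_posterior(c(1, 2, 3) + 7, c(0.5, 0, 1))
  expect_equal(base, shifted)
  expect_error(policy_posterior(c(0, Inf), c(0, 0)), "finite")
})

test_that("action selection marginalizes policies and breaks ties low", {
  pol <- build_policy_set("terminal-choice", 4L)
  expect_equal(select_action(c(0.99, 0.005, 0.005), pol, 3L), 1L)
  expect_equal(select_action(rep(1 / 3, 3), pol, 1L), 1L)  # unanimity: stay
  expect_equal(select_action(c(0, 0.5, 0.5), pol, 3L), 2L) # tie -> pick-blue
  expect_error(select_action(c(1, 0, 0), pol, 4L), "policy length")
})

test_that("belief, outcome and policy distributions stay normalized", {
  m <- build_task_model()
  tr <- run_trial(m, engine_settings(), trial_condition(2, 2, seed = 13L),
                  trace = TRUE)
  for (e in 1:4) {
    expect_equal(sum(tr$policy_posterior[e, ]), 1, tolerance = 1e-9)
    for (i in seq_len(tr$n_iter)) {
      expect_true(all(abs(rowSums(tr$trace[[e]]$post_iter) - 1) < 1e-9))
      st <- tr$trace[[e]]$per_policy[[1]][[i]]
      for (n in seq_along(st$s)) {
        expect_true(all(abs(colSums(st$s[[n]]) - 1) < 1e-9))
        expect_true(all(st$s[[n]] > 0))
      }
    }
  }
})

test_that("posterior-weighted free energy descends within epochs", {
  m <- build_task_model()
  tr <- run_trial(m, engine_settings(), trial_condition(1, 2, seed = 17L),
                  trace = TRUE)
  for (e in 1:4) {
    tot <- rowSums(tr$trace[[e]]$F_iter * tr$trace[[e]]$post_iter)
    expect_lt(max(diff(tot)), 1e-6)
  }
})

test_that("units switch from predictive to mnemonic coding around the cue", {
  m <- build_task_model()
  set <- engine_settings()
  ## before any observation, beliefs about every time are the uniform prior
  st0 <- state_update(m, 1L, list(), set)
  expect_equal(st0$s$rule[, 1], c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(st0$s$rule[, 4], c(0.5, 0.5), tolerance = 1e-6)
  ## after the cue, the tau=1 units hold a concentrated (mnemonic) belief
  ## through the rest of the trial
  tr <- run_trial(m, set, trial_condition(2, 1, seed = 19L), trace = TRUE)
  for (e in 1:4) {
    b <- bma_beliefs(tr, e)
    expect_gt(max(b$rule[, 1]), 0.9)
  }
})

test_that("divergent settings raise a numeric error naming the settings", {
  m <- build_task_model()
  obs <- list(emit_outcomes(trial_condition(1, 1, seed = 1L), 1L, 1L))
  ## an absurd potential makes the error exceed the guard
  st <- init_belief_state(m)
  st$v$rule[1, 1] <- 1e7
  expect_error(state_update(m, 1L, obs, engine_settings(), state = st),
               "kappa")
})
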