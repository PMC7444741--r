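#' Trial condition
#'
#' The true attentional rule and target for one trial, plus the seed driving
#' that trial's private randomness (distractor draws).
#'
#' @param rule Rule level index (1 = attend-vision, 2 = attend-audition) or
#'   label.
#' @param target Target level index (1 = blue, 2 = green) or label.
#' @param seed Integer seed for the trial's random draws.
#' @return A `trial_condition` list.
#' @export
trial_condition <- function(rule, target, seed = 1L) {
  rl <- c("attend-vision", "attend-audition")
  tl <- c("blue", "green")
  if (is.character(rule)) rule <- match(rule, rl)
  if (is.character(target)) target <- match(target, tl)
  if (!rule %in% 1:2 || !target %in% 1:2) {
    stop("trial_condition: rule and target must be valid levels")
  }
  structure(list(rule = as.integer(rule), target = as.integer(target),
                 seed = as.integer(seed)),
            class = "trial_condition")
}

#' Sample a trial condition
#'
#' Rule and target are drawn independently and uniformly.
#'
#' @param seed Optional integer seed; when supplied the draw is made in a
#'   local RNG stream (global RNG state untouched) and recorded in the
#'   condition.
#' @return A [trial_condition()].
#' @export
sample_condition <- function(seed = NULL) {
  draw <- function() trial_condition(sample.int(2L, 1L), sample.int(2L, 1L),
                                     seed = if (is.null(seed)) 0L else seed)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Emit the outcomes for one trial phase
#'
#' The generative process mirrors the task model's likelihood evaluated at
#' the true states: step 1 the cue reflects the rule; step 2 everything is
#' null; step 3 the attended modality shows the target and the unattended
#' modality shows a distractor; step 4 feedback is correct exactly when the
#' choice state matches the target (no-choice is incorrect).
#'
#' @param condition A [trial_condition()].
#' @param choice_state Current choice level (1 no-choice, 2 blue, 3 green).
#' @param tau Trial phase, 1..4.
#' @param distractor `"independent"` draws the unattended stimulus uniformly
#'   from the two stimulus levels (matching the model's uniform likelihood);
#'   `"incongruent"` always shows the opposite of the target (the conflict
#'   condition of the divided-attention task). Uses the current RNG.
#' @return List of one-hot outcome vectors named cue, vision, audition,
#'   feedback.
#' @export
emit_outcomes <- function(condition, choice_state, tau,
                          distractor = c("independent", "incongruent")) {
  distractor <- match.arg(distractor)
  if (!tau %in% 1:4) stop("emit_outcomes: tau must be in 1..4")
  null3 <- one_hot(3L, 3L)
  obs <- list(cue = null3, vision = null3, audition = null3, feedback = null3)
  if (tau == 1L) {
    obs$cue <- one_hot(condition$rule, 3L)
  } else if (tau == 3L) {
    dis <- if (distractor == "independent") sample.int(2L, 1L) else
      3L - condition$target
    if (condition$rule == 1L) {
      obs$vision <- one_hot(condition$target, 3L)
      obs$audition <- one_hot(dis, 3L)
    } else {
      obs$audition <- one_hot(condition$target, 3L)
      obs$vision <- one_hot(dis, 3L)
    }
  } else if (tau == 4L) {
    obs$feedback <- one_hot(if (choice_state == condition$target + 1L) 1L
                            else 2L, 3L)
  }
  obs
}

#' Run one perception-action trial
#'
#' Executes the four observation epochs: outcomes are emitted from the true
#' condition, beliefs are updated for every policy (warm-started across
#' epochs), policies are scored by free energy plus expected free energy,
#' and for epochs 1..3 the marginal-posterior action is selected and applied
#' to the true choice state.
#'
#' @param model A `gen_model` (typically [build_task_model()], possibly
#'   lesioned).
#' @param settings An [engine_settings()] list.
#' @param condition A [trial_condition()].
#' @param distractor Passed to [emit_outcomes()].
#' @param trace Keep iteration-resolved belief trajectories and
#'   per-iteration policy evaluations (needed by [firing_rates()] and
#'   [build_design()]).
#' @return A `trial_record`: condition, observations, actions, per-epoch
#'   `F`, `G` and policy posterior (epoch x policy matrices), per-epoch
#'   belief snapshots, final per-policy states, feedback, `correct` and
#'   `congruent` flags, and (with `trace = TRUE`) per-epoch iteration traces
#'   with per-iteration `F_iter`, `G_iter`, `post_iter`.
#' @export
run_trial <- function(model, settings = engine_settings(), condition,
                      distractor = c("independent", "incongruent"),
                      trace = FALSE) {
  distractor <- match.arg(distractor)
  TT <- model$horizon
  np <- nrow(model$policies)
  run <- function() {
    observations <- vector("list", TT)
    actions <- integer(0)
    Fm <- matrix(NA_real_, TT, np)
    Gm <- matrix(NA_real_, TT, np)
    postm <- matrix(NA_real_, TT, np)
    epoch_states <- vector("list", TT)
    traces <- if (trace) vector("list", TT) else NULL
    states <- NULL
    choice_state <- 1L
    obs_seq <- list()
    for (t in seq_len(TT)) {
      observations[[t]] <- emit_outcomes(condition, choice_state, t, distractor)
      obs_seq[[t]] <- observations[[t]]
      ev <- evaluate_policies(model, obs_seq, settings,
                              states = if (is.null(states)) NULL else
                                lapply(states, function(x) x[c("s", "v")]),
                              trace = trace)
      states <- ev$states
      Fm[t, ] <- ev$F
      Gm[t, ] <- ev$G
      postm[t, ] <- ev$posterior
      epoch_states[[t]] <- lapply(states, function(x) x$s)
      if (trace) {
        it <- iteration_evaluations(model, states, obs_seq, settings)
        traces[[t]] <- list(per_policy = lapply(states, function(x) x$trace),
                            F_iter = it$F, G_iter = it$G, post_iter = it$post)
      }
      if (t < TT) {
        u <- select_action(ev$posterior, model$policies, t)
        actions <- c(actions, u)
        bc <- model$B[[model$control_factor]][, choice_state, u]
        choice_state <- which.max(bc)
      }
    }
    fb <- which(observations[[TT]]$feedback == 1)
    structure(list(
      condition = condition,
      distractor = distractor,
      observations = observations,
      actions = actions,
      F = Fm, G = Gm, policy_posterior = postm,
      epoch_states = epoch_states,
      states = lapply(states, function(x) x[c("s", "v")]),
      trace = traces,
      n_iter = settings$n_iter,
      feedback = c("correct", "incorrect", "null")[fb],
      correct = fb == 1L,
      congruent = is_congruent(observations, condition),
      final_choice = choice_state
    ), class = "trial_record")
  }
  with_local_seed(condition$seed, run())
}

## Did the unattended stimulus agree with the target?
is_congruent <- function(observations, condition) {
  o3 <- observations[[3]]
  unatt <- if (condition$rule == 1L) o3$audition else o3$vision
  which.max(unatt) == condition$target
}

## Per-iteration F, G and policy posterior recovered from stored traces.
iteration_evaluations <- function(model, states, obs_seq, settings) {
  np <- length(states)
  ni <- settings$n_iter
  t_obs <- length(obs_seq)
  F <- matrix(NA_real_, ni, np)
  G <- matrix(NA_real_, ni, np)
  post <- matrix(NA_real_, ni, np)
  for (i in seq_len(ni)) {
    for (p in seq_len(np)) {
      st <- states[[p]]$trace[[i]]
      F[i, p] <- free_energy(model, st, obs_seq, p, settings)
      G[i, p] <- expected_free_energy(model, st, p, t_obs, settings)
    }
    Fv <- if (settings$policy_value == "both") F[i, ] else numeric(np)
    post[i, ] <- policy_posterior(Fv, G[i, ], settings$gamma)
  }
  list(F = F, G = G, post = post)
}

#' Bayesian-model-average beliefs at one epoch
#'
#' Policy-posterior-weighted mixture of the per-policy state beliefs
#' recorded at the end of an observation epoch.
#'
#' @param trial A `trial_record`.
#' @param epoch Observation epoch 1..T.
#' @return List over factors of `level x represented-time` matrices.
#' @export
bma_beliefs <- function(trial, epoch) {
  post <- trial$policy_posterior[epoch, ]
  per_policy <- trial$epoch_states[[epoch]]
  out <- per_policy[[1]]
  for (n in seq_along(out)) {
    acc <- out[[n]] * post[1]
    for (p in seq_along(per_policy)[-1]) {
      acc <- acc + per_policy[[p]][[n]] * post[p]
    }
    out[[n]] <- acc
  }
  out
}

#' Run a session of independent trials
#'
#' Conditions are drawn uniformly at random from a sub-stream of the master
#' seed; each trial gets its own derived seed, so sessions are reproducible
#' from `(model, settings, n_trials, seed)` alone.
#'
#' @param model,settings As in [run_trial()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Master integer seed.
#' @param distractor Passed to [run_trial()].
#' @param keep_trials Keep the individual `trial_record`s in the summary.
#' @return A `session_summary`: accuracy, per-condition accuracy, accuracy
#'   split by distractor congruency, mean epoch-3 policy-posterior entropy,
#'   and the trial records.
#' @export
run_session <- function(model, settings = engine_settings(), n_trials, seed = 1L,
                        distractor = c("independent", "incongruent"),
                        keep_trials = TRUE) {
  distractor <- match.arg(distractor)
  if (n_trials < 1L) stop("run_session: n_trials must be >= 1")
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cond <- sample_condition(seed = derive_seed(seed, 2L * i))
    cond$seed <- derive_seed(seed, 2L * i + 1L)
    trials[[i]] <- run_trial(model, settings, cond, distractor)
  }
  correct <- vapply(trials, `[[`, logical(1), "correct")
  congr <- vapply(trials, `[[`, logical(1), "congruent")
  rule <- vapply(trials, function(x) x$condition$rule, integer(1))
  targ <- vapply(trials, function(x) x$condition$target, integer(1))
  per_cond <- stats::aggregate(correct,
                        by = list(rule = rule, target = targ), FUN = mean)
  names(per_cond)[3] <- "accuracy"
  ent3 <- vapply(trials, function(x) shannon_entropy(x$policy_posterior[3, ]),
                 numeric(1))
  structure(list(
    n_trials = n_trials,
    seed = seed,
    distractor = distractor,
    accuracy = mean(correct),
    per_condition = per_cond,
    accuracy_congruent = if (any(congr)) mean(correct[congr]) else NA_real_,
    accuracy_incongruent = if (any(!congr)) mean(correct[!congr]) else NA_real_,
    prop_congruent = mean(congr),
    mean_policy_entropy_epoch3 = mean(ent3),
    trials = if (keep_trials) trials else NULL
  ), class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %d trials (seed %d, distractor %s)\n",
              x$n_trials, x$seed, x$distractor))
  cat(sprintf("  accuracy %.3f | congruent %.3f | incongruent %.3f\n",
              x$accuracy, x$accuracy_congruent, x$accuracy_incongruent))
  cat(sprintf("  mean policy entropy at epoch 3: %.3f nats\n",
              x$mean_policy_entropy_epoch3))
  invisible(x)
}
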