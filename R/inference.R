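#' Inference engine settings
#'
#' Numerical settings for the variational message passing. Defaults give
#' smooth, convergent belief trajectories suitable for the simulated
#' electrophysiology: 16 gradient iterations per observation epoch with step
#' size 0.25 (so potentials close about 99 percent of the gap to their fixed
#' point within an epoch), a log floor of `exp(-16)` wherever a log of a
#' probability is taken, and unit policy precision.
#'
#' @param n_iter Iterations per observation epoch (positive integer).
#' @param kappa Gradient step size in (0, 1].
#' @param lambda Positive log floor used by [safe_log()].
#' @param gamma Policy precision (positive).
#' @param weighting `"full-sum"` adds forward and backward messages at full
#'   weight; `"half-averaged"` halves them, as in marginal message-passing
#'   variants.
#' @param message_form `"expected-log"` (default) propagates expectations of
#'   log-transition probabilities (`E_s[ln B]`), the exact mean-field
#'   messages whose flow descends the variational free energy and keeps it
#'   an evidence bound; `"marginal"` propagates logs of expected transitions
#'   (`ln(B s)`), the marginal-message variant.
#' @param policy_value `"both"` scores policies by -(F + G); `"prior-only"`
#'   by -G alone.
#' @return An `engine_settings` list.
#' @export
engine_settings <- function(n_iter = 16L, kappa = 0.25, lambda = exp(-16),
                            gamma = 1,
                            weighting = c("full-sum", "half-averaged"),
                            message_form = c("expected-log", "marginal"),
                            policy_value = c("both", "prior-only")) {
  weighting <- match.arg(weighting)
  message_form <- match.arg(message_form)
  policy_value <- match.arg(policy_value)
  stopifnot(n_iter >= 1, kappa > 0, kappa <= 1, lambda > 0, gamma > 0)
  structure(list(n_iter = as.integer(n_iter), kappa = kappa, lambda = lambda,
                 gamma = gamma, weighting = weighting,
                 message_form = message_form, policy_value = policy_value),
            class = "engine_settings")
}

## Forward/backward transition messages for factor n at time tau, under the
## chosen message form.
transition_messages <- function(model, policy_index, n, tau, s_n, settings) {
  TT <- model$horizon
  lambda <- settings$lambda
  B <- model$B[[n]]
  expected <- settings$message_form == "expected-log"
  if (tau == 1L) {
    fwd <- safe_log(model$D[[n]], lambda)
  } else {
    a_prev <- policy_action(model, policy_index, n, tau - 1L)
    fwd <- if (expected) {
      as.vector(safe_log(B[, , a_prev], lambda) %*% s_n[, tau - 1L])
    } else {
      safe_log(as.vector(B[, , a_prev] %*% s_n[, tau - 1L]), lambda)
    }
  }
  if (tau < TT) {
    a_cur <- policy_action(model, policy_index, n, tau)
    bwd <- if (expected) {
      as.vector(crossprod(safe_log(B[, , a_cur], lambda), s_n[, tau + 1L]))
    } else {
      safe_log(as.vector(crossprod(B[, , a_cur], s_n[, tau + 1L])), lambda)
    }
  } else bwd <- 0
  list(fwd = fwd, bwd = bwd)
}

## Fresh (uniform, v = 0) belief state for one policy: lists over factors of
## level x time matrices.
init_belief_state <- function(model) {
  ns <- n_levels(model)
  TT <- model$horizon
  v <- lapply(ns, function(k) matrix(0, nrow = k, ncol = TT))
  s <- lapply(ns, function(k) matrix(1 / k, nrow = k, ncol = TT))
  names(v) <- names(s) <- names(model$factors)
  list(s = s, v = v)
}

#' Sensory message to one hidden-state factor
#'
#' Sums, over outcome modalities, the contraction of the floored
#' log-likelihood with the observed (one-hot) outcome and with the current
#' beliefs about every other factor. This contraction is how beliefs about
#' the rule gate the mapping from the sensory modalities onto the target
#' population: an attended (precise) modality contributes a sharply peaked
#' message, an unattended (uniform) one contributes a constant.
#'
#' @param model A `gen_model`.
#' @param obs List of one-hot outcome vectors, one per modality.
#' @param s List of belief vectors at time `tau`, one per factor.
#' @param n Index of the factor receiving the message.
#' @param tau Time step of the observation.
#' @param lambda Log floor.
#' @return Real vector over the levels of factor `n`.
#' @export
likelihood_message <- function(model, obs, s, n, tau, lambda = exp(-16)) {
  ns <- n_levels(model)
  nf <- length(ns)
  msg <- numeric(ns[n])
  for (g in seq_along(model$modalities)) {
    og <- obs[[g]]
    if (!is_one_hot(og)) {
      stop(sprintf("likelihood_message: outcome for modality '%s' is not one-hot",
                   names(model$modalities)[g]))
    }
    lA <- safe_log(model$A[[g]][[tau]], lambda)
    m <- contract_dims(lA, list(og), 1L)          # drop the outcome index
    others <- setdiff(seq_len(nf), n)
    if (length(others)) m <- contract_dims(m, s[others], others)
    msg <- msg + m
  }
  msg
}

#' Variational belief update for one policy
#'
#' Runs `n_iter` gradient iterations of the message-passing scheme: for each
#' represented time `tau` and factor `n`, the prediction error is the sum of
#' the forward message (log prior at `tau = 1`, else the log of the
#' transition-propagated previous beliefs), the backward message (log of the
#' transposed-transition-propagated next beliefs), and the sensory message
#' for already-observed times, minus the current potential `v`. Potentials
#' move a fraction `kappa` along the error and expectations are their
#' softmax. Beliefs persist across observation epochs (warm start) when the
#' previous `state` is supplied.
#'
#' @param model A `gen_model`.
#' @param policy_index Row of `model$policies`.
#' @param obs_seq List of per-epoch observation lists (each a list of one-hot
#'   vectors per modality); `length(obs_seq)` is the current time `t`.
#' @param settings An [engine_settings()] list.
#' @param state Previous belief state for this policy, or `NULL` to start
#'   from uniform beliefs (v = 0).
#' @param trace If `TRUE`, keep the full iteration-resolved trajectory of
#'   `s` and `v` (used by the electrophysiology module).
#' @return List with elements `s`, `v` (belief state) and, if requested,
#'   `trace` (one entry per iteration with that iteration's `s` and `v`).
#' @export
state_update <- function(model, policy_index, obs_seq, settings = engine_settings(),
                         state = NULL, trace = FALSE) {
  TT <- model$horizon
  t_obs <- length(obs_seq)
  if (is.null(state)) state <- init_belief_state(model)
  s <- state$s
  v <- state$v
  nf <- length(model$factors)
  lambda <- settings$lambda
  w <- if (settings$weighting == "full-sum") 1 else 0.5
  kappa <- settings$kappa
  tr <- if (trace) vector("list", settings$n_iter) else NULL
  ## observation-collapsed log-likelihoods, summed over modalities: one
  ## array over the joint state space per observed time
  M <- obs_loglik_arrays(model, obs_seq, lambda)

  for (i in seq_len(settings$n_iter)) {
    ## parallel (Jacobi) update: every unit computes its prediction error
    ## from the same snapshot of activity, then all potentials move at once,
    ## so beliefs propagate one represented-time step per iteration
    s0 <- s
    for (tau in seq_len(TT)) {
      for (n in seq_len(nf)) {
        tm <- transition_messages(model, policy_index, n, tau, s0[[n]],
                                  settings)
        fwd <- tm$fwd
        bwd <- tm$bwd
        lik <- if (tau <= t_obs) {
          others <- setdiff(seq_len(nf), n)
          if (length(others)) {
            contract_dims(M[[tau]], lapply(s0[others], function(m) m[, tau]),
                          others)
          } else M[[tau]]
        } else 0
        eps <- w * (fwd + bwd) + lik - v[[n]][, tau]
        if (any(abs(eps) > 1e6)) {
          stop(sprintf(paste0("state_update: prediction error diverged ",
                              "(|eps| > 1e6) with kappa=%g, n_iter=%d"),
                       kappa, settings$n_iter))
        }
        v[[n]][, tau] <- v[[n]][, tau] + kappa * eps
        s[[n]][, tau] <- softmax_normalize(v[[n]][, tau])
      }
    }
    if (trace) tr[[i]] <- list(s = s, v = v)
  }
  out <- list(s = s, v = v)
  if (trace) out$trace <- tr
  out
}

## Collapse each observed outcome against the floored log-likelihood and sum
## over modalities: M[[tau]] is an array over the joint hidden-state space
## whose contraction with per-factor beliefs yields the sensory message.
obs_loglik_arrays <- function(model, obs_seq, lambda) {
  lapply(seq_along(obs_seq), function(tau) {
    M <- 0
    for (g in seq_along(model$modalities)) {
      lA <- safe_log(model$A[[g]][[tau]], lambda)
      M <- M + contract_dims(lA, list(obs_seq[[tau]][[g]]), 1L)
    }
    M
  })
}

#' Predicted outcome distributions under one policy
#'
#' Contracts each time-step likelihood with the factorized state beliefs to
#' give the outcome distribution expected under the policy.
#'
#' @param model A `gen_model`.
#' @param state Belief state (as from [state_update()]).
#' @param taus Time steps to evaluate (default all).
#' @return List over modalities of `outcome x time` matrices, each column a
#'   probability vector.
#' @export
predict_outcomes <- function(model, state, taus = seq_len(model$horizon)) {
  nf <- length(model$factors)
  out <- lapply(seq_along(model$modalities), function(g) {
    m <- matrix(NA_real_, nrow = length(model$modalities[[g]]$levels),
                ncol = model$horizon)
    for (tau in taus) {
      s_tau <- lapply(state$s, function(x) x[, tau])
      m[, tau] <- contract_dims(model$A[[g]][[tau]], s_tau, 1L + seq_len(nf))
    }
    m
  })
  names(out) <- names(model$modalities)
  out
}

#' Variational free energy of one policy
#'
#' Complexity (divergence of beliefs from their forward-message predictions,
#' summed over factors and times) minus accuracy (expected floored
#' log-likelihood of the outcomes observed so far). Evaluated at the current
#' beliefs; at the prior with no observations it is exactly zero.
#'
#' @inheritParams state_update
#' @param state Belief state for this policy.
#' @return Scalar free energy (nats).
#' @export
free_energy <- function(model, state, obs_seq, policy_index,
                        settings = engine_settings()) {
  TT <- model$horizon
  t_obs <- length(obs_seq)
  lambda <- settings$lambda
  nf <- length(model$factors)
  F <- 0
  for (tau in seq_len(TT)) {
    for (n in seq_len(nf)) {
      s_n <- state$s[[n]][, tau]
      fwd <- transition_messages(model, policy_index, n, tau, state$s[[n]],
                                 settings)$fwd
      F <- F + sum(s_n * (safe_log(s_n, lambda) - fwd))
    }
    if (tau <= t_obs) {
      s_tau <- lapply(state$s, function(x) x[, tau])
      M <- obs_loglik_cache(model, obs_seq, lambda)
      F <- F - contract_dims(M[[tau]], s_tau, seq_len(nf))
    }
  }
  F
}

## Memoize the observation-collapsed log-likelihood arrays on the obs_seq
## object itself so repeated free-energy evaluations (per-iteration traces)
## do not recompute them.
obs_loglik_cache <- local({
  last_key <- NULL
  last_val <- NULL
  function(model, obs_seq, lambda) {
    key <- list(obs_seq, lambda, model$A)
    if (!identical(key, last_key)) {
      last_val <<- obs_loglik_arrays(model, obs_seq, lambda)
      last_key <<- key
    }
    last_val
  }
})

## Negative-entropy vectors of the likelihood mapping: for each modality and
## time, an array over joint states with H_i = sum_j A[j|i] ln A[j|i]
## (0 ln 0 := 0, so deterministic columns give exactly 0).
likelihood_neg_entropy <- function(model, g, tau) {
  a <- model$A[[g]][[tau]]
  la <- ifelse(a > 0, log(a), 0)
  apply(a * la, seq_along(dim(a))[-1L], sum)
}

## Memoized table of the H arrays for all (modality, time) pairs.
neg_entropy_cache <- local({
  last_key <- NULL
  last_val <- NULL
  function(model) {
    key <- model$A
    if (!identical(key, last_key)) {
      last_val <<- lapply(seq_along(model$modalities), function(g)
        lapply(seq_len(model$horizon), function(tau)
          likelihood_neg_entropy(model, g, tau)))
      last_key <<- key
    }
    last_val
  }
})

#' Expected free energy of one policy
#'
#' Sums, over future time steps and modalities, the risk (divergence of the
#' predicted outcome distribution from the log-preferences) and the
#' ambiguity (expected outcome entropy given states):
#' `G = sum_tau sum_g [ o.(log o - C) - E_s[H] ]` with `H` the
#' negative-entropy vector of the likelihood.
#'
#' @inheritParams free_energy
#' @param t Current observation time; G sums over `tau = t+1 .. T`.
#' @return Scalar expected free energy (nats).
#' @export
expected_free_energy <- function(model, state, policy_index, t,
                                 settings = engine_settings()) {
  TT <- model$horizon
  lambda <- settings$lambda
  nf <- length(model$factors)
  if (t >= TT) return(0)
  G <- 0
  Hs <- neg_entropy_cache(model)
  pred <- predict_outcomes(model, state, taus = (t + 1L):TT)
  for (tau in (t + 1L):TT) {
    s_tau <- lapply(state$s, function(x) x[, tau])
    for (g in seq_along(model$modalities)) {
      o <- pred[[g]][, tau]
      risk <- sum(o * (safe_log(o, lambda) - model$C[[g]][tau, ]))
      amb <- -contract_dims(Hs[[g]][[tau]], s_tau, seq_len(nf))
      G <- G + risk + amb
    }
  }
  G
}

#' Posterior over policies
#'
#' Softmax of the negated, precision-weighted sum of variational and
#' expected free energies: `softmax(-gamma * (F + G))`.
#'
#' @param F,G Numeric vectors of per-policy (expected) free energies.
#' @param gamma Policy precision (default 1).
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(F, G, gamma = 1) {
  if (!all(is.finite(F)) || !all(is.finite(G))) {
    stop("policy_posterior: non-finite free energies")
  }
  softmax_normalize(-gamma * (F + G))
}

#' Select the next action
#'
#' Marginalizes the policy posterior onto the action prescribed at step `t`
#' and returns the action with the greatest mass; exact ties resolve to the
#' lowest action index.
#'
#' @param posterior Probability vector over policies.
#' @param policies Policy matrix (one row per policy).
#' @param t Action slot (1 .. T-1).
#' @return Integer action index.
#' @export
select_action <- function(posterior, policies, t) {
  if (t > ncol(policies)) stop("select_action: t exceeds the policy length")
  acts <- policies[, t]
  mass <- vapply(seq_len(max(policies)), function(u) sum(posterior[acts == u]),
                 numeric(1))
  which.max(mass)
}

## Per-policy evaluation at the current epoch: updated states, F, G and the
## policy posterior. `states` is a list over policies (NULL at trial start).
evaluate_policies <- function(model, obs_seq, settings, states = NULL,
                              trace = FALSE) {
  np <- nrow(model$policies)
  t_obs <- length(obs_seq)
  if (is.null(states)) states <- vector("list", np)
  res <- vector("list", np)
  F <- numeric(np)
  G <- numeric(np)
  for (p in seq_len(np)) {
    res[[p]] <- state_update(model, p, obs_seq, settings, states[[p]],
                             trace = trace)
    F[p] <- free_energy(model, res[[p]], obs_seq, p, settings)
    G[p] <- expected_free_energy(model, res[[p]], p, t_obs, settings)
  }
  Fv <- if (settings$policy_value == "both") F else numeric(np)
  list(states = res, F = F, G = G,
       posterior = policy_posterior(Fv, G, settings$gamma))
}
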