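## Test helpers: random small models, an exhaustive-enumeration smoothing
## oracle, and generative-process observation sampling.

kl_div <- function(p, q) sum(ifelse(p > 0, p * (log(p) - log(q)), 0))

## Random chain/grid model: `sizes` gives the levels of each hidden factor,
## `n_out` the outcome levels per modality (one modality per entry).
## det_A/det_B make the likelihood (an injective map when possible) and the
## transitions deterministic.
random_small_model <- function(seed, sizes = 2L, n_out = 2L, TT = 3L,
                               det_A = FALSE, det_B = FALSE,
                               concentration = 1.5) {
  set.seed(seed)
  rdist <- function(k) {
    x <- stats::rgamma(k, concentration)
    x / sum(x)
  }
  nf <- length(sizes)
  factors <- lapply(seq_len(nf), function(n)
    factor_spec(paste0("f", n), paste0("f", n, "_", seq_len(sizes[n]))))
  names(factors) <- paste0("f", seq_len(nf))
  modalities <- lapply(seq_along(n_out), function(g)
    modality_spec(paste0("g", g),
                  c(paste0("g", g, "_", seq_len(n_out[g] - 1L)), "null")))
  names(modalities) <- paste0("g", seq_along(n_out))
  n_joint <- prod(sizes)
  A <- lapply(seq_along(n_out), function(g) {
    lapply(seq_len(TT), function(tau) {
      a <- array(0, dim = c(n_out[g], sizes))
      am <- matrix(a, nrow = n_out[g])
      if (det_A) {
        hit <- rep(sample.int(n_out[g]), length.out = n_joint)
        am[cbind(hit, seq_len(n_joint))] <- 1
      } else {
        for (j in seq_len(n_joint)) am[, j] <- rdist(n_out[g])
      }
      array(am, dim = c(n_out[g], sizes))
    })
  })
  names(A) <- names(modalities)
  B <- lapply(seq_len(nf), function(n) {
    b <- matrix(0, sizes[n], sizes[n])
    for (j in seq_len(sizes[n])) {
      b[, j] <- if (det_B) {
        v <- numeric(sizes[n]); v[sample.int(sizes[n], 1)] <- 1; v
      } else rdist(sizes[n])
    }
    array(b, dim = c(sizes[n], sizes[n], 1L))
  })
  names(B) <- names(factors)
  C <- lapply(n_out, function(k) matrix(0, TT, k))
  names(C) <- names(modalities)
  D <- lapply(seq_len(nf), function(n) {
    if (det_A && det_B) {
      v <- numeric(sizes[n]); v[sample.int(sizes[n], 1)] <- 1; v
    } else rdist(sizes[n])
  })
  names(D) <- names(factors)
  policies <- matrix(1L, 1L, TT - 1L)
  new_gen_model(factors, modalities, A, B, C, D, policies, TT)
}

## Sample a state trajectory and outcomes from the generative process.
sample_process_obs <- function(model, seed) {
  set.seed(seed)
  TT <- model$horizon
  sizes <- vapply(model$factors, function(f) length(f$levels), integer(1))
  nf <- length(sizes)
  x <- matrix(0L, nf, TT)
  for (n in seq_len(nf)) {
    x[n, 1] <- sample.int(sizes[n], 1, prob = model$D[[n]])
    for (tau in 2:TT) {
      x[n, tau] <- sample.int(sizes[n], 1, prob = model$B[[n]][, x[n, tau - 1], 1])
    }
  }
  obs <- lapply(seq_len(TT), function(tau) {
    o <- lapply(seq_along(model$modalities), function(g) {
      a <- model$A[[g]][[tau]]
      no <- dim(a)[1]
      am <- matrix(a, nrow = no)
      joint <- 1L + sum((x[, tau] - 1L) * cumprod(c(1L, sizes))[seq_len(nf)])
      v <- numeric(no)
      v[sample.int(no, 1, prob = am[, joint])] <- 1
      v
    })
    names(o) <- names(model$modalities)
    o
  })
  list(obs = obs, states = x)
}

## Exact smoothing and log evidence by enumeration of all joint-state
## trajectories under one policy.
exact_smoothing <- function(model, policy_index, obs_seq) {
  TT <- model$horizon
  sizes <- vapply(model$factors, function(f) length(f$levels), integer(1))
  nf <- length(sizes)
  per_tau <- as.matrix(do.call(expand.grid, lapply(sizes, seq_len)))
  n_joint <- nrow(per_tau)
  traj <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_joint)), TT)))
  logp <- apply(traj, 1, function(tr) {
    lp <- 0
    for (n in seq_len(nf)) {
      lp <- lp + log(model$D[[n]][per_tau[tr[1], n]])
      for (tau in 2:TT) {
        a <- policy_action(model, policy_index, n, tau - 1L)
        lp <- lp + log(model$B[[n]][per_tau[tr[tau], n],
                                    per_tau[tr[tau - 1], n], a])
      }
    }
    for (tau in seq_along(obs_seq)) {
      for (g in seq_along(model$modalities)) {
        a <- model$A[[g]][[tau]]
        am <- matrix(a, nrow = dim(a)[1])
        joint <- 1L + sum((per_tau[tr[tau], ] - 1L) *
                            cumprod(c(1L, sizes))[seq_len(nf)])
        lp <- lp + log(am[which.max(obs_seq[[tau]][[g]]), joint])
      }
    }
    lp
  })
  mx <- max(logp)
  if (!is.finite(mx)) return(list(marginals = NULL, log_evidence = -Inf))
  w <- exp(logp - mx)
  logev <- log(sum(w)) + mx
  w <- w / sum(w)
  marginals <- lapply(seq_len(nf), function(n) {
    m <- matrix(0, sizes[n], TT)
    for (tau in seq_len(TT)) {
      lev <- per_tau[traj[, tau], n]
      for (i in seq_len(sizes[n])) m[i, tau] <- sum(w[lev == i])
    }
    m
  })
  names(marginals) <- names(model$factors)
  list(marginals = marginals, log_evidence = logev)
}

## Default small-engine settings for oracle comparisons (run to fixed point).
oracle_settings <- function(...) {
  engine_settings(n_iter = 300L, kappa = 0.5, ...)
}
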