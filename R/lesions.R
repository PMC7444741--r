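#' Lesion configuration
#'
#' Named perturbations of the task model, each a convex mixture of the
#' targeted arrays toward uniform so severity is graded:
#' * `lateral` - rule-factor transitions mixed to uniform (loss of the
#'   recurrent connectivity that maintains rule beliefs across the delay).
#' * `medial` - feedback likelihood mixed to uniform at every time step
#'   (disconnection of interoceptive feedback).
#' * `extrinsic-rule-cue` - cue likelihood at step 1 mixed to uniform
#'   (rule and cue rendered conditionally independent).
#' * `flat-preferences` - feedback log-preferences scaled by (1 - severity).
#' * `none` - identity.
#'
#' @param kind One of `"none"`, `"lateral"`, `"medial"`,
#'   `"extrinsic-rule-cue"`, `"flat-preferences"`.
#' @param severity Real in \[0, 1\]; 1 is a complete lesion.
#' @return A `lesion_config` list.
#' @export
lesion_config <- function(kind = c("none", "lateral", "medial",
                                   "extrinsic-rule-cue", "flat-preferences"),
                          severity = 1) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("none", "lateral", "medial", "extrinsic-rule-cue",
                   "flat-preferences")) {
    stop("lesion_config: unknown lesion kind")
  }
  if (!is.numeric(severity) || severity < 0 || severity > 1) {
    stop("lesion_config: severity must lie in [0, 1]")
  }
  structure(list(kind = kind, severity = severity), class = "lesion_config")
}

## Mix the columns of a stochastic array toward uniform over its first
## dimension.
mix_to_uniform <- function(a, severity) {
  k <- dim(a)[1]
  (1 - severity) * a + severity * array(1 / k, dim = dim(a))
}

#' Apply a synthetic lesion to a model
#'
#' Returns a modified deep copy; `kind = "none"` returns the model
#' unchanged. All lesions preserve stochasticity, so lesioned models still
#' pass [validate_model()].
#'
#' @param model A `gen_model`.
#' @param config A [lesion_config()] (or a kind string, severity 1).
#' @return The lesioned `gen_model`.
#' @export
#' @examples
#' m <- build_task_model()
#' lat <- apply_lesion(m, lesion_config("lateral"))
#' lat$B$rule[, , 1]  # every column (0.5, 0.5)
apply_lesion <- function(model, config) {
  if (is.character(config)) config <- lesion_config(config)
  stopifnot(inherits(config, "lesion_config"))
  sev <- config$severity
  switch(config$kind,
    "none" = model,
    "lateral" = {
      model$B$rule <- mix_to_uniform(model$B$rule, sev)
      model
    },
    "medial" = {
      model$A$feedback <- lapply(model$A$feedback, mix_to_uniform,
                                 severity = sev)
      model
    },
    "extrinsic-rule-cue" = {
      model$A$cue[[1]] <- mix_to_uniform(model$A$cue[[1]], sev)
      model
    },
    "flat-preferences" = {
      model$C$feedback <- (1 - sev) * model$C$feedback
      model
    }
  )
}

#' Lesion battery
#'
#' Runs a session for the intact model and for each lesion kind at severity
#' 1, on matched trial seeds, and tabulates behavior and belief metrics:
#' accuracy, mean rule-belief concentration during the delay (max rule
#' belief about the current time at epoch 2), mean belief in the true target
#' at epoch 3, and mean policy-posterior entropy at epoch 3.
#'
#' @param model Intact `gen_model`.
#' @param settings An [engine_settings()] list.
#' @param n_trials Trials per arm (>= 50).
#' @param seed Master seed (shared across arms, so arms see matched
#'   conditions).
#' @param distractor Passed to [run_session()].
#' @param kinds Lesion kinds to include alongside the intact arm.
#' @return Data frame with one row per arm, class `lesion_battery`.
#' @export
lesion_battery <- function(model, settings = engine_settings(), n_trials = 50L,
                           seed = 1L,
                           distractor = c("independent", "incongruent"),
                           kinds = c("lateral", "medial", "extrinsic-rule-cue",
                                     "flat-preferences")) {
  distractor <- match.arg(distractor)
  if (n_trials < 50L) stop("lesion_battery: n_trials must be >= 50")
  arms <- c("none", kinds)
  rows <- lapply(arms, function(kind) {
    m <- apply_lesion(model, lesion_config(kind, severity = 1))
    ses <- run_session(m, settings, n_trials, seed, distractor)
    met <- session_belief_metrics(ses)
    data.frame(arm = if (kind == "none") "intact" else kind,
               accuracy = ses$accuracy,
               delay_rule_concentration = met$delay_rule,
               target_concentration_epoch3 = met$target_epoch3,
               policy_entropy_epoch3 = ses$mean_policy_entropy_epoch3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lesion_battery", class(out))
  out
}

## Mean belief-concentration metrics over the trials of a session.
session_belief_metrics <- function(session) {
  dr <- vapply(session$trials, function(tr) {
    b <- bma_beliefs(tr, 2L)
    max(b$rule[, 2])
  }, numeric(1))
  tg <- vapply(session$trials, function(tr) {
    b <- bma_beliefs(tr, 3L)
    b$target[tr$condition$target, 3]
  }, numeric(1))
  list(delay_rule = mean(dr), target_epoch3 = mean(tg))
}
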