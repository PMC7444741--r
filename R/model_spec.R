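#' Hidden-state factor specification
#'
#' @param name Factor label.
#' @param levels Character vector of at least two unique level labels.
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, levels) {
  if (!is.character(name) || length(name) != 1L) {
    stop("factor_spec: 'name' must be a single string")
  }
  if (length(levels) < 2L) {
    stop(sprintf("factor_spec: factor '%s' needs at least 2 levels", name))
  }
  if (anyDuplicated(levels)) {
    stop(sprintf("factor_spec: factor '%s' has duplicated level labels", name))
  }
  structure(list(name = name, levels = as.character(levels)),
            class = "factor_spec")
}

#' Outcome modality specification
#'
#' Every modality carries a designated "null" (uninformative) outcome level,
#' emitted whenever the modality carries no information at a given trial
#' phase.
#'
#' @param name Modality label.
#' @param levels Character vector of at least two unique outcome labels.
#' @param null_level Which level is the null outcome (must be in `levels`).
#' @return An object of class `modality_spec`.
#' @export
modality_spec <- function(name, levels, null_level = "null") {
  if (!is.character(name) || length(name) != 1L) {
    stop("modality_spec: 'name' must be a single string")
  }
  if (length(levels) < 2L) {
    stop(sprintf("modality_spec: modality '%s' needs at least 2 levels", name))
  }
  if (anyDuplicated(levels)) {
    stop(sprintf("modality_spec: modality '%s' has duplicated levels", name))
  }
  if (sum(levels == null_level) != 1L) {
    stop(sprintf("modality_spec: modality '%s' must have exactly one null level",
                 name))
  }
  structure(list(name = name, levels = as.character(levels),
                 null_level = null_level),
            class = "modality_spec")
}

## Low-level constructor; performs shape bookkeeping only (see
## validate_model() for the full invariant checks).
new_gen_model <- function(factors, modalities, A, B, C, D, policies, horizon) {
  n_actions <- vapply(B, function(b) dim(b)[3], integer(1))
  control <- which(n_actions > 1L)
  if (length(control) > 1L) {
    stop("gen_model: only one factor may have more than one action")
  }
  control_factor <- if (length(control) == 1L) control else which.max(n_actions)
  m <- structure(list(
    factors = factors,
    modalities = modalities,
    A = A, B = B, C = C, D = D,
    policies = policies,
    horizon = as.integer(horizon),
    n_actions = n_actions,
    control_factor = as.integer(control_factor)
  ), class = "gen_model")
  m
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<gen_model>\n")
  cat("  factors:   ",
      paste(sprintf("%s(%d)", names(x$factors),
                    vapply(x$factors, function(f) length(f$levels), 1L)),
            collapse = ", "), "\n")
  cat("  modalities:",
      paste(sprintf("%s(%d)", names(x$modalities),
                    vapply(x$modalities, function(g) length(g$levels), 1L)),
            collapse = ", "), "\n")
  cat("  horizon T =", x$horizon,
      "| policies:", nrow(x$policies), "\n")
  invisible(x)
}

n_levels <- function(model) {
  vapply(model$factors, function(f) length(f$levels), integer(1))
}

n_outcomes <- function(model) {
  vapply(model$modalities, function(g) length(g$levels), integer(1))
}

## Action index for factor n at policy step tau (1..T-1).
policy_action <- function(model, policy_index, n, tau) {
  if (n == model$control_factor && model$n_actions[n] > 1L) {
    model$policies[policy_index, tau]
  } else 1L
}

#' Enumerate the policy space
#'
#' @param mode `"terminal-choice"` (default task behavior: hold the choice
#'   through the delay and respond once, after the stimuli) or `"full-tree"`
#'   (all action sequences, allowing premature responses).
#' @param horizon Trial horizon T; policies have length T - 1.
#' @param n_actions Number of actions on the controllable factor (3 for the
#'   task: stay, pick-blue, pick-green).
#' @return Integer matrix, one policy per row, one action column per step.
#' @export
build_policy_set <- function(mode = c("terminal-choice", "full-tree"),
                             horizon = 4L, n_actions = 3L) {
  if (!is.character(mode) ||
      !mode[1] %in% c("terminal-choice", "full-tree")) {
    stop("build_policy_set: unknown policy-depth mode")
  }
  mode <- match.arg(mode)
  steps <- horizon - 1L
  if (steps < 1L) stop("build_policy_set: horizon must be at least 2")
  if (mode == "terminal-choice") {
    pol <- t(vapply(seq_len(n_actions),
                    function(a) c(rep(1L, steps - 1L), a),
                    integer(steps)))
  } else {
    grid <- do.call(expand.grid, rep(list(seq_len(n_actions)), steps))
    pol <- as.matrix(grid[, rev(seq_len(steps)), drop = FALSE])
  }
  dimnames(pol) <- NULL
  storage.mode(pol) <- "integer"
  pol
}

#' Build the delayed cross-modal attention task model
#'
#' Constructs the four-step generative model of the rule-cued attention task.
#' Hidden states: rule (attend-vision / attend-audition), target
#' (blue / green), choice (no-choice / blue / green). Outcome modalities:
#' cue, vision, audition, feedback, each with a null level. The likelihood
#' changes across the four trial phases: the cue identifies the rule at step
#' 1; every modality is null during the delay (step 2); at step 3 the
#' rule-attended modality is an identity image of the target while the
#' unattended modality is uniform over its two stimulus levels; at step 4
#' feedback is "correct" exactly when the choice state matches the target
#' (failing to choose counts as incorrect). Transitions are identities except
#' for the action-dependent choice factor; preferences are zero everywhere
#' except feedback at the final step (+c correct, -c incorrect).
#'
#' @param preference Positive preference magnitude c in nats (default 3).
#' @param policy_mode Passed to [build_policy_set()].
#' @return A validated `gen_model`.
#' @export
#' @examples
#' m <- build_task_model()
#' m$A$cue[[1]][, 1, 1, 1]  # cue distribution when rule = attend-vision
build_task_model <- function(preference = 3,
                             policy_mode = c("terminal-choice", "full-tree")) {
  policy_mode <- match.arg(policy_mode)
  if (!is.numeric(preference) || length(preference) != 1L ||
      !is.finite(preference) || preference <= 0) {
    stop("build_task_model: 'preference' must be a positive number")
  }
  TT <- 4L
  factors <- list(
    rule   = factor_spec("rule", c("attend-vision", "attend-audition")),
    target = factor_spec("target", c("blue", "green")),
    choice = factor_spec("choice", c("no-choice", "blue", "green"))
  )
  ## cue levels ordered so the identity map sends attend-vision -> blue-noise
  ## and attend-audition -> brown-noise
  modalities <- list(
    cue      = modality_spec("cue", c("blue-noise", "brown-noise", "null")),
    vision   = modality_spec("vision", c("blue", "green", "null")),
    audition = modality_spec("audition", c("blue", "green", "null")),
    feedback = modality_spec("feedback", c("correct", "incorrect", "null"))
  )
  ns <- c(2L, 2L, 3L)
  null_idx <- 3L

  null_A <- function() {
    a <- array(0, dim = c(3L, ns))
    a[null_idx, , , ] <- 1
    a
  }
  A <- list(cue = vector("list", TT), vision = vector("list", TT),
            audition = vector("list", TT), feedback = vector("list", TT))

  ## step 1: cue is the identity image of the rule; all else null
  a <- array(0, dim = c(3L, ns))
  for (r in 1:2) a[r, r, , ] <- 1
  A$cue[[1]] <- a
  A$vision[[1]] <- null_A(); A$audition[[1]] <- null_A()
  A$feedback[[1]] <- null_A()

  ## step 2 (delay): no modality carries information
  for (g in names(A)) A[[g]][[2]] <- null_A()

  ## step 3: attended modality = identity image of target, unattended uniform
  vis <- array(0, dim = c(3L, ns)); aud <- array(0, dim = c(3L, ns))
  for (tg in 1:2) {
    vis[tg, 1, tg, ] <- 1          # attend-vision: vision reveals target
    vis[1:2, 2, tg, ] <- 0.5       # attend-audition: vision uninformative
    aud[tg, 2, tg, ] <- 1          # attend-audition: audition reveals target
    aud[1:2, 1, tg, ] <- 0.5       # attend-vision: audition uninformative
  }
  A$vision[[3]] <- vis; A$audition[[3]] <- aud
  A$cue[[3]] <- null_A(); A$feedback[[3]] <- null_A()

  ## step 4: feedback depends on choice-target match; no-choice is incorrect
  fb <- array(0, dim = c(3L, ns))
  for (tg in 1:2) for (ch in 1:3) {
    fb[if (ch == tg + 1L) 1L else 2L, , tg, ch] <- 1
  }
  A$feedback[[4]] <- fb
  A$cue[[4]] <- null_A(); A$vision[[4]] <- null_A(); A$audition[[4]] <- null_A()

  ## transitions: identities except the choice factor
  B <- list(
    rule   = array(diag(2), dim = c(2L, 2L, 1L)),
    target = array(diag(2), dim = c(2L, 2L, 1L)),
    choice = array(0, dim = c(3L, 3L, 3L))
  )
  B$choice[, , 1] <- diag(3)                 # stay
  for (u in 2:3) {
    B$choice[u, 1, u] <- 1                   # no-choice -> picked level
    B$choice[2, 2, u] <- 1                   # picked levels absorb
    B$choice[3, 3, u] <- 1
  }

  C <- lapply(modalities, function(g) matrix(0, nrow = TT,
                                             ncol = length(g$levels)))
  C$feedback[TT, ] <- c(preference, -preference, 0)

  D <- list(rule = c(0.5, 0.5), target = c(0.5, 0.5), choice = c(1, 0, 0))

  policies <- build_policy_set(policy_mode, horizon = TT, n_actions = 3L)
  new_gen_model(factors, modalities, A, B, C, D, policies, TT)
}

#' Validate a generative model
#'
#' Report-only check of every structural invariant: stochasticity of
#' likelihood columns and transition columns (tolerance 1e-9), entries in
#' \[0, 1\], a single controllable factor, finite preferences that are
#' uniform everywhere except feedback at the final step, normalized
#' non-negative priors, and a well-formed policy set.
#'
#' @param model A `gen_model`.
#' @return A data frame of failures (zero rows when valid) with class
#'   `validation_report`.
#' @export
validate_model <- function(model) {
  fail <- list()
  add <- function(check, location, detail) {
    fail[[length(fail) + 1L]] <<- data.frame(check = check,
                                             location = location,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  tol <- 1e-9
  ns <- n_levels(model)
  nf <- length(ns)
  TT <- model$horizon

  for (f in model$factors) {
    if (length(f$levels) < 2L)
      add("factor_levels", f$name, "fewer than 2 levels")
    if (anyDuplicated(f$levels))
      add("factor_levels", f$name, "duplicate level labels")
  }
  for (g in model$modalities) {
    if (length(g$levels) < 2L)
      add("modality_levels", g$name, "fewer than 2 levels")
    if (sum(g$levels == g$null_level) != 1L)
      add("modality_null", g$name, "must have exactly one null level")
  }

  joint <- as.matrix(do.call(expand.grid, lapply(ns, seq_len)))
  for (g in names(model$A)) {
    for (tau in seq_len(TT)) {
      a <- model$A[[g]][[tau]]
      if (any(a < -tol | a > 1 + tol)) {
        add("A_range", sprintf("A[%s][tau=%d]", g, tau),
            "entries outside [0,1]")
      }
      for (r in seq_len(nrow(joint))) {
        idx <- joint[r, ]
        col <- a[cbind(seq_len(dim(a)[1]),
                       matrix(idx, nrow = dim(a)[1], ncol = nf, byrow = TRUE))]
        s <- sum(col)
        if (abs(s - 1) > tol) {
          add("A_column_stochastic",
              sprintf("A[%s][tau=%d], joint state (%s)", g, tau,
                      paste(idx, collapse = ",")),
              sprintf("column sums to %.12g", s))
        }
      }
    }
  }

  n_act_gt1 <- 0L
  for (n in names(model$B)) {
    b <- model$B[[n]]
    if (dim(b)[1] != dim(b)[2])
      add("B_square", sprintf("B[%s]", n), "transition matrix not square")
    if (dim(b)[3] > 1L) n_act_gt1 <- n_act_gt1 + 1L
    for (u in seq_len(dim(b)[3])) {
      cs <- colSums(b[, , u, drop = FALSE][, , 1])
      bad <- which(abs(cs - 1) > tol)
      for (j in bad) {
        add("B_column_stochastic",
            sprintf("B[%s][action=%d], column %d", n, u, j),
            sprintf("column sums to %.12g", cs[j]))
      }
    }
  }
  if (n_act_gt1 > 1L)
    add("B_actions", "B", "more than one factor has multiple actions")

  for (g in names(model$C)) {
    cm <- model$C[[g]]
    if (!all(is.finite(cm)))
      add("C_finite", sprintf("C[%s]", g), "non-finite preference entries")
    if (nrow(cm) != TT)
      add("C_horizon", sprintf("C[%s]", g),
          sprintf("%d rows but horizon is %d", nrow(cm), TT))
    for (tau in seq_len(nrow(cm))) {
      uniform_required <- !(g == "feedback" && tau == TT)
      if (uniform_required && diff(range(cm[tau, ])) > tol) {
        add("C_uniform", sprintf("C[%s][tau=%d]", g, tau),
            "non-uniform preferences outside the final feedback step")
      }
    }
  }

  for (n in names(model$D)) {
    d <- model$D[[n]]
    if (any(d < -tol))
      add("D_nonnegative", sprintf("D[%s]", n), "negative prior mass")
    if (abs(sum(d) - 1) > tol)
      add("D_normalized", sprintf("D[%s]", n),
          sprintf("prior sums to %.12g", sum(d)))
  }

  pol <- model$policies
  if (is.null(pol) || nrow(pol) == 0L) {
    add("policies_nonempty", "policies", "empty policy set")
  } else {
    if (ncol(pol) != TT - 1L)
      add("policies_length", "policies",
          sprintf("policies have %d steps but horizon is %d", ncol(pol), TT))
    nu <- model$n_actions[model$control_factor]
    if (any(pol < 1L | pol > nu))
      add("policies_actions", "policies", "action index out of range")
  }

  report <- if (length(fail)) do.call(rbind, fail) else
    data.frame(check = character(), location = character(),
               detail = character(), stringsAsFactors = FALSE)
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Model valid: all invariant checks passed.\n")
  } else {
    cat(sprintf("Model INVALID: %d failed check(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname validate_model
#' @export
is_valid_model <- function(model) {
  nrow(validate_model(model)) == 0L
}

## ---- serialization -------------------------------------------------------

array_to_list <- function(a) list(dim = dim(a), values = as.numeric(a))
list_to_array <- function(l) array(as.numeric(l$values),
                                   dim = as.integer(l$dim))

#' Serialize / restore a generative model as JSON
#'
#' The JSON document stores factor and modality specs together with all
#' A/B/C/D arrays (dimensions plus column-major values) and the policy set;
#' the round trip is lossless to full double precision.
#'
#' @param model A `gen_model`.
#' @param path File path; for `model_to_json` with `path = NULL` the JSON
#'   string is returned instead of written.
#' @return `model_to_json`: the path (invisibly) or a JSON string;
#'   `model_from_json`: the restored `gen_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    factors = lapply(model$factors, function(f) f[c("name", "levels")]),
    modalities = lapply(model$modalities,
                        function(g) g[c("name", "levels", "null_level")]),
    A = lapply(model$A, function(per_tau) lapply(per_tau, array_to_list)),
    B = lapply(model$B, array_to_list),
    C = lapply(model$C, array_to_list),
    D = model$D,
    policies = array_to_list(model$policies),
    horizon = model$horizon
  )
  txt <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  factors <- lapply(doc$factors, function(f)
    factor_spec(f$name, unlist(f$levels)))
  modalities <- lapply(doc$modalities, function(g)
    modality_spec(g$name, unlist(g$levels), g$null_level))
  A <- lapply(doc$A, function(per_tau) lapply(per_tau, list_to_array))
  B <- lapply(doc$B, list_to_array)
  C <- lapply(doc$C, function(l) {
    m <- list_to_array(l)
    matrix(m, nrow = dim(m)[1])
  })
  D <- lapply(doc$D, unlist)
  pol <- list_to_array(doc$policies)
  pol <- matrix(as.integer(pol), nrow = dim(pol)[1])
  new_gen_model(factors, modalities, A, B, C, D, pol, doc$horizon)
}
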