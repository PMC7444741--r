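#' Run configuration
#'
#' Single structured configuration covering all modules. Every quantity has
#' the package default; configuration files (JSON, or YAML when the yaml
#' package is installed) override fields by name, and a master seed spawns
#' the sub-streams used for conditions, distractors and CVA noise.
#'
#' @param ... Named overrides of the default fields (`preference`,
#'   `policy_mode`, `engine` sub-list, `lesion` sub-list, `n_trials`,
#'   `distractor`, `cva` sub-list, `seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    preference = 3,
    policy_mode = "terminal-choice",
    engine = list(n_iter = 16L, kappa = 0.25, lambda = exp(-16), gamma = 1,
                  weighting = "full-sum", policy_value = "both"),
    lesion = list(kind = "none", severity = 1),
    n_trials = 64L,
    distractor = "independent",
    cva = list(k = 10L, snr = 8, alpha = 0.05, n_seeds = 100L),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a JSON (or YAML) configuration document.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("load_run_config: the 'yaml' package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(run_config, doc)
}

config_model <- function(config) {
  m <- build_task_model(preference = config$preference,
                        policy_mode = config$policy_mode)
  apply_lesion(m, lesion_config(config$lesion$kind, config$lesion$severity))
}

config_settings <- function(config) {
  do.call(engine_settings, config$engine)
}

#' Reproduce a figure-style artifact bundle
#'
#' * `fig5`: one intact trial with full traces; raster, rate and LFP tables
#'   for the rule, target and choice populations.
#' * `fig7`: the same trial condition and seed run under the intact, lateral
#'   and medial models (brown-noise cue, i.e. attend-audition, blue target).
#' * `fig6`: the CVA predictive-validity summary for one intact trial.
#'
#' All bundles are plain data structures backed by exportable tables;
#' `out_dir`, when given, receives delimited-text exports.
#'
#' @param name `"fig5"`, `"fig6"` or `"fig7"`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV exports.
#' @return A named list bundle (contents depend on `name`).
#' @export
reproduce_figure <- function(name, config = run_config(), out_dir = NULL) {
  if (!name %in% c("fig5", "fig6", "fig7")) {
    stop("reproduce_figure: unknown figure name (use fig5, fig6 or fig7)")
  }
  settings <- config_settings(config)
  cond <- trial_condition("attend-audition", "blue",
                          seed = derive_seed(config$seed, 5L))
  bundle <- switch(name,
    fig5 = {
      model <- config_model(config)
      trial <- run_trial(model, settings, cond,
                         distractor = config$distractor, trace = TRUE)
      traces <- firing_rates(trial)
      list(name = name, condition = cond, trial = trial, traces = traces,
           lfp = local_field_potentials(traces),
           rasters = lapply(stats::setNames(nm = unique(traces$factor)),
                            function(fn) raster(rate_matrix(traces, fn))))
    },
    fig7 = {
      base <- build_task_model(preference = config$preference,
                               policy_mode = config$policy_mode)
      arms <- lapply(stats::setNames(nm = c("intact", "lateral", "medial")),
                     function(arm) {
        m <- if (arm == "intact") base else
          apply_lesion(base, lesion_config(arm, 1))
        trial <- run_trial(m, settings, cond,
                           distractor = config$distractor, trace = TRUE)
        list(trial = trial, traces = firing_rates(trial))
      })
      list(name = name, condition = cond, seed = cond$seed, arms = arms)
    },
    fig6 = {
      model <- config_model(config)
      trial <- run_trial(model, settings, cond,
                         distractor = config$distractor, trace = TRUE)
      design <- build_design(trial)
      study <- cva_variate_study(design, k = config$cva$k,
                                 snr = config$cva$snr,
                                 alpha = config$cva$alpha,
                                 n_seeds = config$cva$n_seeds,
                                 seed = config$seed)
      example <- cva(design,
                     synthesize_data(design, k = config$cva$k,
                                     snr = config$cva$snr,
                                     seed = derive_seed(config$seed, 101L)),
                     alpha = config$cva$alpha)
      list(name = name, condition = cond, design = design,
           example = example, study = study)
    })
  if (!is.null(out_dir)) export_bundle(bundle, out_dir)
  bundle
}

export_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) utils::write.csv(df, file.path(out_dir, file),
                                            row.names = FALSE)
  if (bundle$name == "fig5") {
    wr(bundle$traces, "fig5_unit_traces.csv")
    wr(bundle$lfp, "fig5_lfp.csv")
  } else if (bundle$name == "fig7") {
    for (arm in names(bundle$arms)) {
      wr(bundle$arms[[arm]]$traces, sprintf("fig7_%s_unit_traces.csv", arm))
    }
  } else if (bundle$name == "fig6") {
    wr(as.data.frame(bundle$design), "fig6_design.csv")
    wr(data.frame(variate = seq_along(bundle$example$correlations),
                  correlation = bundle$example$correlations,
                  p_value = bundle$example$p_values),
       "fig6_cva_example.csv")
    wr(data.frame(count = as.integer(names(bundle$study$table)),
                  seeds = as.integer(bundle$study$table)),
       "fig6_variate_counts.csv")
  }
  invisible(out_dir)
}

#' Aggregate session summaries into a report
#'
#' @param summaries A list of `session_summary` objects (at least one).
#' @return List with a per-session data frame (`table`) and formatted text
#'   lines (`text`), class `summary_report`.
#' @export
summary_report <- function(summaries) {
  if (inherits(summaries, "session_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("summary_report: no session summaries")
  ok <- vapply(summaries, inherits, logical(1), "session_summary")
  if (!all(ok)) stop("summary_report: inputs must be session summaries")
  tab <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(session = i, n_trials = s$n_trials, seed = s$seed,
               distractor = s$distractor, accuracy = s$accuracy,
               accuracy_congruent = s$accuracy_congruent,
               accuracy_incongruent = s$accuracy_incongruent,
               policy_entropy_epoch3 = s$mean_policy_entropy_epoch3,
               stringsAsFactors = FALSE)
  }))
  txt <- c(sprintf("Sessions: %d", nrow(tab)),
           sprintf("Session %d: n=%d accuracy=%.3f entropy(epoch3)=%.3f",
                   tab$session, tab$n_trials, tab$accuracy,
                   tab$policy_entropy_epoch3))
  structure(list(table = tab, text = txt), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
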