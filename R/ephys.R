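#' Simulated firing rates from a trial's belief trajectories
#'
#' One "unit" per (factor, level, represented time): its firing rate at an
#' iteration bin is the Bayesian-model-average expectation
#' `sum_pi posterior(pi) * s[pi][factor][level, tau]`, with the policy
#' posterior evaluated at the same iteration. Bins concatenate across the
#' four observation epochs (`4 * n_iter` bins per trial); the matching
#' model-averaged depolarization `v` is carried alongside.
#'
#' @param trial A `trial_record` produced with `trace = TRUE`.
#' @return Long data frame (class `unit_traces`) with columns `factor`,
#'   `level`, `rep_tau`, `epoch`, `iteration`, `bin`, `rate`, `depol`.
#' @export
firing_rates <- function(trial) {
  if (is.null(trial$trace)) {
    stop("firing_rates: trial was run without trace = TRUE")
  }
  TT <- length(trial$trace)
  ni <- trial$n_iter
  np <- ncol(trial$policy_posterior)
  fac_names <- names(trial$states[[1]]$s)
  rows <- list()
  for (e in seq_len(TT)) {
    tre <- trial$trace[[e]]
    for (i in seq_len(ni)) {
      post <- tre$post_iter[i, ]
      bin <- (e - 1L) * ni + i
      for (n in seq_along(fac_names)) {
        sbar <- tre$per_policy[[1]][[i]]$s[[n]] * post[1]
        vbar <- tre$per_policy[[1]][[i]]$v[[n]] * post[1]
        for (p in seq_len(np)[-1]) {
          sbar <- sbar + tre$per_policy[[p]][[i]]$s[[n]] * post[p]
          vbar <- vbar + tre$per_policy[[p]][[i]]$v[[n]] * post[p]
        }
        nl <- nrow(sbar)
        rows[[length(rows) + 1L]] <- data.frame(
          factor = fac_names[n],
          level = rep(seq_len(nl), times = TT),
          rep_tau = rep(seq_len(TT), each = nl),
          epoch = e, iteration = i, bin = bin,
          rate = as.vector(sbar), depol = as.vector(vbar),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_iter") <- ni
  attr(out, "epochs") <- TT
  class(out) <- c("unit_traces", class(out))
  out
}

#' Unit-by-bin rate matrix
#'
#' Pivots [firing_rates()] output into a matrix with one row per unit
#' (ordered by represented time, then level) and one column per bin.
#'
#' @param traces A `unit_traces` data frame.
#' @param factor Factor name to extract (default: all factors stacked).
#' @param value `"rate"` or `"depol"`.
#' @return Numeric matrix with informative rownames (`factor:level@t<tau>`).
#' @export
rate_matrix <- function(traces, factor = NULL, value = c("rate", "depol")) {
  value <- match.arg(value)
  df <- if (is.null(factor)) traces else traces[traces$factor == factor, ]
  df$unit <- sprintf("%s:%d@t%d", df$factor, df$level, df$rep_tau)
  units <- unique(df$unit[order(df$factor, df$rep_tau, df$level)])
  bins <- sort(unique(df$bin))
  m <- matrix(NA_real_, nrow = length(units), ncol = length(bins),
              dimnames = list(units, bins))
  m[cbind(match(df$unit, units), match(df$bin, bins))] <- df[[value]]
  m
}

#' Simulated local field potentials
#'
#' For each hidden-state factor, the LFP trace is the first difference of
#' the model-averaged depolarization summed over that factor's units,
#' optionally smoothed with a centered moving average. The trace is zero
#' wherever beliefs are static across consecutive bins.
#'
#' @param trial A `trial_record` with traces (or a `unit_traces` frame).
#' @param window Centered moving-average window in bins (default 1 = off).
#' @return Data frame with columns `factor`, `bin`, `lfp`.
#' @export
local_field_potentials <- function(trial, window = 1L) {
  if (window < 1L) stop("local_field_potentials: window must be >= 1")
  traces <- if (inherits(trial, "unit_traces")) trial else firing_rates(trial)
  out <- lapply(unique(traces$factor), function(fn) {
    vm <- rate_matrix(traces, factor = fn, value = "depol")
    series <- colSums(vm)
    lfp <- c(0, diff(series))
    if (window > 1L) {
      kern <- rep(1 / window, window)
      sm <- stats::filter(lfp, kern, sides = 2)
      lfp <- ifelse(is.na(sm), lfp, as.numeric(sm))
    }
    data.frame(factor = fn, bin = as.integer(colnames(vm)), lfp = lfp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Raster rendering of unit traces
#'
#' `density` mode returns the rate matrix itself (grayscale density, the
#' Fig-style rendering); `point-process` mode draws independent binary
#' events per bin with probability `rate * scale`.
#'
#' @param rates A rate matrix (from [rate_matrix()]) or `unit_traces` frame.
#' @param mode `"density"` or `"point-process"`.
#' @param scale Event probability per unit rate in point-process mode.
#' @param seed Optional seed for the point-process draw.
#' @return Numeric matrix of densities or 0/1 events, class `raster_matrix`.
#' @export
raster <- function(rates, mode = c("density", "point-process"), scale = 1,
                   seed = NULL) {
  mode <- match.arg(mode)
  m <- if (inherits(rates, "unit_traces")) rate_matrix(rates) else rates
  if (any(m < -1e-9 | m > 1 + 1e-9)) {
    stop("raster: rates must lie in [0, 1]")
  }
  m <- pmin(pmax(m, 0), 1)
  out <- if (mode == "density") m else with_local_seed(seed, {
    ev <- matrix(stats::rbinom(length(m), 1L, pmin(1, as.vector(m) * scale)),
                 nrow = nrow(m), dimnames = dimnames(m))
    ev
  })
  class(out) <- c("raster_matrix", class(out))
  out
}

#' Export a trial's iteration-resolved beliefs as a long table
#'
#' One row per (epoch, iteration, policy, factor, level, represented time)
#' with the expectation `s` and depolarization `v`; suitable for writing as
#' delimited text.
#'
#' @param trial A `trial_record` with traces.
#' @return Long data frame.
#' @export
belief_trace_df <- function(trial) {
  if (is.null(trial$trace)) stop("belief_trace_df: trial lacks traces")
  TT <- length(trial$trace)
  ni <- trial$n_iter
  np <- ncol(trial$policy_posterior)
  fac_names <- names(trial$states[[1]]$s)
  rows <- list()
  for (e in seq_len(TT)) for (i in seq_len(ni)) for (p in seq_len(np)) {
    st <- trial$trace[[e]]$per_policy[[p]][[i]]
    for (n in seq_along(fac_names)) {
      sm <- st$s[[n]]; vm <- st$v[[n]]
      nl <- nrow(sm)
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = e, iteration = i, policy = p, factor = fac_names[n],
        level = rep(seq_len(nl), times = TT),
        rep_tau = rep(seq_len(TT), each = nl),
        s = as.vector(sm), v = as.vector(vm), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Three-row electrophysiology plot for one population
#'
#' Base-graphics rendering in the style of the simulated-electrophysiology
#' figures: raster (density image), per-unit rate traces, and the LFP.
#'
#' @param trial A `trial_record` with traces.
#' @param factor Factor name (`"rule"`, `"target"` or `"choice"`).
#' @return Invisibly, the rate matrix.
#' @export
plot_trial_ephys <- function(trial, factor = "rule") {
  traces <- firing_rates(trial)
  m <- rate_matrix(traces, factor = factor)
  lfp <- local_field_potentials(traces)
  lfp <- lfp[lfp$factor == factor, ]
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "", ylab = "unit", main = paste(factor, "raster"))
  graphics::matplot(t(m), type = "l", lty = 1, ylab = "rate", xlab = "",
                    main = "firing rates")
  graphics::plot(lfp$bin, lfp$lfp, type = "l", xlab = "bin", ylab = "LFP",
                 main = "simulated LFP")
  invisible(m)
}
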