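#' Design matrix of population time-courses
#'
#' Builds the three-column design used for the predictive-validity analysis:
#' for each hidden-state factor the Bayesian-model-average belief in that
#' factor's eventually-inferred level (the argmax of the final-bin belief)
#' at every iteration bin. Rule and target columns average this belief
#' across the factor's represented-time units, all of which carry the
#' inference; for the choice population the default signal is the belief of
#' the units representing the present, because choice units for times before
#' the decision represent the "no choice" state and carry no decision
#' signal - their average merely rescales the decision-time unit and leaves
#' the column collinear with the target time-course.
#'
#' @param trial A `trial_record` run with `trace = TRUE`.
#' @param aggregate `"iteration"` (one row per iteration bin, the default)
#'   or `"epoch"` (one row per observation epoch).
#' @param choice_signal `"present"` (default) reads the choice population at
#'   the currently represented time; `"represented-average"` averages across
#'   represented times like the other factors.
#' @return Numeric matrix with columns `rule`, `target`, `choice`; attribute
#'   `inferred_levels` records the level picked for each factor.
#' @export
build_design <- function(trial, aggregate = c("iteration", "epoch"),
                         choice_signal = c("present", "represented-average")) {
  aggregate <- match.arg(aggregate)
  choice_signal <- match.arg(choice_signal)
  traces <- firing_rates(trial)
  fac_names <- unique(traces$factor)
  TT <- attr(traces, "epochs")
  last_bin <- max(traces$bin)
  inferred <- vapply(fac_names, function(fn) {
    df <- traces[traces$factor == fn & traces$bin == last_bin &
                   traces$rep_tau == TT, ]
    df$level[which.max(df$rate)]
  }, integer(1))
  cols <- lapply(seq_along(fac_names), function(k) {
    fn <- fac_names[k]
    df <- traces[traces$factor == fn & traces$level == inferred[k], ]
    if (fn == "choice" && choice_signal == "present") {
      df <- df[df$rep_tau == df$epoch, ]
      df$rate[order(df$bin)]
    } else {
      as.vector(tapply(df$rate, df$bin, mean))
    }
  })
  X <- do.call(cbind, cols)
  colnames(X) <- fac_names
  rownames(X) <- NULL
  if (aggregate == "epoch") {
    ni <- attr(traces, "n_iter")
    ep <- rep(seq_len(TT), each = ni)
    X <- apply(X, 2, function(col) tapply(col, ep, mean))
  }
  if (any(apply(X, 2, function(c) all(c == 0)))) {
    stop("build_design: design contains a constant-zero column")
  }
  if (aggregate == "iteration" && nrow(X) < ncol(X) + 2L) {
    stop("build_design: too few rows for the number of regressors")
  }
  attr(X, "inferred_levels") <- inferred
  X
}

#' Synthesize multivariate neural data from a design
#'
#' Each simulated neuron is a distinct random linear mixture of the design
#' columns plus Gaussian noise: `data = design %*% M + E` with standard
#' normal mixing weights and noise standard deviation set to the
#' root-mean-square of the column-centered mixtures divided by `snr`. The
#' signal is the variation of the mixtures about their means - the component
#' the canonical-variates analysis actually sees, since it centers both
#' matrices - so `snr` is a root-mean-square signal-to-noise ratio on that
#' analyzed signal.
#'
#' @param design Design matrix (rows = time bins).
#' @param k Number of simulated neurons (columns), at least `ncol(design)`.
#' @param snr Positive signal-to-noise ratio (default 8).
#' @param seed Optional seed; the draw is reproducible given the seed.
#' @return List with `data`, `mixing`, `noise_sd`, `snr`, `seed`, class
#'   `synthetic_neural_data`.
#' @export
synthesize_data <- function(design, k = 10L, snr = 8, seed = NULL) {
  p <- ncol(design)
  if (k < p) stop("synthesize_data: k must be at least ncol(design)")
  if (!is.numeric(snr) || snr <= 0) stop("synthesize_data: snr must be > 0")
  out <- with_local_seed(seed, {
    M <- matrix(stats::rnorm(p * k), nrow = p, ncol = k)
    S <- design %*% M
    Sc <- scale(S, center = TRUE, scale = FALSE)
    noise_sd <- sqrt(mean(Sc^2)) / snr
    E <- matrix(stats::rnorm(nrow(S) * k, sd = noise_sd), nrow = nrow(S))
    list(data = S + E, mixing = M, noise_sd = noise_sd)
  })
  structure(c(out, list(snr = snr, seed = seed)),
            class = "synthetic_neural_data")
}

#' Canonical variates analysis with sequential significance tests
#'
#' Centers both matrices, computes canonical correlations and vectors via
#' the singular-value decomposition of the whitened cross-covariance (QR
#' orthonormalization of each side), and tests successive variates with
#' Bartlett's chi-square approximation to Wilks' lambda. The significant
#' count is the number of leading variates rejected sequentially at level
#' `alpha`. A permutation test (row shuffling of the data side) is available
#' as an assumption-free alternative.
#'
#' @param design Matrix of explanatory time-courses (rows = bins).
#' @param data Matrix of responses with the same rows.
#' @param alpha Significance level (default 0.05).
#' @param method `"bartlett"` (default) or `"permutation"`.
#' @param n_perm Permutations when `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return A `cva_result`: `correlations` (descending), `xcoef`, `ycoef`,
#'   `p_values`, `n_significant`, `alpha`.
#' @export
cva <- function(design, data, alpha = 0.05,
                method = c("bartlett", "permutation"), n_perm = 999L,
                seed = NULL) {
  method <- match.arg(method)
  if (inherits(data, "synthetic_neural_data")) data <- data$data
  X <- scale(as.matrix(design), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(data), center = TRUE, scale = FALSE)
  n <- nrow(X)
  if (nrow(Y) != n) stop("cva: design and data must have matching rows")
  p <- ncol(X); q <- ncol(Y)
  if (n <= max(p, q)) stop("cva: need more rows than columns after centering")
  m <- min(p, q)
  cc <- canonical_correlations(X, Y)
  r <- cc$r
  pvals <- switch(method,
    bartlett = bartlett_pvalues(r, n, p, q),
    permutation = permutation_pvalues(X, Y, r, n_perm, seed))
  nsig <- 0L
  for (k in seq_len(m)) {
    if (pvals[k] < alpha) nsig <- nsig + 1L else break
  }
  structure(list(correlations = r, xcoef = cc$xcoef, ycoef = cc$ycoef,
                 p_values = pvals, n_significant = nsig, alpha = alpha,
                 method = method, n = n),
            class = "cva_result")
}

## Canonical correlations and vectors via QR orthonormalization of both
## (already centered) sides and an SVD of the cross-product of the Q bases.
canonical_correlations <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X); q <- ncol(Y)
  qx <- qr(X); qy <- qr(Y)
  if (qx$rank < p) stop("cva: design matrix is rank deficient")
  if (qy$rank < q) stop("cva: data matrix is rank deficient")
  m <- min(p, q)
  Qy <- qr.qy(qy, diag(n)[, seq_len(q), drop = FALSE])
  sv <- svd(qr.qty(qx, Qy)[seq_len(p), , drop = FALSE])
  r <- pmin(pmax(sv$d[seq_len(m)], 0), 1)
  xcoef <- backsolve(qr.R(qx), sv$u[, seq_len(m), drop = FALSE])
  ycoef <- backsolve(qr.R(qy), sv$v[, seq_len(m), drop = FALSE])
  list(r = r, xcoef = xcoef, ycoef = ycoef)
}

## Bartlett's chi-square approximation to Wilks' lambda for variates k..m.
bartlett_pvalues <- function(r, n, p, q) {
  m <- length(r)
  r2 <- pmin(r^2, 1 - 1e-12)
  vapply(seq_len(m), function(k) {
    stat <- -(n - 1 - (p + q + 1) / 2) * sum(log(1 - r2[k:m]))
    df <- (p - k + 1) * (q - k + 1)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }, numeric(1))
}

permutation_pvalues <- function(X, Y, r, n_perm, seed) {
  m <- length(r)
  obs <- wilks_stats(r)
  with_local_seed(seed, {
    exceed <- numeric(m)
    for (b in seq_len(n_perm)) {
      Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
      rp <- canonical_correlations(X, Yp)$r
      sp <- wilks_stats(rp)
      exceed <- exceed + (sp[seq_len(m)] <= obs)
    }
    (exceed + 1) / (n_perm + 1)
  })
}

## Wilks' lambda for the sequential tests (smaller = stronger association).
wilks_stats <- function(r) {
  r2 <- pmin(r^2, 1 - 1e-12)
  rev(cumprod(rev(1 - r2)))
}

#' @export
print.cva_result <- function(x, ...) {
  cat("<cva_result>\n  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n")
  cat("  p-values:",
      paste(sprintf("%.3g", x$p_values), collapse = ", "), "\n")
  cat(sprintf("  significant variates at alpha=%.3g: %d (%s)\n",
              x$alpha, x$n_significant, x$method))
  invisible(x)
}

#' Distribution of significant-variate counts over random mixings
#'
#' Repeats [synthesize_data()] + [cva()] over `n_seeds` derived seeds and
#' tabulates the number of significant canonical variates.
#'
#' @param design Design matrix from [build_design()].
#' @param k,snr,alpha As in [synthesize_data()] / [cva()].
#' @param n_seeds Number of replicate syntheses.
#' @param seed Master seed.
#' @return List with `counts` (per-seed), `table`, and `modal` (the modal
#'   significant-variate count).
#' @export
cva_variate_study <- function(design, k = 10L, snr = 8, alpha = 0.05,
                              n_seeds = 100L, seed = 1L) {
  counts <- vapply(seq_len(n_seeds), function(i) {
    syn <- synthesize_data(design, k = k, snr = snr,
                           seed = derive_seed(seed, 100L + i))
    cva(design, syn$data, alpha = alpha)$n_significant
  }, integer(1))
  tab <- table(counts)
  list(counts = counts, table = tab,
       modal = as.integer(names(tab)[which.max(tab)]))
}
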