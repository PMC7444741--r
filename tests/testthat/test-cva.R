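traced_trial_for_cva <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_trial(build_task_model(), engine_settings(),
                          trial_condition("attend-audition", "blue",
                                          seed = 42L),
                          trace = TRUE)
    }
    cache
  }
})

test_that("the design matrix has three distinguishable population columns", {
  tr <- traced_trial_for_cva()
  X <- build_design(tr)
  expect_equal(dim(X), c(64L, 3L))
  expect_equal(colnames(X), c("rule", "target", "choice"))
  cors <- stats::cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.99)
  expect_true(all(apply(X, 2, stats::sd) > 0))
  ## epoch aggregation collapses to one row per observation epoch
  Xe <- build_design(tr, aggregate = "epoch")
  expect_equal(nrow(Xe), 4L)
  ## the represented-average choice variant is available
  Xa <- build_design(tr, choice_signal = "represented-average")
  expect_equal(dim(Xa), dim(X))
  expect_false(isTRUE(all.equal(Xa[, "choice"], X[, "choice"])))
})

test_that("synthetic neural data respects the mixing and noise contract", {
  X <- build_design(traced_trial_for_cva())
  ## noise-free limit reconstructs the mixtures
  hi <- synthesize_data(X, k = 10L, snr = 1e9, seed = 1L)
  expect_lt(max(abs(hi$data - X %*% hi$mixing)) /
              max(abs(X %*% hi$mixing)), 1e-6)
  ## empirical signal-to-noise near the nominal value
  syn <- synthesize_data(X, k = 10L, snr = 8, seed = 2L)
  S <- X %*% syn$mixing
  E <- syn$data - S
  emp <- sqrt(mean(scale(S, scale = FALSE)^2)) / sqrt(mean(E^2))
  expect_equal(emp, 8, tolerance = 0.05 * 8)
  ## reproducibility and input validation
  expect_identical(synthesize_data(X, seed = 3L), synthesize_data(X, seed = 3L))
  expect_error(synthesize_data(X, k = 2L), "k must be")
  expect_error(synthesize_data(X, snr = -1), "snr")
})

test_that("canonical correlations agree with independent formulations", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40)
  Y <- X %*% matrix(rnorm(3 * 5), 3) + 0.5 * matrix(rnorm(40 * 5), 40)
  res <- cva(X, Y)
  ## oracle 1: stats::cancor
  cc <- stats::cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_equal(res$correlations, cc$cor, tolerance = 1e-10)
  ## oracle 2: generalized-eigenvalue formulation on the covariances
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  ev <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy))$values
  expect_equal(res$correlations^2, sort(Re(ev), decreasing = TRUE)[1:3],
               tolerance = 1e-8)
  ## self-correlation: a full-rank design predicts itself perfectly
  self <- cva(X, X + 0)
  expect_true(all(self$correlations > 1 - 1e-10))
  expect_error(cva(X, cbind(Y, Y[, 1])), "rank deficient")
})

test_that("canonical correlations are invariant to affine recoding", {
  set.seed(11)
  X <- matrix(rnorm(50 * 3), 50)
  Y <- X %*% matrix(rnorm(3 * 6), 3) + matrix(rnorm(50 * 6), 50)
  base <- cva(X, Y)$correlations
  Tx <- matrix(rnorm(9), 3); while (abs(det(Tx)) < 0.1) Tx <- matrix(rnorm(9), 3)
  Ty <- matrix(rnorm(36), 6); while (abs(det(Ty)) < 0.1) Ty <- matrix(rnorm(36), 6)
  rec <- cva(sweep(X %*% Tx, 2, c(1, -2, 3), "+"),
             sweep(Y %*% Ty, 2, rnorm(6), "+"))$correlations
  expect_equal(base, rec, tolerance = 1e-8)
})

test_that("sequential tests are calibrated and respond to signal strength", {
  tr <- traced_trial_for_cva()
  X <- build_design(tr)
  ## pure-noise data: rarely any significant variate
  false_pos <- vapply(1:200, function(i) {
    Y <- with_local_seed(1000L + i,
                         matrix(stats::rnorm(nrow(X) * 10), ncol = 10))
    cva(X, Y)$n_significant >= 1L
  }, logical(1))
  expect_lte(mean(false_pos), 0.10)
  ## modal significant count does not decrease along an SNR ladder
  modals <- vapply(c(0.5, 2, 8, 32), function(snr) {
    cva_variate_study(X, snr = snr, n_seeds = 40L, seed = 1L)$modal
  }, integer(1))
  expect_true(all(diff(modals) >= 0))
  ## permutation alternative broadly agrees at strong signal
  syn <- synthesize_data(X, seed = 6L)
  bart <- cva(X, syn)
  perm <- cva(X, syn, method = "permutation", n_perm = 199L, seed = 7L)
  expect_equal(perm$n_significant, bart$n_significant)
})
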