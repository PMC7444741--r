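test_that("task model has the documented structure", {
  m <- build_task_model()
  expect_s3_class(m, "gen_model")
  expect_equal(unname(vapply(m$factors, function(f) length(f$levels), 1L)),
               c(2L, 2L, 3L))
  expect_length(m$modalities, 4L)
  expect_equal(m$horizon, 4L)
  ## delay step: every modality emits null with probability 1
  for (g in names(m$A)) {
    a <- m$A[[g]][[2]]
    expect_true(all(a[3, , , ] == 1))
    expect_true(all(a[1:2, , , ] == 0))
  }
  ## identity transitions for rule and target
  expect_equal(m$B$rule[, , 1], diag(2))
  expect_equal(m$B$target[, , 1], diag(2))
  ## choice actions move no-choice to the picked level; picked levels absorb
  expect_equal(m$B$choice[, 1, 2], c(0, 1, 0))
  expect_equal(m$B$choice[, 1, 3], c(0, 0, 1))
  expect_equal(m$B$choice[, 2, 3], c(0, 1, 0))
  ## preferences only at the final feedback step
  expect_equal(m$C$feedback[4, ], c(3, -3, 0))
  expect_true(all(m$C$feedback[1:3, ] == 0))
  expect_equal(m$D$choice, c(1, 0, 0))
})

test_that("feedback likelihood implements the matching rule including no-choice", {
  m <- build_task_model()
  fb <- m$A$feedback[[4]]
  for (r in 1:2) for (tg in 1:2) for (ch in 1:3) {
    expected <- if (ch == tg + 1L) 1L else 2L
    expect_equal(which.max(fb[, r, tg, ch]), expected)
  }
})

test_that("attended modality carries ln 2 of target information, unattended none", {
  m <- build_task_model()
  mi <- function(a, rule) {
    ## conditional mutual information between target and outcome, uniform
    ## target prior, any choice level (likelihood ignores choice)
    p_joint <- sapply(1:2, function(tg) 0.5 * a[, rule, tg, 1])
    p_o <- rowSums(p_joint)
    h_o <- -sum(ifelse(p_o > 0, p_o * log(p_o), 0))
    h_o_given <- -sum(ifelse(p_joint > 0, p_joint * log(p_joint / 0.5), 0))
    h_o - h_o_given
  }
  expect_equal(mi(m$A$vision[[3]], 1), log(2), tolerance = 1e-12)
  expect_equal(mi(m$A$audition[[3]], 2), log(2), tolerance = 1e-12)
  expect_equal(mi(m$A$vision[[3]], 2), 0, tolerance = 1e-12)
  expect_equal(mi(m$A$audition[[3]], 1), 0, tolerance = 1e-12)
})

test_that("model construction is deterministic and validates parameters", {
  expect_identical(build_task_model(), build_task_model())
  expect_error(build_task_model(preference = -1), "preference")
  expect_error(build_task_model(preference = 0), "preference")
  expect_error(build_policy_set("nonsense"), "mode")
  expect_error(factor_spec("f", "one-level"), "at least 2")
  expect_error(modality_spec("g", c("a", "b")), "null")
})

test_that("policy sets enumerate as documented", {
  tc <- build_policy_set("terminal-choice", horizon = 4L)
  expect_equal(dim(tc), c(3L, 3L))
  expect_true(all(tc[, 1:2] == 1L))
  expect_equal(tc[, 3], 1:3)
  ft <- build_policy_set("full-tree", horizon = 4L)
  expect_equal(nrow(ft), 27L)
  expect_equal(nrow(unique(ft)), 27L)
})

test_that("validator passes the task model and locates forced violations", {
  m <- build_task_model()
  rep0 <- validate_model(m)
  expect_equal(nrow(rep0), 0L)
  expect_true(is_valid_model(m))
  ## scale one likelihood column: the report names modality, time and state
  m2 <- m
  m2$A$vision[[3]][, 2, 1, 3] <- 0.5 * m2$A$vision[[3]][, 2, 1, 3]
  rep2 <- validate_model(m2)
  expect_gt(nrow(rep2), 0L)
  expect_true(any(grepl("A\\[vision\\]\\[tau=3\\]", rep2$location) &
                    grepl("2,1,3", rep2$location)))
  ## every lesion preserves validity at full severity
  for (kind in c("lateral", "medial", "extrinsic-rule-cue",
                 "flat-preferences")) {
    expect_true(is_valid_model(apply_lesion(m, lesion_config(kind, 1))),
                label = kind)
  }
})

test_that("likelihood and transition columns are stochastic within 1e-9", {
  m <- build_task_model()
  for (g in names(m$A)) for (tau in 1:4) {
    a <- m$A[[g]][[tau]]
    sums <- apply(a, 2:4, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  for (n in names(m$B)) {
    for (u in seq_len(dim(m$B[[n]])[3])) {
      expect_true(all(abs(colSums(m$B[[n]][, , u]) - 1) < 1e-9))
    }
  }
})

test_that("JSON serialization round-trips losslessly", {
  m <- build_task_model(preference = 2.5)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2$A, m$A)
  expect_equal(m2$B, m$B)
  expect_equal(m2$C, m$C)
  expect_equal(m2$D, m$D)
  expect_equal(m2$policies, m$policies)
  expect_equal(m2$horizon, m$horizon)
  expect_equal(lapply(m2$factors, `[[`, "levels"),
               lapply(m$factors, `[[`, "levels"))
})
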