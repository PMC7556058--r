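test_that("the Hebbian update reproduces direct substitution", {
  expect_equal(nhl_update(0.5, 0.6, 0.7, eta = 0.045, gamma = 0.98),
               0.5008, tolerance = 1e-12)
  expect_equal(nhl_update(-0.5, 0.6, 0.7, eta = 0.045, gamma = 0.98),
               -0.4792, tolerance = 1e-12)
  # identity limit
  expect_identical(nhl_update(0.31, 0.9, 0.1, eta = 0, gamma = 1), 0.31)
  # clipping contract (checked outside the admissible training ranges,
  # where the raw recurrence would overshoot)
  expect_identical(nhl_update(0.9, 1, 1, eta = 2, gamma = 1), 1)
  expect_identical(nhl_update(-0.9, 1, -0.5, eta = 3, gamma = 1), -1)
  expect_error(nhl_update(0, 0.5, 0.5, eta = 0.045, gamma = 0.98), "nonzero")
})

test_that("termination functions match their definitions", {
  expect_identical(target_midpoint(0, 1), 0.5)
  expect_equal(target_midpoint(0.66, 1), 0.83, tolerance = 1e-12)
  expect_identical(target_midpoint(0.5, 0.5), 0.5)
  expect_error(target_midpoint(0.7, 0.3), "exceed")

  expect_identical(f1_criterion(c(0.5, 0.8), c(0.5, 0.8)), 0)
  expect_equal(f1_criterion(0.6, 0.5), 0.01, tolerance = 1e-15)
  expect_equal(f1_criterion(c(0.6, 0.9), c(0.5, 0.7)), 0.05,
               tolerance = 1e-15)
  expect_error(f1_criterion(c(1, 2), 1), "length")

  expect_true(f2_criterion(c(0.5, 0.5), c(0.5, 0.5), e = 0.002))
  expect_false(f2_criterion(0.502, 0.5, e = 0.002))  # strict inequality
  expect_true(f2_criterion(0.5019, 0.5, e = 0.002))
  expect_error(f2_criterion(1, c(1, 2)), "length")
  expect_error(f2_criterion(0.5, 0.5, e = 0), "> 0")
})

test_that("control bounds mirror the admissible learning-parameter ranges", {
  expect_error(nhl_control(eta = 0), "\\(0, 0.1\\)")
  expect_error(nhl_control(eta = 0.1), "\\(0, 0.1\\)")
  expect_error(nhl_control(gamma = 0.9), "\\(0.9, 1\\)")
  expect_error(nhl_control(gamma = 1), "\\(0.9, 1\\)")
  ctl <- nhl_control(eta = 0.045, gamma = 0.98)
  expect_s3_class(ctl, "nhl_control")
})

test_that("two interleaved iterations on a toy map match a hand-stepped oracle", {
  b <- toy_bundle(w = 0.5, clamp_inputs = TRUE)
  rec <- data.frame(F1 = "present", risk_label = "medium",
                    stringsAsFactors = FALSE)
  ctl <- nhl_control(eta = 0.045, gamma = 0.98, e = 1e-9,
                     max_epochs = 1, record_cap = 2, seed = 1)
  fit <- fcm_nhl(b, rec, control = ctl)

  # oracle: state (A, OUT) starts at (1, 0); input clamped
  eta <- 0.045; gam <- 0.98
  w <- 0.5
  A <- c(1, 0)
  for (k in 1:2) {
    A_prev <- A
    A <- c(A_prev[1], 1 / (1 + exp(-(A_prev[2] + w * A_prev[1]))))
    w <- gam * w + eta * A_prev[2] * (A_prev[1] - sign(w) * w * A_prev[2])
  }
  expect_equal(coef(fit)["F1", "OUT"], w, tolerance = 1e-12)
  expect_identical(fit$epochs, 1L)
  expect_identical(fit$terminated_by, "max_epochs")
  # epoch F1 is the squared gap between the final output and the class target
  expect_equal(fit$f1, (A[2] - 0.5)^2, tolerance = 1e-12)
})

test_that("training is a no-op in the eta -> 0, gamma -> 1 limit", {
  b <- toy_bundle(w = 0.5)
  set.seed(3)
  rec <- data.frame(F1 = sample(c("absent", "present"), 20, replace = TRUE),
                    risk_label = sample(c("low", "medium", "high"), 20,
                                        replace = TRUE),
                    stringsAsFactors = FALSE)
  ctl <- nhl_control(eta = 1e-9, gamma = 1 - 1e-9, max_epochs = 5, seed = 1)
  fit <- fcm_nhl(b, rec, control = ctl)
  expect_equal(coef(fit), b$model$weights, tolerance = 1e-5)
})

test_that("zero pattern, sign pattern and bounds survive a 50-epoch run", {
  bundle <- gc_bundle()
  cohort <- label_cohort(sample_cohort(25, seed = 11), bundle)
  # a small per-record cap with a tight tolerance keeps every epoch active
  ctl <- nhl_control(eta = 0.045, gamma = 0.98, e = 1e-12, max_epochs = 50,
                     record_cap = 3, f1_patience = 100L, seed = 2)
  fit <- fcm_nhl(bundle, cohort, control = ctl)
  expect_identical(fit$epochs, 50L)
  W0 <- fit$initial_weights
  W1 <- coef(fit)
  expect_identical(W1 == 0, W0 == 0)
  expect_identical(sign(W1), sign(W0))
  expect_true(all(abs(W1) <= 1))
  expect_length(fit$f1, 50L)
})

test_that("the fit object supports the standard modelling verbs", {
  bundle <- gc_bundle()
  cohort <- label_cohort(sample_cohort(40, seed = 12), bundle)
  fit <- fcm_nhl(bundle, cohort, control = nhl_control(seed = 1))
  expect_s3_class(fit, "fcm_nhl")
  expect_output(print(fit), "Nonlinear Hebbian")
  s <- summary(fit)
  expect_s3_class(s, "summary.fcm_nhl")
  expect_true(s$sign_preserved)
  expect_identical(s$n_edges, 38L)

  pred <- predict(fit, cohort)
  expect_identical(nrow(pred), 40L)
  expect_s3_class(pred$risk, "factor")
  expect_length(fitted(fit), 40L)
  r <- residuals(fit)
  expect_length(r, 40L)
  expect_true(all(abs(r) <= 1))

  sim <- simulate(fit, nsim = 2, n = 15, seed = 5)
  expect_length(sim, 2L)
  expect_identical(nrow(sim[[1]]), 15L)
  expect_true("risk_label" %in% names(sim[[1]]))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training rejects malformed datasets", {
  b <- toy_bundle()
  expect_error(fcm_nhl(b, data.frame()), "empty")
  expect_error(
    fcm_nhl(b, data.frame(F1 = "present", stringsAsFactors = FALSE)),
    "risk_label")
  expect_error(
    fcm_nhl(b, data.frame(F1 = "present", risk_label = "extreme",
                          stringsAsFactors = FALSE)),
    "unknown class")
})

test_that("a 1x1 grid reduces to one train-and-evaluate row", {
  bundle <- gc_bundle()
  cohort <- label_cohort(sample_cohort(60, seed = 9), bundle)
  sp <- split_cohort(cohort, 0.7, seed = 9)
  res <- fcm_nhl_grid(bundle, sp$train, sp$test,
                      etas = 0.045, gammas = 0.98,
                      control = nhl_control(seed = 1))
  expect_identical(nrow(res), 1L)
  expect_identical(res$eta, 0.045)
  expect_identical(res$gamma, 0.98)
  expect_true(res$accuracy >= 0 && res$accuracy <= 100)
  cms <- attr(res, "confusion")
  expect_identical(sum(cms[[1]]), nrow(sp$test))
  expect_error(fcm_nhl_grid(bundle, sp$train, sp$test,
                            etas = numeric(0), gammas = 0.98),
               "non-empty")
  expect_error(fcm_nhl_grid(bundle, sp$train, sp$test,
                            etas = 0.5, gammas = 0.98),
               "\\(0, 0.1\\)")
})
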