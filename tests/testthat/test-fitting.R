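test_that("protocol estimation recovers rate and hold level from the data", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.01, 0.01, 8 * p$tau_R)
  est <- estimate_protocol(simulate_relaxation(p, proto))
  expect_s3_class(est, "relaxation_protocol")
  expect_equal(est$rate, 0.01, tolerance = 1e-6)
  expect_equal(est$hold_level, 0.01, tolerance = 1e-6)

  cproto <- creep_protocol(100, 100, 8 * p$tau_C)
  cest <- estimate_protocol(simulate_creep(p, cproto))
  expect_s3_class(cest, "creep_protocol")
  expect_equal(cest$rate, 100, tolerance = 1e-6)
  expect_equal(cest$hold_level, 100, tolerance = 1e-6)

  hold_only <- simulate_relaxation(p, proto)
  hold_only <- hold_only[hold_only$phase == "hold", ]
  expect_error(estimate_protocol(hold_only), "protocol")
  no_phase <- tibble::tibble(time_s = 1:5, stress_Pa = 5:1, strain = 0.01)
  expect_error(estimate_protocol(no_phase), "phase")
})

test_that("finite-rate fits recover the generating parameters from noiseless data", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.01, 0.01, 8 * p$tau_R)
  fit <- fit_relaxation(simulate_relaxation(p, proto), proto)
  expect_true(fit$converged)
  expect_false(fit$condition_warning)
  expect_lt(relative_error(fit$E1, p$E1), 0.005)
  expect_lt(relative_error(fit$E2, p$E2), 0.005)
  expect_lt(relative_error(fit$eta, p$eta), 0.005)
  expect_true(fit$k >= 0.99 && fit$k <= 1)
  expect_gt(fit$tau_C, fit$tau_R)

  cproto <- creep_protocol(1000, 100, 8 * p$tau_C)
  cfit <- fit_creep(simulate_creep(p, cproto), cproto)
  expect_lt(relative_error(cfit$E1, p$E1), 0.005)
  expect_lt(relative_error(cfit$E2, p$E2), 0.005)
  expect_lt(relative_error(cfit$eta, p$eta), 0.005)

  # the same fits work with the protocol estimated from the curve
  fit2 <- fit_relaxation(simulate_relaxation(p, proto))
  expect_lt(relative_error(fit2$E2, p$E2), 0.005)
})

test_that("fixing k = 1 reduces the finite form to three parameters", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.1, 0.01, 8 * p$tau_R)
  fit <- fit_relaxation(simulate_relaxation(p, proto), proto, fit_k = FALSE)
  expect_identical(fit$k, 1)
  expect_lt(relative_error(fit$eta, p$eta), 0.005)
})

test_that("step-loading fits are accurate only when the ramp is fast", {
  slow_mat <- sls_parameters(5000, 20000, 10000)   # tau_R = 0.5 s
  fast_ok <- sls_parameters(5000, 20000, 100000)   # tau_R = 5 s

  # fast ramp relative to tau_R: step form fine
  proto_fast <- relaxation_protocol(100, 0.01, 8 * fast_ok$tau_R)
  fit <- fit_relaxation(simulate_relaxation(fast_ok, proto_fast), proto_fast,
                        form = "infinite")
  expect_lt(relative_error(fit$E2, fast_ok$E2), 0.05)

  # slow ramp: the Maxwell arm relaxes during loading, E2 badly biased
  proto_slow <- relaxation_protocol(1e-4, 0.01, 8 * slow_mat$tau_R)
  fit_slow <- fit_relaxation(simulate_relaxation(slow_mat, proto_slow),
                             proto_slow, form = "infinite")
  expect_gt(relative_error(fit_slow$E2, slow_mat$E2), 0.5)
  # ... but the equilibrium modulus E1 is recovered regardless
  expect_lt(relative_error(fit_slow$E1, slow_mat$E1), 0.05)

  # creep mirror
  cfast <- creep_protocol(1e6, 100, 8 * fast_ok$tau_C)
  cfit <- fit_creep(simulate_creep(fast_ok, cfast), cfast, form = "infinite")
  expect_lt(relative_error(cfit$E2, fast_ok$E2), 0.05)
  cslow <- creep_protocol(1, 100, 8 * slow_mat$tau_C)
  cfit_slow <- fit_creep(simulate_creep(slow_mat, cslow), cslow,
                         form = "infinite")
  expect_gt(relative_error(cfit_slow$E2, slow_mat$E2), 0.5)
  expect_lt(relative_error(cfit_slow$E1, slow_mat$E1), 0.05)
})

test_that("a vanishing creep transient sets the conditioning flag", {
  p <- soft_gel()
  # at 0.01 Pa/s the decay amplitude is ~2e-4 of the equilibrium strain
  proto <- creep_protocol(0.01, 100, 8 * p$tau_C)
  fit <- fit_creep(simulate_creep(p, proto), proto)
  expect_true(fit$condition_warning)

  # at a moderate rate the transient is strong and no flag is raised
  proto2 <- creep_protocol(1000, 100, 8 * p$tau_C)
  fit2 <- fit_creep(simulate_creep(p, proto2), proto2)
  expect_false(fit2$condition_warning)
})

test_that("fits demand enough hold samples for their free parameters", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.01, 0.01, 8 * p$tau_R)
  tiny <- simulate_relaxation(p, proto, sampling = sampling_plan(200, 3))
  expect_error(fit_relaxation(tiny, proto), "at least 4")
  # three samples do satisfy the three-parameter step form
  expect_s3_class(fit_relaxation(tiny, proto, form = "infinite"), "sls_fit")
})

test_that("the relative-error metric matches its definition", {
  expect_equal(relative_error(21, 20), 0.05)
  expect_equal(relative_error(20, 20), 0)
  expect_equal(relative_error(0.5, 1), 0.5)
  expect_equal(relative_error(c(21, 19), c(20, 20)), c(0.05, 0.05))
  expect_error(relative_error(1, 0), "non-zero")
})

test_that("tidy and glance summarize a fit against ground truth", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.1, 0.01, 8 * p$tau_R)
  fit <- fit_relaxation(simulate_relaxation(p, proto), proto)

  td <- tidy(fit)
  expect_setequal(td$term, c("E1", "E2", "eta", "tau_R", "tau_C", "k"))
  expect_equal(td$true[td$term == "eta"], 10000)
  expect_lt(max(td$rel_error_pct[td$term != "k"]), 0.5)

  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_identical(gl$form, "finite")
})
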