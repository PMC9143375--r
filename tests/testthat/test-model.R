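test_that("loading-ramp stress follows the finite-rate closed form", {
  p <- soft_gel()
  expect_equal(ramp_stress(0, p, rate = 0.01), 0)
  # independent arithmetic: E1*r*t + E1*r*(tauC - tauR)*(1 - exp(-t/tauR))
  expect_equal(
    ramp_stress(1, p, rate = 0.01),
    50 + 100 * (1 - exp(-2)),
    tolerance = 1e-12
  )
  # initial slope is r * instantaneous modulus (E1 + E2)
  h <- 1e-8
  expect_equal(ramp_stress(h, p, 0.01) / h, 0.01 * 25000, tolerance = 1e-4)
  expect_error(ramp_stress(2, p, 0.01, ramp_duration = 1), "ramp window")
  expect_error(ramp_stress(-0.1, p, 0.01), "ramp window")
})

test_that("loading-ramp strain follows the finite-rate closed form", {
  p <- soft_gel()
  expect_equal(ramp_strain(0, p, rate = 100), 0)
  h <- 1e-9
  expect_equal(ramp_strain(h, p, 100) / h, 100 / 25000, tolerance = 1e-4)
  # strain lags the quasi-static line r*t/E1 since tau_R < tau_C
  t <- c(0.1, 1, 5)
  expect_true(all(ramp_strain(t, p, 100) < 100 * t / p$E1))
  expect_error(ramp_strain(3, p, 100, ramp_duration = 1), "ramp window")
})

test_that("ramp-end responses hit their fast- and slow-loading limits", {
  p <- soft_gel()
  eps0 <- 0.01
  fast <- relaxation_protocol(1e9, eps0, 1)
  slow <- relaxation_protocol(1e-9, eps0, 1)
  expect_equal(ramp_end_stress(p, fast), (p$E1 + p$E2) * eps0, tolerance = 1e-6)
  expect_equal(ramp_end_stress(p, slow), p$E1 * eps0, tolerance = 1e-6)

  sigma0 <- 100
  cfast <- creep_protocol(1e12, sigma0, 1)
  cslow <- creep_protocol(1e-9, sigma0, 1)
  expect_equal(ramp_end_strain(p, cfast), sigma0 / (p$E1 + p$E2), tolerance = 1e-6)
  expect_equal(ramp_end_strain(p, cslow), sigma0 / p$E1, tolerance = 1e-6)

  # the ramp-end expression is the loading solution evaluated at t'
  proto <- relaxation_protocol(0.01, eps0, 1)
  expect_equal(
    ramp_end_stress(p, proto),
    ramp_stress(proto$ramp_duration, p, proto$rate),
    tolerance = 1e-15
  )
  cproto <- creep_protocol(100, sigma0, 1)
  expect_equal(
    ramp_end_strain(p, cproto),
    ramp_strain(cproto$ramp_duration, p, cproto$rate),
    tolerance = 1e-15
  )
})

test_that("hold-phase forms are continuous with the ramp and reach equilibrium", {
  for (p in random_materials()) {
    proto <- relaxation_protocol(0.05, 0.02, 8 * p$tau_R)
    expect_equal(
      relaxation_stress(0, p, proto, k = 1),
      ramp_end_stress(p, proto),
      tolerance = 1e-15
    )
    for (k in c(0.4, 0.7, 1)) {
      expect_equal(
        relaxation_stress(1e9 * p$tau_R, p, proto, k = k),
        p$E1 * proto$hold_level,
        tolerance = 1e-9
      )
    }
    cproto <- creep_protocol(50, 80, 8 * p$tau_C)
    expect_equal(
      creep_strain(0, p, cproto, k = 1),
      ramp_end_strain(p, cproto),
      tolerance = 1e-15
    )
    for (k in c(0.4, 0.7, 1)) {
      expect_equal(
        creep_strain(1e9 * p$tau_C, p, cproto, k = k),
        cproto$hold_level / p$E1,
        tolerance = 1e-9
      )
    }
  }
})

test_that("step-loading forms match their textbook values", {
  p <- soft_gel()
  eps0 <- 0.01
  expect_equal(relaxation_stress_step(0, p, eps0), 250)
  expect_equal(relaxation_stress_step(1e9, p, eps0), p$E1 * eps0)
  expect_equal(
    relaxation_stress_step(p$tau_R, p, eps0),
    (p$E1 + p$E2 / exp(1)) * eps0
  )

  sigma0 <- 100
  expect_equal(creep_strain_step(0, p, sigma0), 0.004)
  expect_equal(creep_strain_step(1e9, p, sigma0), 0.02)
  expect_equal(
    creep_strain_step(p$tau_C, p, sigma0),
    (sigma0 / p$E1) * (1 - 0.8 / exp(1))
  )
})

test_that("finite-rate forms converge to the step forms as the rate grows", {
  t <- seq(0, 20, length.out = 400)
  for (p in random_materials(6)) {
    proto <- relaxation_protocol(1e9, 0.01, 20)
    dev <- abs(
      relaxation_stress(t, p, proto, k = 1) -
        relaxation_stress_step(t, p, 0.01)
    )
    expect_lt(max(dev) / ((p$E1 + p$E2) * 0.01), 1e-6)
    # amplitude limit: E2 * eps0
    expect_equal(
      ramp_end_stress(p, proto) - p$E1 * 0.01, p$E2 * 0.01,
      tolerance = 1e-6
    )

    cproto <- creep_protocol(1e12, 100, 20)
    cdev <- abs(
      creep_strain(t, p, cproto, k = 1) - creep_strain_step(t, p, 100)
    )
    expect_lt(max(cdev) / (100 / p$E1), 1e-6)
    # amplitude limit: -sigma0 E2 / (E1 (E1 + E2))
    expect_equal(
      ramp_end_strain(p, cproto) - 100 / p$E1,
      -100 * p$E2 / (p$E1 * (p$E1 + p$E2)),
      tolerance = 1e-6
    )
  }
})

test_that("hold responses are monotone and ramp responses strictly increasing", {
  for (p in random_materials(6)) {
    proto <- relaxation_protocol(0.02, 0.01, 8 * p$tau_R)
    tr <- seq(0, proto$ramp_duration, length.out = 200)
    expect_true(all(diff(ramp_stress(tr, p, proto$rate)) > 0))
    th <- seq(0, proto$hold_duration, length.out = 300)
    for (k in c(0.5, 1)) {
      expect_true(all(diff(relaxation_stress(th, p, proto, k)) <= 0))
    }

    cproto <- creep_protocol(200, 100, 8 * p$tau_C)
    tc <- seq(0, cproto$ramp_duration, length.out = 200)
    expect_true(all(diff(ramp_strain(tc, p, cproto$rate)) > 0))
    for (k in c(0.5, 1)) {
      expect_true(all(diff(creep_strain(th, p, cproto, k)) >= 0))
    }

    # amplitude signs: relaxation decays from above, creep rises from below
    expect_gt(relaxation_stress(0, p, proto), p$E1 * proto$hold_level)
    expect_lt(creep_strain(0, p, cproto), cproto$hold_level / p$E1)
  }
})

test_that("stretch exponent is validated", {
  p <- soft_gel()
  proto <- relaxation_protocol(0.01, 0.01, 4)
  expect_error(relaxation_stress(1, p, proto, k = 0), "k")
  expect_error(relaxation_stress(1, p, proto, k = 1.5), "k")
  expect_error(creep_strain(1, p, creep_protocol(100, 100, 20), k = -1), "k")
})
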