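#' Estimate the test protocol from a measured curve
#'
#' Recovers the loading rate and hold level of a ramp-hold test from the
#' data themselves: the rate is the least-squares slope of the controlled
#' channel (strain for a relaxation test, stress for a creep test) over the
#' loading phase, and the hold level is the mean of that channel over the
#' hold phase. The hold duration is the hold-phase time span.
#'
#' @param curve An `sls_curve` (or any tibble with columns `time_s`,
#'   `stress_Pa`, `strain` and a `phase` column labelling `"loading"` and
#'   `"hold"` samples). At least two samples are required in each phase.
#' @param test `"relaxation"` or `"creep"`; taken from the curve's `test`
#'   attribute (or inferred from which channel is constant during the hold)
#'   when omitted.
#'
#' @return A [relaxation_protocol()] or [creep_protocol()].
#' @export
estimate_protocol <- function(curve, test = NULL) {
  if (!"phase" %in% names(curve) || !any(curve$phase == "loading") ||
      !any(curve$phase == "hold")) {
    abort(paste(
      "The curve carries no usable `phase` labels;",
      "supply the test protocol explicitly."
    ))
  }
  loading <- curve[curve$phase == "loading", ]
  hold <- curve[curve$phase == "hold", ]
  if (nrow(loading) < 2L || nrow(hold) < 2L) {
    abort("Need at least two loading samples and two hold samples to estimate the protocol.")
  }
  test <- test %||% attr(curve, "test") %||% infer_test_kind(curve)
  test <- match.arg(test, c("relaxation", "creep"))
  channel <- if (test == "relaxation") "strain" else "stress_Pa"
  rate <- unname(coef(lm(loading[[channel]] ~ 0 + loading$time_s))[1])
  level <- mean(hold[[channel]])
  duration <- diff(range(hold$time_s))
  if (test == "relaxation") {
    relaxation_protocol(rate, level, duration)
  } else {
    creep_protocol(rate, level, duration)
  }
}

#' Fit standard-linear-solid parameters to a ramp-hold test curve
#'
#' Curvefits the *hold phase* of a measured or simulated ramp-hold test with
#' a standard-linear-solid constitutive solution and recovers the material
#' triple (`E1`, `E2`, `eta`). Two equation forms are available:
#'
#' * `form = "finite"` — the finite-loading-rate solution
#'   ([relaxation_stress()] / [creep_strain()]), with free parameters `E1`,
#'   `tau_R`, `tau_C` and (optionally) the stretch exponent `k`, while the
#'   loading rate and hold level are fixed at their protocol values. `E2` and
#'   `eta` then follow from [moduli_from_time_constants()]. This form models
#'   the partial relaxation that occurs already during a ramp of finite rate,
#'   and remains accurate however slow the ramp.
#' * `form = "infinite"` — the traditional step-loading solution
#'   ([relaxation_stress_step()] / [creep_strain_step()]), free parameters
#'   `E1`, `E2`, `tau_R` (relaxation) or `E1`, `E2`, `tau_C` (creep), with
#'   `eta` recovered from the time constant. Accurate only when the ramp is
#'   fast compared to the material's relaxation time.
#'
#' Fitting is bounded Levenberg-Marquardt ([minpack.lm::nls.lm()]) on the
#' hold-phase residuals, with data-driven initialization (equilibrium level
#' from the late hold, decay amplitude from the first hold sample, time
#' constant from the 1/e crossing) and up to three deterministic perturbed
#' restarts if the optimizer does not converge. Positivity of moduli and
#' time constants is enforced by fitting on the log scale, and
#' `tau_C > tau_R` by the parameterization `tau_C = tau_R * (1 + delta)`,
#' `delta > 0`.
#'
#' When the fitted decay amplitude falls below 1e-3 of the equilibrium
#' response the transient carries almost no information about the Maxwell
#' arm; the result is then flagged with `condition_warning` (this is how
#' slow-ramp creep tests lose identifiability of `E2`).
#'
#' @param curve An `sls_curve` or compatible tibble (columns `time_s`,
#'   `stress_Pa`, `strain`, `phase`).
#' @param proto The test protocol; estimated from the curve via
#'   [estimate_protocol()] when `NULL`.
#' @param form `"finite"` or `"infinite"`.
#' @param fit_k Whether the stretch exponent `k` is a free parameter of the
#'   finite form (default) or held at 1 (ordinary exponential). Ignored for
#'   the infinite form.
#'
#' @return An object of class `sls_fit` with fields `test`, `form`, `E1`,
#'   `E2`, `eta`, `tau_R`, `tau_C`, `k`, `residual_rms`, `converged`,
#'   `condition_warning`, `n_obs`, `protocol` and, when the curve carries
#'   ground truth, `truth`. See [tidy.sls_fit()] and [glance.sls_fit()].
#'
#' @examples
#' p <- sls_parameters(5000, 20000, 10000)
#' proto <- relaxation_protocol(0.01, 0.01, hold_duration = 4)
#' fit <- fit_relaxation(simulate_relaxation(p, proto), proto)
#' tidy(fit)
#' @export
fit_relaxation <- function(curve, proto = NULL, form = c("finite", "infinite"),
                           fit_k = TRUE) {
  form <- match.arg(form)
  proto <- proto %||% estimate_protocol(curve, "relaxation")
  stopifnot(inherits(proto, "relaxation_protocol"))
  hold <- hold_phase(curve, proto, "stress_Pa")
  fit_hold_curve("relaxation", form, hold, proto, fit_k,
                 truth = attr(curve, "truth"))
}

#' @rdname fit_relaxation
#' @export
fit_creep <- function(curve, proto = NULL, form = c("finite", "infinite"),
                      fit_k = TRUE) {
  form <- match.arg(form)
  proto <- proto %||% estimate_protocol(curve, "creep")
  stopifnot(inherits(proto, "creep_protocol"))
  hold <- hold_phase(curve, proto, "strain")
  fit_hold_curve("creep", form, hold, proto, fit_k,
                 truth = attr(curve, "truth"))
}

hold_phase <- function(curve, proto, channel) {
  if (!"phase" %in% names(curve)) {
    abort("The curve needs a `phase` column labelling loading and hold samples.")
  }
  hold <- curve[curve$phase == "hold", ]
  list(t = hold$time_s - min(hold$time_s), y = hold[[channel]])
}

#' Relative estimation error
#'
#' The accuracy metric of the validation study:
#' `|analyzed - true| / true`, the magnitude of the relative deviation of an
#' estimated viscoelastic property from its ground-truth value. Reported
#' tables and plots express it in percent; an estimate is conventionally
#' called accurate when the error is below 5%.
#'
#' @param analyzed Estimated value(s).
#' @param true Ground-truth value(s); must be non-zero.
#'
#' @return The absolute relative error as a fraction (multiply by 100 for %).
#'
#' @examples
#' relative_error(21, 20) # 0.05
#' @export
relative_error <- function(analyzed, true) {
  if (any(true == 0, na.rm = TRUE)) abort("`true` must be non-zero.")
  abs(analyzed - true) / abs(true)
}

# ---- internal least-squares machinery --------------------------------------

fit_hold_curve <- function(test, form, hold, proto, fit_k, truth = NULL) {
  n_par <- if (form == "finite") (3L + as.integer(fit_k)) else 3L
  if (length(hold$t) < n_par) {
    abort(sprintf(
      "The hold phase has %d samples but the %s form needs at least %d.",
      length(hold$t), form, n_par
    ))
  }
  spec <- fit_spec(test, form, hold, proto, fit_k)
  out <- lm_multistart(spec)
  est <- spec$extract(out$par)
  equilibrium <- if (test == "relaxation") {
    est$E1 * proto$hold_level
  } else {
    proto$hold_level / est$E1
  }
  result <- structure(
    c(est, list(
      test = test, form = form,
      residual_rms = sqrt(mean(out$resid^2)),
      converged = out$converged,
      condition_warning = abs(est$amplitude) < 1e-3 * abs(equilibrium),
      n_obs = length(hold$t),
      protocol = proto,
      truth = truth
    )),
    class = "sls_fit"
  )
  result
}

# Builds the residual function, start values, bounds and back-transform for
# one (test, form) combination. Free parameters are log-scaled except k.
fit_spec <- function(test, form, hold, proto, fit_k) {
  t <- hold$t
  y <- hold$y
  r <- proto$rate
  level <- proto$hold_level
  init <- hold_init(test, hold, proto)

  if (form == "finite") {
    model <- function(par) {
      E1 <- exp(par[1]); tau_R <- exp(par[2]); delta <- exp(par[3])
      k <- if (fit_k) par[4] else 1
      tau_C <- tau_R * (1 + delta)
      if (test == "relaxation") {
        A <- -E1 * r * (tau_C - tau_R) * expm1(-level / (tau_R * r))
        A * exp(-(t / tau_R)^k) + E1 * level
      } else {
        A <- (r / E1) * (tau_C - tau_R) * expm1(-level / (tau_C * r))
        A * exp(-(t / tau_C)^k) + level / E1
      }
    }
    start <- c(log(init$E1), log(init$tau_R), log(init$delta))
    lower <- c(-Inf, -Inf, -Inf)
    upper <- c(Inf, Inf, Inf)
    if (fit_k) {
      start <- c(start, 1)
      lower <- c(lower, 1e-3)
      upper <- c(upper, 1)
    }
    extract <- function(par) {
      E1 <- exp(par[1]); tau_R <- exp(par[2])
      tau_C <- tau_R * (1 + exp(par[3]))
      arm <- moduli_from_time_constants(E1, tau_R, tau_C)
      A <- if (test == "relaxation") {
        -E1 * r * (tau_C - tau_R) * expm1(-level / (tau_R * r))
      } else {
        (r / E1) * (tau_C - tau_R) * expm1(-level / (tau_C * r))
      }
      list(
        E1 = E1, E2 = arm$E2, eta = arm$eta,
        tau_R = tau_R, tau_C = tau_C,
        k = if (fit_k) par[4] else 1,
        amplitude = A
      )
    }
    perturb <- function(start, i) {
      s <- start
      s[2] <- s[2] + c(-log(2), log(2), -log(5))[i]
      s[3] <- s[3] + c(log(2), -log(2), log(5))[i]
      s
    }
  } else if (test == "relaxation") {
    # step-loading relaxation: free E1, E2, tau_R
    model <- function(par) {
      (exp(par[1]) + exp(par[2]) * exp(-t / exp(par[3]))) * level
    }
    start <- c(log(init$E1), log(init$E2), log(init$tau_R))
    lower <- rep(-Inf, 3)
    upper <- rep(Inf, 3)
    extract <- function(par) {
      E1 <- exp(par[1]); E2 <- exp(par[2]); tau_R <- exp(par[3])
      eta <- tau_R * E2
      list(
        E1 = E1, E2 = E2, eta = eta,
        tau_R = tau_R, tau_C = eta * (E1 + E2) / (E1 * E2),
        k = NA_real_, amplitude = E2 * level
      )
    }
    perturb <- function(start, i) {
      s <- start
      s[3] <- s[3] + c(-log(2), log(2), log(5))[i]
      s[2] <- s[2] + c(log(2), -log(2), -log(5))[i]
      s
    }
  } else {
    # step-loading creep: free E1, G = E2/(E1+E2) in (0,1), tau_C
    model <- function(par) {
      (level / exp(par[1])) * (1 - par[2] * exp(-t / exp(par[3])))
    }
    start <- c(log(init$E1), min(max(init$G, 1e-4), 1 - 1e-4), log(init$tau_C))
    lower <- c(-Inf, 1e-6, -Inf)
    upper <- c(Inf, 1 - 1e-6, Inf)
    extract <- function(par) {
      E1 <- exp(par[1]); G <- par[2]; tau_C <- exp(par[3])
      E2 <- E1 * G / (1 - G)
      eta <- tau_C * E1 * E2 / (E1 + E2)
      list(
        E1 = E1, E2 = E2, eta = eta,
        tau_R = eta / E2, tau_C = tau_C,
        k = NA_real_, amplitude = -G * level / E1
      )
    }
    perturb <- function(start, i) {
      s <- start
      s[3] <- s[3] + c(-log(2), log(2), log(5))[i]
      s[2] <- min(max(s[2] * c(0.5, 1.5, 0.1)[i], 1e-6), 1 - 1e-6)
      s
    }
  }
  list(
    residual = function(par) model(par) - y,
    start = start, lower = lower, upper = upper,
    extract = extract, perturb = perturb
  )
}

# Data-driven starting values shared by both forms.
hold_init <- function(test, hold, proto) {
  t <- hold$t
  y <- hold$y
  n <- length(y)
  y_inf <- mean(y[t >= 0.9 * max(t)]) # last-decile mean = equilibrium level
  A0 <- y[1] - y_inf
  tau0 <- efold_time(t, y, y_inf, A0)
  if (test == "relaxation") {
    E1 <- max(y_inf / proto$hold_level, .Machine$double.eps)
    E2 <- max(abs(A0) / proto$hold_level, 1e-6 * E1)
    # invert the finite-rate amplitude for tau_C - tau_R given E1, tau0
    denom <- -proto$rate * E1 * expm1(-proto$hold_level / (tau0 * proto$rate))
    dtau <- abs(A0) / max(denom, .Machine$double.xmin)
    list(E1 = E1, E2 = E2, tau_R = tau0, tau_C = tau0 + dtau,
         delta = max(dtau / tau0, 1e-6), G = NA)
  } else {
    E1 <- max(proto$hold_level / y_inf, .Machine$double.eps)
    denom <- (proto$rate / E1) *
      (-expm1(-proto$hold_level / (tau0 * proto$rate)))
    dtau <- abs(A0) / max(denom, .Machine$double.xmin)
    y0 <- y[1]
    G <- min(max(1 - y0 / y_inf, 1e-4), 1 - 1e-4)
    list(E1 = E1, E2 = E1 * G / (1 - G), tau_R = tau0, tau_C = tau0 + dtau,
         delta = max(dtau / tau0, 1e-6), G = G)
  }
}

# Time at which the normalized decay crosses 1/e (linear interpolation);
# falls back to a third of the hold span for degenerate decays.
efold_time <- function(t, y, y_inf, A0) {
  fallback <- max(t) / 3
  if (abs(A0) <= .Machine$double.eps * max(abs(y))) return(fallback)
  z <- (y - y_inf) / A0
  below <- which(z <= exp(-1))
  below <- below[below > 1L]
  if (length(below) == 0L) return(fallback)
  i <- below[1]
  t0 <- t[i - 1]; t1 <- t[i]
  z0 <- z[i - 1]; z1 <- z[i]
  if (!is.finite(z0) || !is.finite(z1) || z0 == z1) return(t1)
  tau <- t0 + (z0 - exp(-1)) / (z0 - z1) * (t1 - t0)
  if (!is.finite(tau) || tau <= 0) fallback else tau
}

lm_multistart <- function(spec, max_restarts = 3L) {
  run <- function(start) {
    minpack.lm::nls.lm(
      par = start, fn = spec$residual,
      lower = spec$lower, upper = spec$upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-12, ptol = 1e-12, maxiter = 500
      )
    )
  }
  safe_run <- function(start) {
    tryCatch(run(start), error = function(e) NULL)
  }
  best <- safe_run(spec$start)
  ok <- function(fit) !is.null(fit) && fit$info %in% 1:4
  if (!ok(best)) {
    for (i in seq_len(max_restarts)) {
      cand <- safe_run(spec$perturb(spec$start, i))
      if (!is.null(cand) &&
          (is.null(best) || cand$deviance < best$deviance)) {
        best <- cand
      }
      if (ok(best)) break
    }
  }
  if (is.null(best)) {
    abort("Least-squares fit failed from every starting point.")
  }
  list(
    par = best$par,
    resid = best$fvec,
    converged = best$info %in% 1:4
  )
}
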