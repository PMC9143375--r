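#' Closed-form ramp (loading-phase) responses of the standard linear solid
#'
#' During the loading ramp of a stress-relaxation test the strain grows as
#' `eps(t) = r * t` and the stress follows
#' \deqn{\sigma(t) = E_1 r t + E_1 r (\tau_C - \tau_R)(1 - e^{-t/\tau_R}),}
#' strictly increasing from zero with initial slope `r * (E1 + E2)` (the
#' instantaneous modulus) and late-time slope `r * E1`. During the loading
#' ramp of a creep test the stress grows as `sigma(t) = r * t` and the strain
#' follows
#' \deqn{\varepsilon(t) = \frac{r}{E_1} t + \frac{r}{E_1}(\tau_R - \tau_C)(1 - e^{-t/\tau_C}),}
#' strictly increasing with initial slope `r / (E1 + E2)`; since
#' `tau_R < tau_C` the second term is negative and the strain lags the
#' quasi-static line `r * t / E1`.
#'
#' Time is measured from the start of the ramp; both functions are defined
#' only on the ramp window `0 <= t <= ramp_duration` implied by `rate` and a
#' hold level (pass `ramp_duration = Inf` to evaluate the expression
#' unrestricted).
#'
#' @param t Time(s) since the start of loading, s; vectorized.
#' @param p An [sls_parameters()] object.
#' @param rate Loading rate: strain rate (1/s) for `ramp_stress()`, stress
#'   rate (Pa/s) for `ramp_strain()`.
#' @param ramp_duration End of the ramp window, s. Values of `t` outside
#'   `[0, ramp_duration]` are a domain error.
#'
#' @return Numeric vector: stress in Pa (`ramp_stress`) or dimensionless
#'   strain (`ramp_strain`).
#'
#' @examples
#' p <- sls_parameters(5000, 20000, 10000)
#' ramp_stress(c(0, 0.5, 1), p, rate = 0.01, ramp_duration = 1)
#' @export
ramp_stress <- function(t, p, rate, ramp_duration = Inf) {
  stopifnot(inherits(p, "sls_parameters"))
  check_positive_scalar(rate, "rate")
  check_ramp_window(t, ramp_duration)
  p$E1 * rate * t - p$E1 * rate * (p$tau_C - p$tau_R) * expm1(-t / p$tau_R)
}

#' @rdname ramp_stress
#' @export
ramp_strain <- function(t, p, rate, ramp_duration = Inf) {
  stopifnot(inherits(p, "sls_parameters"))
  check_positive_scalar(rate, "rate")
  check_ramp_window(t, ramp_duration)
  (rate / p$E1) * t + (rate / p$E1) * (p$tau_R - p$tau_C) * (-expm1(-t / p$tau_C))
}

#' Response at the end of the loading ramp
#'
#' `ramp_end_stress()` evaluates the loading solution at the ramp end
#' `t' = eps0 / r` of a stress-relaxation test:
#' \deqn{\sigma_0 = E_1 \varepsilon_0 + E_1 r (\tau_C - \tau_R)\left(1 - e^{-\varepsilon_0/(\tau_R r)}\right),}
#' the stress from which relaxation starts. As `r -> Inf` this tends to the
#' step-loading value `(E1 + E2) * eps0`; as `r -> 0` it tends to the
#' quasi-static `E1 * eps0`. `ramp_end_strain()` is the creep-test mirror,
#' \deqn{\varepsilon_0 = \sigma_0/E_1 + \frac{r}{E_1}(\tau_R - \tau_C)\left(1 - e^{-\sigma_0/(\tau_C r)}\right),}
#' tending to `sigma0 / (E1 + E2)` (fast) and `sigma0 / E1` (slow).
#'
#' The exponential complements are evaluated with `expm1()` so that very fast
#' ramps (`r * tau_R >> eps0`) do not suffer catastrophic cancellation.
#'
#' @param p An [sls_parameters()] object.
#' @param proto A [relaxation_protocol()] (for `ramp_end_stress`) or
#'   [creep_protocol()] (for `ramp_end_strain`).
#'
#' @return Stress in Pa, or dimensionless strain.
#'
#' @examples
#' p <- sls_parameters(5000, 20000, 10000)
#' ramp_end_stress(p, relaxation_protocol(0.01, 0.01, 4))
#' @export
ramp_end_stress <- function(p, proto) {
  stopifnot(inherits(proto, "relaxation_protocol"))
  p$E1 * proto$hold_level + relaxation_amplitude(p, proto)
}

#' @rdname ramp_end_stress
#' @export
ramp_end_strain <- function(p, proto) {
  stopifnot(inherits(proto, "creep_protocol"))
  proto$hold_level / p$E1 + creep_amplitude(p, proto)
}

# Amplitude of the hold-phase exponential: positive for relaxation,
# negative for creep. expm1 keeps the fast-ramp limit accurate.
relaxation_amplitude <- function(p, proto) {
  stopifnot(inherits(p, "sls_parameters"))
  r <- proto$rate
  -p$E1 * r * (p$tau_C - p$tau_R) * expm1(-proto$hold_level / (p$tau_R * r))
}

creep_amplitude <- function(p, proto) {
  stopifnot(inherits(p, "sls_parameters"))
  r <- proto$rate
  -(r / p$E1) * (p$tau_R - p$tau_C) * expm1(-proto$hold_level / (p$tau_C * r))
}

#' Hold-phase responses: finite-rate and step-loading (infinite-rate) forms
#'
#' `relaxation_stress()` is the finite-loading-rate solution for the stress
#' during the hold (relaxation) phase of a ramp-hold stress-relaxation test,
#' with time restarted at the beginning of the hold:
#' \deqn{\sigma(t) = E_1 r (\tau_C - \tau_R)\left(1 - e^{-\varepsilon_0/(\tau_R r)}\right) e^{-(t/\tau_R)^k} + E_1 \varepsilon_0.}
#' The decay amplitude is the ramp-end overshoot above the equilibrium stress
#' `E1 * eps0`; with `k < 1` the ordinary exponential is broadened to a
#' stretched-exponential (Kohlrausch) decay, which fits real materials whose
#' relaxation is not single-exponential. `creep_strain()` is the mirror for
#' the creep hold phase,
#' \deqn{\varepsilon(t) = \frac{r}{E_1}(\tau_R - \tau_C)\left(1 - e^{-\sigma_0/(\tau_C r)}\right) e^{-(t/\tau_C)^k} + \sigma_0/E_1,}
#' whose amplitude is negative: the strain rises towards `sigma0 / E1`.
#'
#' `relaxation_stress_step()` and `creep_strain_step()` are the traditional
#' solutions derived assuming step (infinite-rate) loading:
#' `sigma(t) = (E1 + E2 * exp(-t/tau_R)) * eps0` and
#' `eps(t) = (sigma0/E1) * (1 - (E2/(E1+E2)) * exp(-t/tau_C))`. The
#' finite-rate forms converge to them (with `k = 1`) as the loading rate
#' grows without bound.
#'
#' @param t Time(s) since the start of the hold phase, s; non-negative,
#'   vectorized.
#' @param p An [sls_parameters()] object.
#' @param proto A [relaxation_protocol()] or [creep_protocol()] supplying the
#'   loading rate and hold level.
#' @param k Stretch exponent in (0, 1]; `k = 1` is the ordinary exponential.
#' @param hold_strain,hold_stress Hold level for the step-loading forms.
#'
#' @return Numeric vector: stress in Pa, or dimensionless strain.
#'
#' @examples
#' p <- sls_parameters(5000, 20000, 10000)
#' proto <- relaxation_protocol(0.01, 0.01, hold_duration = 4)
#' relaxation_stress(c(0, 1, 4), p, proto)
#' relaxation_stress_step(c(0, 1, 4), p, hold_strain = 0.01)
#' @export
relaxation_stress <- function(t, p, proto, k = 1) {
  stopifnot(inherits(p, "sls_parameters"), inherits(proto, "relaxation_protocol"))
  check_nonnegative_time(t)
  check_stretch_exponent(k)
  relaxation_amplitude(p, proto) * exp(-(t / p$tau_R)^k) + p$E1 * proto$hold_level
}

#' @rdname relaxation_stress
#' @export
relaxation_stress_step <- function(t, p, hold_strain) {
  stopifnot(inherits(p, "sls_parameters"))
  check_nonnegative_time(t)
  check_positive_scalar(hold_strain, "hold_strain")
  (p$E1 + p$E2 * exp(-t / p$tau_R)) * hold_strain
}

#' @rdname relaxation_stress
#' @export
creep_strain <- function(t, p, proto, k = 1) {
  stopifnot(inherits(p, "sls_parameters"), inherits(proto, "creep_protocol"))
  check_nonnegative_time(t)
  check_stretch_exponent(k)
  creep_amplitude(p, proto) * exp(-(t / p$tau_C)^k) + proto$hold_level / p$E1
}

#' @rdname relaxation_stress
#' @export
creep_strain_step <- function(t, p, hold_stress) {
  stopifnot(inherits(p, "sls_parameters"))
  check_nonnegative_time(t)
  check_positive_scalar(hold_stress, "hold_stress")
  (hold_stress / p$E1) * (1 - (p$E2 / (p$E1 + p$E2)) * exp(-t / p$tau_C))
}

check_ramp_window <- function(t, ramp_duration) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.")
  }
  if (any(t < 0) || any(t > ramp_duration)) {
    abort("`t` must lie within the loading ramp window [0, ramp_duration].")
  }
  invisible(t)
}
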