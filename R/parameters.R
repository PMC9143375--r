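#' Standard linear solid material parameters
#'
#' The Maxwell form of the standard linear solid (Zener) model consists of a
#' spring `E1` in parallel with a Maxwell arm (spring `E2` in series with a
#' dashpot `eta`). `E1` is the equilibrium (long-time) modulus, `E1 + E2` the
#' instantaneous modulus. Two derived time constants govern the transient
#' response: the relaxation time constant `tau_R = eta / E2` (stress decay at
#' fixed strain) and the creep, or retardation, time constant
#' `tau_C = eta * (E1 + E2) / (E1 * E2)` (strain growth at fixed stress).
#' `tau_C > tau_R` always, since `(E1 + E2) / E1 > 1`.
#'
#' @param E1 Equilibrium spring modulus, Pa. Must be finite and positive.
#' @param E2 Maxwell-arm spring modulus, Pa. Must be finite and positive.
#' @param eta Dashpot viscosity, Pa s. Must be finite and positive.
#'
#' @return An object of class `sls_parameters`: a list with fields `E1`,
#'   `E2`, `eta` and the derived `tau_R`, `tau_C`.
#'
#' @examples
#' p <- sls_parameters(E1 = 5000, E2 = 20000, eta = 10000)
#' p$tau_R # 0.5 s
#' p$tau_C # 2.5 s
#' @export
sls_parameters <- function(E1, E2, eta) {
  check_positive_scalar(E1, "E1")
  check_positive_scalar(E2, "E2")
  check_positive_scalar(eta, "eta")
  structure(
    list(
      E1 = E1, E2 = E2, eta = eta,
      tau_R = eta / E2,
      tau_C = eta * (E1 + E2) / (E1 * E2)
    ),
    class = "sls_parameters"
  )
}

#' @export
print.sls_parameters <- function(x, ...) {
  cat("<sls_parameters>\n")
  cat(sprintf("  E1  = %g Pa   E2 = %g Pa   eta = %g Pa s\n", x$E1, x$E2, x$eta))
  cat(sprintf("  tau_R = %g s   tau_C = %g s\n", x$tau_R, x$tau_C))
  invisible(x)
}

#' One-branch Prony (relaxation-modulus) material parameters
#'
#' Finite-element packages commonly parameterize a linear viscoelastic
#' material by an instantaneous modulus `E` and a one-branch dimensionless
#' Prony series for the relaxation modulus,
#' `gR(t) = 1 - g * (1 - exp(-t / tau_R))`, where `g` is the relaxed modulus
#' fraction, `0 < g < 1`. This triple maps one-to-one onto the standard
#' linear solid triple via `E1 = E`, `E2 = E * g / (1 - g)`,
#' `eta = tau_R * E2` (see [prony_to_sls()], [sls_to_prony()]).
#'
#' @param E Modulus of elasticity, Pa. Must be finite and positive.
#' @param g Relaxed fraction, dimensionless, strictly between 0 and 1.
#' @param tau_R Relaxation time constant, s. Must be finite and positive.
#'
#' @return An object of class `prony_parameters`.
#'
#' @examples
#' prony_parameters(E = 30000, g = 0.8, tau_R = 5)
#' @export
prony_parameters <- function(E, g, tau_R) {
  check_positive_scalar(E, "E")
  check_positive_scalar(tau_R, "tau_R")
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0 || g >= 1) {
    abort("`g` must be a single finite value strictly between 0 and 1.")
  }
  structure(list(E = E, g = g, tau_R = tau_R), class = "prony_parameters")
}

#' @export
print.prony_parameters <- function(x, ...) {
  cat("<prony_parameters>\n")
  cat(sprintf("  E = %g Pa   g = %g   tau_R = %g s\n", x$E, x$g, x$tau_R))
  invisible(x)
}

#' Convert between standard linear solid and Prony parameterizations
#'
#' `sls_to_prony()` maps (`E1`, `E2`, `eta`) to (`E`, `g`, `tau_R`) via
#' `E = E1`, `g = E2 / (E1 + E2)`, `tau_R = eta / E2`. `prony_to_sls()` is
#' the exact inverse: `E1 = E`, `E2 = E * g / (1 - g)`,
#' `eta = tau_R * E * g / (1 - g)`. The two round-trip to machine precision.
#'
#' @param p An [sls_parameters()] object.
#' @param q A [prony_parameters()] object.
#'
#' @return `sls_to_prony()` returns a `prony_parameters` object;
#'   `prony_to_sls()` returns an `sls_parameters` object.
#'
#' @examples
#' prony_to_sls(prony_parameters(E = 30, g = 0.8, tau_R = 5)) # kPa scale
#' @export
sls_to_prony <- function(p) {
  stopifnot(inherits(p, "sls_parameters"))
  prony_parameters(E = p$E1, g = p$E2 / (p$E1 + p$E2), tau_R = p$eta / p$E2)
}

#' @rdname sls_to_prony
#' @export
prony_to_sls <- function(q) {
  stopifnot(inherits(q, "prony_parameters"))
  E2 <- q$E * q$g / (1 - q$g)
  sls_parameters(E1 = q$E, E2 = E2, eta = q$tau_R * E2)
}

#' Dimensionless one-branch relaxation modulus
#'
#' Evaluates `gR(t) = 1 - g * (1 - exp(-t / tau_R))`, the normalized
#' relaxation modulus of the one-branch Prony material: 1 at `t = 0`,
#' decaying to the plateau `1 - g` as `t -> Inf`.
#'
#' @param t Time(s), s; non-negative, vectorized.
#' @param q A [prony_parameters()] object.
#'
#' @return Numeric vector of modulus fractions in `(1 - g, 1]`.
#'
#' @examples
#' relaxation_modulus(c(0, 5, Inf), prony_parameters(30000, 0.8, 5))
#' @export
relaxation_modulus <- function(t, q) {
  stopifnot(inherits(q, "prony_parameters"))
  check_nonnegative_time(t)
  1 + q$g * expm1(-t / q$tau_R)
}

#' Recover the Maxwell-arm parameters from time constants
#'
#' Solves the pair `tau_R = eta / E2` and
#' `tau_C = eta * (E1 + E2) / (E1 * E2)` for `E2` and `eta` given `E1`:
#' `E2 = E1 * (tau_C - tau_R) / tau_R`, `eta = tau_R * E2`. This is the step
#' used after curve fitting, where the hold-phase fit yields `E1`, `tau_R`
#' and `tau_C` and the remaining material constants follow algebraically.
#'
#' @param E1 Equilibrium modulus, Pa, positive.
#' @param tau_R Relaxation time constant, s, positive.
#' @param tau_C Creep time constant, s; must exceed `tau_R` (a standard
#'   linear solid with `tau_C <= tau_R` is non-physical).
#'
#' @return A list with fields `E2` (Pa) and `eta` (Pa s).
#'
#' @examples
#' moduli_from_time_constants(5000, tau_R = 0.5, tau_C = 2.5)
#' @export
moduli_from_time_constants <- function(E1, tau_R, tau_C) {
  check_positive_scalar(E1, "E1")
  check_positive_scalar(tau_R, "tau_R")
  check_positive_scalar(tau_C, "tau_C")
  if (tau_C <= tau_R) {
    abort("`tau_C` must exceed `tau_R`: the pair is otherwise non-physical for a standard linear solid.")
  }
  E2 <- E1 * (tau_C - tau_R) / tau_R
  list(E2 = E2, eta = tau_R * E2)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite positive number.", name))
  }
  invisible(x)
}

check_nonnegative_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t) & !is.infinite(t)) || any(t < 0, na.rm = TRUE)) {
    abort("`t` must be numeric and non-negative.")
  }
  invisible(t)
}
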