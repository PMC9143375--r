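#' Sampling plan for simulated ramp-hold curves
#'
#' @param n_ramp Number of samples on the loading ramp (the ramp-end instant
#'   itself is the first hold sample). If fewer than 10 are requested the
#'   plan is raised to 50 so the ramp is always resolved, and the returned
#'   curve records a note in its `sampling_note` attribute.
#' @param n_hold Number of samples on the hold phase, including its first
#'   instant.
#'
#' @return A list with fields `n_ramp`, `n_hold`.
#' @export
sampling_plan <- function(n_ramp = 200, n_hold = 1000) {
  stopifnot(is.numeric(n_ramp), n_ramp >= 2, is.numeric(n_hold), n_hold >= 2)
  list(n_ramp = as.integer(n_ramp), n_hold = as.integer(n_hold))
}

#' Simulate ramp-hold stress-relaxation and creep tests
#'
#' Generates the full time/stress/strain record of one ramp-hold test on a
#' standard linear solid at a single material point — the desk-scale
#' surrogate for a finite-element specimen of a linear, isotropic,
#' homogeneous material under uniform uniaxial ramp-hold loading, where every
#' element follows the same 1-D constitutive relations.
#'
#' With `method = "analytic"` the curve is evaluated from the closed-form
#' ramp and hold solutions ([ramp_stress()], [relaxation_stress()] with
#' `k = 1`, and their creep mirrors). With `method = "ode"` the governing
#' differential relation of the standard linear solid,
#' \deqn{\sigma + \tau_R \dot\sigma = E_1 (\varepsilon + \tau_C \dot\varepsilon),}
#' is integrated numerically (adaptive `lsoda`, relative tolerance 1e-9)
#' under the same controlled input, giving an oracle that is independent of
#' the closed forms.
#'
#' @param p An [sls_parameters()] object; stored in the curve as ground truth.
#' @param proto A [relaxation_protocol()] or [creep_protocol()].
#' @param sampling A [sampling_plan()].
#' @param method `"analytic"` (closed form) or `"ode"` (numerical oracle).
#'
#' @return A tibble of class `sls_curve` with columns `time_s` (from load
#'   start, strictly increasing), `stress_Pa`, `strain`, `phase`
#'   (`"loading"` then `"hold"`), and attributes `test`, `protocol`, `truth`,
#'   `method`.
#'
#' @examples
#' p <- sls_parameters(5000, 20000, 10000)
#' curve <- simulate_relaxation(p, relaxation_protocol(0.01, 0.01, 4))
#' head(curve)
#' @export
simulate_relaxation <- function(p, proto, sampling = sampling_plan(),
                                method = c("analytic", "ode")) {
  stopifnot(inherits(proto, "relaxation_protocol"))
  method <- match.arg(method)
  tm <- ramp_hold_times(proto, sampling)
  strain <- c(proto$rate * tm$ramp, rep(proto$hold_level, length(tm$hold)))
  stress <- if (method == "analytic") {
    c(
      ramp_stress(tm$ramp, p, proto$rate, proto$ramp_duration),
      relaxation_stress(tm$hold - proto$ramp_duration, p, proto, k = 1)
    )
  } else {
    integrate_sls(p, proto, tm, response = "stress")
  }
  new_sls_curve(tm, stress, strain, "relaxation", proto, p, method, tm$note)
}

#' @rdname simulate_relaxation
#' @export
simulate_creep <- function(p, proto, sampling = sampling_plan(),
                           method = c("analytic", "ode")) {
  stopifnot(inherits(proto, "creep_protocol"))
  method <- match.arg(method)
  tm <- ramp_hold_times(proto, sampling)
  stress <- c(proto$rate * tm$ramp, rep(proto$hold_level, length(tm$hold)))
  strain <- if (method == "analytic") {
    c(
      ramp_strain(tm$ramp, p, proto$rate, proto$ramp_duration),
      creep_strain(tm$hold - proto$ramp_duration, p, proto, k = 1)
    )
  } else {
    integrate_sls(p, proto, tm, response = "strain")
  }
  new_sls_curve(tm, stress, strain, "creep", proto, p, method, tm$note)
}

ramp_hold_times <- function(proto, sampling) {
  n_ramp <- sampling$n_ramp
  note <- NULL
  if (n_ramp < 10L) {
    n_ramp <- 50L
    note <- "ramp sampling raised to 50 points (requested plan was coarser than 10)"
  }
  tp <- proto$ramp_duration
  ramp <- seq(0, tp, length.out = n_ramp + 1L)[seq_len(n_ramp)]
  hold <- tp + seq(0, proto$hold_duration, length.out = sampling$n_hold)
  list(ramp = ramp, hold = hold, note = note)
}

new_sls_curve <- function(tm, stress, strain, test, proto, truth, method, note) {
  curve <- tibble::tibble(
    time_s = c(tm$ramp, tm$hold),
    stress_Pa = stress,
    strain = strain,
    phase = c(rep("loading", length(tm$ramp)), rep("hold", length(tm$hold)))
  )
  structure(
    curve,
    class = c("sls_curve", class(curve)),
    test = test, protocol = proto, truth = truth, method = method,
    sampling_note = note
  )
}

# Integrates sigma + tau_R*dsigma = E1*(eps + tau_C*deps) with the controlled
# channel prescribed, in two legs (ramp, hold) so the rate discontinuity at
# the ramp end is not smoothed over.
integrate_sls <- function(p, proto, tm, response) {
  tp <- proto$ramp_duration
  rtol <- 1e-9
  if (response == "stress") {
    deriv <- function(t, y, parms) {
      eps <- if (parms$ramp) proto$rate * t else proto$hold_level
      deps <- if (parms$ramp) proto$rate else 0
      list((p$E1 * (eps + p$tau_C * deps) - y) / p$tau_R)
    }
    scale <- (p$E1 + p$E2) * proto$hold_level
  } else {
    deriv <- function(t, y, parms) {
      sig <- if (parms$ramp) proto$rate * t else proto$hold_level
      dsig <- if (parms$ramp) proto$rate else 0
      list((sig + p$tau_R * dsig - p$E1 * y) / (p$E1 * p$tau_C))
    }
    scale <- proto$hold_level / p$E1
  }
  leg1 <- deSolve::lsoda(
    y = 0, times = unique(c(tm$ramp, tp)), func = deriv,
    parms = list(ramp = TRUE), rtol = rtol, atol = rtol * scale
  )
  y_tp <- leg1[nrow(leg1), 2]
  leg2 <- deSolve::lsoda(
    y = y_tp, times = tm$hold - tp, func = deriv,
    parms = list(ramp = FALSE), rtol = rtol, atol = rtol * scale
  )
  c(leg1[seq_along(tm$ramp), 2], leg2[, 2])
}

#' Add multiplicative measurement noise to a simulated curve
#'
#' Perturbs the *measured* channel of the test — stress for a relaxation
#' test, strain for a creep test — by independent multiplicative Gaussian
#' noise, `y * (1 + N(0, relative_sd^2))`. The controlled channel is left
#' exact. Reproducible for a fixed `seed`.
#'
#' @param curve An `sls_curve`.
#' @param relative_sd Relative standard deviation of the noise;
#'   `relative_sd = 0` returns the curve unchanged.
#' @param seed Integer RNG seed.
#'
#' @return The noisy `sls_curve`; the noise specification is recorded in the
#'   `noise` attribute.
#' @export
add_noise <- function(curve, relative_sd, seed) {
  stopifnot(inherits(curve, "sls_curve"))
  if (!is.numeric(relative_sd) || length(relative_sd) != 1L || relative_sd < 0) {
    abort("`relative_sd` must be a single non-negative number.")
  }
  if (relative_sd == 0) return(curve)
  channel <- if (attr(curve, "test") == "relaxation") "stress_Pa" else "strain"
  noisy <- curve
  withr::with_seed(seed, {
    noisy[[channel]] <- curve[[channel]] *
      (1 + rnorm(nrow(curve), sd = relative_sd))
  })
  attr(noisy, "noise") <- list(relative_sd = relative_sd, seed = seed)
  noisy
}

#' Read and write ramp-hold test curves as CSV
#'
#' Curves are stored as plain CSV with columns `time_s`, `stress_Pa`,
#' `strain`, `phase`; the protocol, ground truth and noise specification go
#' to a JSON sidecar (`<path>.json`) so a written curve round-trips.
#'
#' @param curve An `sls_curve`.
#' @param path CSV file path.
#'
#' @return `write_curve()` returns `path` invisibly; `read_curve()` returns
#'   an `sls_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sls_curve"))
  readr::write_csv(as.data.frame(curve), path)
  proto <- attr(curve, "protocol")
  truth <- attr(curve, "truth")
  meta <- list(
    test = attr(curve, "test"),
    method = attr(curve, "method"),
    protocol = proto[c("rate", "hold_level", "hold_duration")],
    truth = if (!is.null(truth)) truth[c("E1", "E2", "eta")],
    noise = attr(curve, "noise")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          time_s = "d", stress_Pa = "d",
                          strain = "d", phase = "c"
                        ))
  sidecar <- paste0(path, ".json")
  test <- proto <- truth <- noise <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    test <- meta$test
    if (!is.null(meta$protocol)) {
      proto <- if (identical(test, "creep")) {
        creep_protocol(meta$protocol$rate, meta$protocol$hold_level,
                       meta$protocol$hold_duration)
      } else {
        relaxation_protocol(meta$protocol$rate, meta$protocol$hold_level,
                            meta$protocol$hold_duration)
      }
    }
    if (!is.null(meta$truth)) {
      truth <- sls_parameters(meta$truth$E1, meta$truth$E2, meta$truth$eta)
    }
    noise <- meta$noise
  }
  if (is.null(test)) test <- infer_test_kind(df)
  structure(
    df,
    class = c("sls_curve", class(df)),
    test = test, protocol = proto, truth = truth,
    method = NULL, noise = noise
  )
}

infer_test_kind <- function(df) {
  hold <- df[df$phase == "hold", ]
  if (nrow(hold) < 2) return(NA_character_)
  # the controlled channel is (near-)constant during the hold
  rel_range <- function(x) diff(range(x)) / max(abs(x), .Machine$double.eps)
  if (rel_range(hold$strain) <= rel_range(hold$stress_Pa)) "relaxation" else "creep"
}
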