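#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf("<sls_fit> %s test, %s-rate form\n", x$test, x$form))
  cat(sprintf(
    "  E1 = %.6g Pa   E2 = %.6g Pa   eta = %.6g Pa s\n", x$E1, x$E2, x$eta
  ))
  cat(sprintf("  tau_R = %.6g s   tau_C = %.6g s", x$tau_R, x$tau_C))
  if (!is.na(x$k)) cat(sprintf("   k = %.4g", x$k))
  cat("\n")
  cat(sprintf(
    "  residual RMS = %.4g on %d hold samples%s%s\n",
    x$residual_rms, x$n_obs,
    if (x$converged) "" else "  [NOT CONVERGED]",
    if (x$condition_warning) "  [ill-conditioned: decay amplitude ~ 0]" else ""
  ))
  invisible(x)
}

#' Tidy a fitted standard-linear-solid model
#'
#' `tidy()` returns one row per recovered quantity (`E1`, `E2`, `eta`,
#' `tau_R`, `tau_C`, and `k` for the finite form); when the fitted curve
#' carried ground truth, columns `true` and `rel_error_pct` (the
#' [relative_error()] in percent) are added. `glance()` returns a one-row
#' summary of the fit.
#'
#' @param x An `sls_fit` from [fit_relaxation()] or [fit_creep()].
#' @param ... Unused.
#'
#' @return A tibble.
#' @method tidy sls_fit
#' @export
tidy.sls_fit <- function(x, ...) {
  terms <- c("E1", "E2", "eta", "tau_R", "tau_C")
  if (!is.na(x$k)) terms <- c(terms, "k")
  out <- tibble::tibble(
    term = terms,
    estimate = purrr::map_dbl(terms, ~ x[[.x]])
  )
  truth <- x$truth
  if (!is.null(truth)) {
    true_vals <- c(truth$E1, truth$E2, truth$eta, truth$tau_R, truth$tau_C)
    if (!is.na(x$k)) true_vals <- c(true_vals, NA_real_)
    out$true <- true_vals
    out$rel_error_pct <- ifelse(
      is.na(out$true), NA_real_,
      100 * relative_error(out$estimate, out$true)
    )
  }
  out
}

#' @rdname tidy.sls_fit
#' @method glance sls_fit
#' @export
glance.sls_fit <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    form = x$form,
    residual_rms = x$residual_rms,
    n_obs = x$n_obs,
    converged = x$converged,
    condition_warning = x$condition_warning
  )
}

#' Plot a simulated or measured ramp-hold curve
#'
#' Shows the measured channel (stress for relaxation, strain for creep)
#' against time, colored by test phase.
#'
#' @param object An `sls_curve`.
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot sls_curve
#' @export
autoplot.sls_curve <- function(object, ...) {
  test <- attr(object, "test") %||% infer_test_kind(object)
  channel <- if (identical(test, "creep")) "strain" else "stress_Pa"
  ylab <- if (identical(test, "creep")) "strain" else "stress (Pa)"
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time_s, y = .data[[channel]], color = .data$phase)
  ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = ylab, color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.sls_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot estimation error against loading rate for a sweep
#'
#' One panel per (viscoelastic property, modulus of elasticity), error in
#' percent against the loading rate on a log axis, colored by the material's
#' relaxation time constant and keyed by equation form; the conventional 5%
#' accuracy line is drawn for reference.
#'
#' @param object A sweep tibble from [run_sweep()].
#' @param criterion_pct Accuracy reference line, percent.
#' @param ... Unused.
#'
#' @return A ggplot.
#' @method autoplot sls_sweep
#' @export
autoplot.sls_sweep <- function(object, criterion_pct = 5, ...) {
  long <- sweep_errors(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$rate, y = .data$error_pct,
      color = factor(.data$tau_R_true), linetype = .data$form,
      group = interaction(.data$model, .data$form)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = criterion_pct, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$E_true),
      cols = ggplot2::vars(.data$parameter)
    ) +
    ggplot2::labs(
      x = if (unique(object$test)[1] == "relaxation") {
        "strain rate (1/s)"
      } else {
        "stress rate (Pa/s)"
      },
      y = "error (%)", color = "tau_R (s)", linetype = "form"
    ) +
    ggplot2::theme_minimal()
}
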