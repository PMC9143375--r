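#' Ramp-hold test protocols
#'
#' A ramp-hold test loads the specimen at a constant rate from the unloaded
#' state to a prescribed hold level, then holds that level. In a
#' stress-relaxation test the *strain* is controlled: ramp at strain rate `r`
#' (1/s) to the hold strain `eps0`, so the ramp lasts `t' = eps0 / r` seconds.
#' In a creep test the *stress* is controlled: ramp at stress rate `r` (Pa/s)
#' to the hold stress `sigma0`, ramp duration `t' = sigma0 / r`.
#'
#' @param strain_rate Constant strain rate of the loading ramp, 1/s; positive.
#' @param hold_strain Strain held during the relaxation phase, dimensionless;
#'   positive.
#' @param stress_rate Constant stress rate of the loading ramp, Pa/s; positive.
#' @param hold_stress Stress held during the creep phase, Pa; positive.
#' @param hold_duration Length of the hold phase, s; positive.
#'
#' @return An object of class `relaxation_protocol` or `creep_protocol`, a
#'   list carrying the rate, hold level, hold duration and derived
#'   `ramp_duration`.
#'
#' @examples
#' relaxation_protocol(strain_rate = 0.01, hold_strain = 0.01, hold_duration = 4)
#' creep_protocol(stress_rate = 100, hold_stress = 100, hold_duration = 20)
#' @export
relaxation_protocol <- function(strain_rate, hold_strain, hold_duration) {
  check_positive_scalar(strain_rate, "strain_rate")
  check_positive_scalar(hold_strain, "hold_strain")
  check_positive_scalar(hold_duration, "hold_duration")
  structure(
    list(
      rate = strain_rate, hold_level = hold_strain,
      hold_duration = hold_duration,
      ramp_duration = hold_strain / strain_rate
    ),
    class = c("relaxation_protocol", "sls_protocol")
  )
}

#' @rdname relaxation_protocol
#' @export
creep_protocol <- function(stress_rate, hold_stress, hold_duration) {
  check_positive_scalar(stress_rate, "stress_rate")
  check_positive_scalar(hold_stress, "hold_stress")
  check_positive_scalar(hold_duration, "hold_duration")
  structure(
    list(
      rate = stress_rate, hold_level = hold_stress,
      hold_duration = hold_duration,
      ramp_duration = hold_stress / stress_rate
    ),
    class = c("creep_protocol", "sls_protocol")
  )
}

#' @export
print.sls_protocol <- function(x, ...) {
  kind <- if (inherits(x, "relaxation_protocol")) "relaxation" else "creep"
  unit_rate <- if (kind == "relaxation") "1/s" else "Pa/s"
  unit_level <- if (kind == "relaxation") "" else " Pa"
  cat(sprintf("<%s_protocol>\n", kind))
  cat(sprintf(
    "  rate = %g %s   hold level = %g%s   ramp %g s + hold %g s\n",
    x$rate, unit_rate, x$hold_level, unit_level, x$ramp_duration, x$hold_duration
  ))
  invisible(x)
}

protocol_kind <- function(proto) {
  if (inherits(proto, "relaxation_protocol")) "relaxation" else "creep"
}

check_stretch_exponent <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0 || k > 1) {
    abort("Stretch exponent `k` must be a single value in (0, 1].")
  }
  invisible(k)
}
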