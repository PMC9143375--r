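#' Benchmark soft-tissue-mimicking materials
#'
#' Nine hydrogel-like material models spanning moduli of elasticity
#' E in {5, 10, 30} kPa and relaxation time constants tau_R in
#' {0.5, 2, 5} s at a fixed relaxed fraction g = 0.8 — values in the range
#' reported for soft tissues. Each row carries both the Prony-style setting
#' (`E`, `tau_R`, `g`) and the equivalent standard-linear-solid triple
#' (`E1`, `E2`, `eta`) obtained with [prony_to_sls()]. All values are SI
#' (Pa, Pa s, s).
#'
#' @return A tibble with columns `model` (1-9), `E`, `tau_R`, `g`, `E1`,
#'   `E2`, `eta`.
#'
#' @examples
#' benchmark_materials()
#' @export
benchmark_materials <- function() {
  grid <- tidyr::expand_grid(
    E = c(5000, 10000, 30000),
    tau_R = c(0.5, 2, 5)
  )
  dplyr::mutate(
    grid,
    model = dplyr::row_number(),
    g = 0.8,
    E1 = .data$E,
    E2 = .data$E * .data$g / (1 - .data$g),
    eta = .data$tau_R * .data$E2,
    .before = 1
  ) |>
    dplyr::select("model", "E", "tau_R", "g", "E1", "E2", "eta")
}

#' Benchmark rate grids and trial plan
#'
#' `benchmark_rates()` returns the seven decade-spaced loading rates used in
#' the validation study: strain rates 1e-4 to 100 1/s for stress relaxation,
#' stress rates 1 to 1e6 Pa/s for creep — in both cases the ramp to the hold
#' level lasts from 100 s down to 1e-4 s. `benchmark_grid()` crosses the nine
#' [benchmark_materials()] with those rates (9 x 7 = 63 trials) at the study
#' hold levels: hold strain 0.01 (a 0.1 mm compression of a 10 mm specimen)
#' for relaxation, hold stress 100 Pa for creep. The hold phase lasts
#' `hold_multiplier` relaxation (creep) time constants so the plateau is
#' effectively reached.
#'
#' @param test `"relaxation"` or `"creep"`.
#' @param hold_multiplier Hold duration in units of the governing time
#'   constant (`tau_R` for relaxation, `tau_C` for creep). Default 8.
#'
#' @return `benchmark_rates()`: a numeric vector of 7 rates.
#'   `benchmark_grid()`: a tibble with one row per trial and columns `model`,
#'   `rate`, the material columns of [benchmark_materials()], and
#'   list-columns `params` ([sls_parameters()]) and `protocol`.
#'
#' @examples
#' nrow(benchmark_grid("relaxation")) # 63
#' @export
benchmark_grid <- function(test = c("relaxation", "creep"), hold_multiplier = 8) {
  test <- match.arg(test)
  check_positive_scalar(hold_multiplier, "hold_multiplier")
  mats <- benchmark_materials()
  trials <- tidyr::expand_grid(mats, rate = benchmark_rates(test))
  trials$params <- purrr::pmap(
    trials[c("E1", "E2", "eta")],
    function(E1, E2, eta) sls_parameters(E1, E2, eta)
  )
  trials$protocol <- purrr::map2(trials$params, trials$rate, function(p, r) {
    if (test == "relaxation") {
      relaxation_protocol(r, hold_strain = 0.01,
                          hold_duration = hold_multiplier * p$tau_R)
    } else {
      creep_protocol(r, hold_stress = 100,
                     hold_duration = hold_multiplier * p$tau_C)
    }
  })
  dplyr::relocate(trials, "model", "rate")
}

#' @rdname benchmark_grid
#' @export
benchmark_rates <- function(test = c("relaxation", "creep")) {
  test <- match.arg(test)
  if (test == "relaxation") 10^(-4:2) else 10^(0:6)
}
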