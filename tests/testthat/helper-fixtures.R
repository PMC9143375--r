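# Shared fixtures: the soft-gel reference material (E1 = 5 kPa, E2 = 20 kPa,
# eta = 10 kPa s, i.e. tau_R = 0.5 s, tau_C = 2.5 s) and lazily cached
# benchmark sweeps so the expensive grids are computed once per run.

soft_gel <- function() sls_parameters(E1 = 5000, E2 = 20000, eta = 10000)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

benchmark_sweep <- function(test) {
  cached(paste0("sweep_", test), run_sweep(test, forms = c("finite", "infinite")))
}

# deterministic random SLS parameter draws for property-style tests
random_materials <- function(n = 12, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sls_parameters(
        E1 = exp(runif(1, log(500), log(5e4))),
        E2 = exp(runif(1, log(500), log(5e4))),
        eta = exp(runif(1, log(100), log(1e5)))
      )
    })
  })
}
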