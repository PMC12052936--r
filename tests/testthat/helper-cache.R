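# Shared fixtures: expensive traveling-wave solves and linearizations are
# computed once per test run and reused across files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

cached_front <- function(preset) {
  cached(paste0("front_", preset),
         solve_front(load_preset(preset)$params))
}

cached_op0 <- function(preset) {
  cached(paste0("op0_", preset),
         assemble_linearization(cached_front(preset), 0))
}

cached_adjoint <- function(preset) {
  cached(paste0("adj_", preset),
         adjoint_null(cached_front(preset), op = cached_op0(preset)))
}
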