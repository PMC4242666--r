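## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

## Seed handling: every stochastic generator takes `seed`; when non-NULL the
## RNG state is set locally and restored on exit, so callers' streams are
## never disturbed and identical seeds give bit-identical output.
.use_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite integer")
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

## Lightweight numeric fingerprint used to verify that two model fits were
## computed on the same data (select_model contract).
.data_key <- function(conc, response) {
  c(n = length(response),
    sc = sum(conc), sc2 = sum(conc^2),
    sy = sum(response), sy2 = sum(response^2))
}
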