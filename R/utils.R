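#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' A single run-level seed fans out to per-stage seeds through a fixed integer
#' hash of the stage name, so each pipeline stage is independently
#' reproducible. Results always lie in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483563
  as.integer((abs(seed) %% 2147483563 * 48271 + h) %% 2147483562 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Canonical key string for a treatment group
#'
#' @param compound,system,dose,time_h Treatment attributes (vectorized).
#' @return Character vector `compound|system|dose|time_h`.
#' @export
treatment_key <- function(compound, system, dose, time_h) {
  paste(compound, system, dose, format(time_h, trim = TRUE), sep = "|")
}
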