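# Shared helpers: classed errors, seeded evaluation, seed derivation, checks.

cs_abort <- function(msg, class) {
  stop(structure(class = c(class, "cardiosynth_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_pow2 <- function(x) {
  x <- as.numeric(x)
  length(x) == 1L && is.finite(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived
#' deterministically from the master seed and a stage label, so that no stage
#' reads global randomness and runs are reproducible end to end. The derivation
#' hashes the label with a 32-bit FNV-1a accumulator folded into `[0, 2^31)`.
#'
#' @param master Integer master seed.
#' @param label Character stage label (e.g. `"gan_train"`).
#' @param index Optional non-negative integer for per-item seeds.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label, index = 0L) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 2166136261
  mix <- function(h, byte) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(byte))
    (h * 16777619) %% 2^31
  }
  for (b in utf8ToInt(paste0(label, ":", as.integer(index)))) h <- mix(h, b)
  h <- mix(h, as.integer(master) %% 256)
  h <- (h + as.numeric(master) * 2654435761) %% 2^31
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
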