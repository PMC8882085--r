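# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding with ties broken away from zero (so 0.5 -> 1, -16.5 -> -17),
#' the convention used for percent-difference tables. Base R's `round()` rounds
#' half to even and would give different integers on exact .5 ties.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic sub-seed derivation: every stochastic stage draws its own seed
# from a single master seed so stages can be re-run independently and the whole
# pipeline is reproducible bit-for-bit. Kept below 2^31 - 1.
derive_seed <- function(master_seed, stage, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + offs * 7919 + index * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pttq_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("pttq_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
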