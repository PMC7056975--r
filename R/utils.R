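#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' All stochastic stages draw from their own substream whose seed is a
#' deterministic hash of the master seed and a stage label. Adding genes to a
#' screen panel therefore never perturbs the genome simulation, and any stage
#' can be re-run in isolation with identical output.
#'
#' @param seed master integer seed.
#' @param tag character stage label, e.g. `"genome"` or `"gene:sgg"`.
#' @return an integer seed in `[0, 2^31 - 21)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483629 # large prime below 2^31
  h <- 5381
  for (code in utf8ToInt(tag)) h <- (h * 33 + code) %% m
  as.integer((h + (seed %% m) * 1000003) %% m)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# significance -> direction word used throughout the effect-call tables
call_direction <- function(estimate, p_value, alpha) {
  ifelse(p_value < alpha, ifelse(estimate > 0, "increase", "decrease"), "ns")
}
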