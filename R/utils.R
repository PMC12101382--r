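# Shared numeric helpers.

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding with ties going up (for positive values), the convention
#' used throughout clinical screening reports; base [round()] rounds half to
#' even and would disagree on printed report cells. A small epsilon absorbs
#' binary representation error: a quotient such as 3.15/60 is stored just
#' below the true tie point 0.0525 and must still display as 0.053.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up (away from zero) to `digits` decimals.
#' @examples
#' round_half_up(2.845, 2)  # 2.85
#' round_half_up(3.15 / 60, 3)  # 0.053
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Derive a reproducible sub-stream seed
#'
#' One master seed drives every stochastic operation; each operation draws
#' from its own stream identified by a salt string, so adding draws to one
#' stage never perturbs another. The derived seed is kept inside the 32-bit
#' integer range.
#'
#' @param seed master seed (integer).
#' @param salt operation label.
#' @return an integer seed, deterministic in `(seed, salt)`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(salt))
  codes <- utf8ToInt(salt)
  h <- sum(codes * seq_along(codes) * 31771) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646) + 1L
}

# stop() with a sprintf-style message, no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
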