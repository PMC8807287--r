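# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Printed tables in psychology journals conventionally round halves away
#' from zero (so -2.65 renders as -2.7), unlike [round()]'s banker's
#' rounding. Used when reproducing printed statistics.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic entry points route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-participant RNG seed from the cohort seed and the participant
# index, so a cohort can be extended with new participants without
# perturbing existing ones. Kept below 2^31 - 1.
participant_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 2147483629 + 1000003 * idx) %% 2147483629)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_config(field, "must be numeric, no NA")
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(x < lo | x > hi)) stop_config(field, "must lie in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x != floor(x)) || any(x < min)) {
    stop_config(field, sprintf("must be an integer >= %d", min))
  }
  invisible(x)
}
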