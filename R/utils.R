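# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all printed percentages and money
#' figures, so that e.g. 34.5% reports as 35%. R's [round()] rounds half to
#' even, which does not match how costing reports are conventionally printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), 0)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Partition `amount` across `weights` in whole cents, assigning the leftover
# cents by descending fractional remainder (ties resolved toward the final
# key) so the parts always sum to round(amount, 2).
largest_remainder_split <- function(amount, weights) {
  if (length(weights) == 0) {
    rlang::abort("`weights` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    rlang::abort("`weights` must be nonnegative and finite.")
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    rlang::abort(sprintf("`weights` must sum to 1 (got %.12g).", s))
  }
  total_cents <- round(amount * 100)
  raw <- total_cents * weights
  base <- floor(raw + 1e-9)
  k <- as.integer(round(total_cents - sum(base)))
  if (k > 0) {
    ord <- order(-(raw - base), -seq_along(weights))
    base[ord[seq_len(k)]] <- base[ord[seq_len(k)]] + 1
  } else if (k < 0) {
    ord <- order(raw - base, seq_along(weights))
    base[ord[seq_len(-k)]] <- base[ord[seq_len(-k)]] - 1
  }
  out <- base / 100
  names(out) <- names(weights)
  out
}

# Deterministic sub-stream seed so each generator is a pure function of
# (config, seed) yet different generators do not share a stream.
derive_seed <- function(seed, salt) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + (sum(utf8ToInt(salt)) %% 997L)
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single finite number %s %s.",
      name, if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}
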