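# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used at the
#' reporting layer for person counts and percentages. Internal arithmetic is
#' never rounded.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(36.5)   # 37, unlike round()'s banker's rounding
#' round_half_up(256.33) # 256
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Largest-remainder apportionment of an integer total
#'
#' Splits `total` across categories proportionally to `fractions`, rounding to
#' integers so the parts sum exactly to `total`. Each part gets the floor of
#' its exact share; leftover units go to the largest fractional remainders,
#' ties broken by position (first category wins).
#'
#' @param total non-negative integer to apportion.
#' @param fractions numeric vector of non-negative shares summing to 1
#'   (within 1e-9).
#' @return integer vector, same length as `fractions`, summing to `total`.
#' @examples
#' largest_remainder(7, c(0.5, 0.5)) # 4 3
#' @export
largest_remainder <- function(total, fractions) {
  if (total < 0 || abs(total - round(total)) > 1e-9) {
    qi_stop("`total` must be a non-negative integer", "qi_validation_error")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    qi_stop("`fractions` must be non-negative and sum to 1",
            "qi_validation_error")
  }
  total <- round(total)
  raw <- total * fractions
  base <- floor(raw)
  leftover <- total - sum(base)
  if (leftover > 0) {
    take <- order(-(raw - base), seq_along(raw))[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Signalling helpers: every package error carries class "qi_error" plus a
# specific subclass so callers can condition on the failure mode.
qi_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "qi_error")))
}

qi_warn <- function(msg, class = "qi_warning") {
  warning(warningCondition(msg, class = c(class, "qi_warning")))
}

# scalar checks used by constructors
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    qi_stop(sprintf("`%s` must be a single positive number", name),
            "qi_validation_error")
  }
  invisible(x)
}
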