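# Money is carried as integer cents stored in doubles (exact below 2^53).
# All proportional splits go through largest-remainder apportionment so that
# conservation identities hold to the cent, never approximately.

#' Convert US dollars to integer cents
#'
#' Amounts are carried internally as integer cents so that every accounting
#' identity (`Total = Sub + Ret`, `Ret = EC + NEC`, ...) can be asserted
#' exactly rather than to floating-point tolerance.
#'
#' @param usd Numeric vector of dollar amounts.
#' @return Numeric vector of integer cents (half-even rounding).
#' @export
#' @examples
#' as_cents(12.345) # 1234 (half-even)
as_cents <- function(usd) round(usd * 100)

#' Convert integer cents back to dollars
#' @param cents Numeric vector of integer cents.
#' @return Numeric vector of dollars.
#' @export
cents_to_usd <- function(cents) cents / 100

#' Convert integer cents to thousands of dollars
#' @param cents Numeric vector of integer cents.
#' @return Numeric vector in thousands of USD (the reporting unit).
#' @export
cents_to_thousands <- function(cents) cents / 1e5

#' Apportion an integer amount of cents across non-negative weights
#'
#' Largest-remainder (Hamilton) apportionment: each weight receives the floor
#' of its exact proportional share and the remaining cents go to the largest
#' fractional remainders, ties broken by position. The result always sums to
#' `total` exactly, which is what makes stratum-level proportional allocation
#' conserve money to the cent.
#'
#' @param total Non-negative integer number of cents to distribute.
#' @param weights Non-negative numeric weights, at least one positive.
#' @return Integer vector of cents, same length as `weights`, summing to
#'   `total`.
#' @export
#' @examples
#' apportion_cents(10, c(60, 40)) # 6 4
apportion_cents <- function(total, weights) {
  if (length(weights) == 0L) {
    abort("`weights` must have at least one element.",
          class = "copcost_error_empty_weights")
  }
  if (is.na(total) || total < 0) {
    abort("`total` must be a non-negative number of cents.",
          class = "copcost_error_bad_total")
  }
  if (any(is.na(weights)) || any(weights < 0)) {
    abort("`weights` must be non-negative and non-missing.",
          class = "copcost_error_bad_weights")
  }
  n <- length(weights)
  if (total == 0) return(rep(0, n))
  wsum <- sum(weights)
  if (wsum == 0) {
    abort("cannot apportion over all-zero weights.",
          class = "copcost_error_zero_weights")
  }
  exact <- total * (weights / wsum)
  base <- floor(exact)
  rem <- round(total - sum(base))
  if (rem > 0) {
    frac <- exact - base
    idx <- order(frac, decreasing = TRUE)[seq_len(min(rem, n))]
    base[idx] <- base[idx] + 1
    rem <- round(total - sum(base))
    if (rem != 0) base[which.max(weights)] <- base[which.max(weights)] + rem
  } else if (rem < 0) {
    # floating overshoot; take back from the largest shares
    idx <- order(base, decreasing = TRUE)[seq_len(min(-rem, n))]
    base[idx] <- base[idx] - 1
  }
  base
}
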