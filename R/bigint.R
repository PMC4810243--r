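# Exact non-negative big-integer arithmetic.
#
# Code-space counts (factorials of 20, 64-codon allocation counts) exceed
# the 2^53 exact-integer range of doubles, so counting is done on
# arbitrary-precision integers represented as little-endian digit vectors
# in base 1e4.  Only the operations the counting paths need are
# implemented: add, multiply, power, factorial, binomial (Pascal's rule,
# addition only), comparison and decimal rendering.

.BIG_BASE <- 10000L

#' Construct an exact big integer
#'
#' @param x non-negative integer-valued scalar (must be below 2^53), or a
#'   decimal digit string of any length.
#' @return object of class `bigint`.
#' @examples
#' big(20) * big("123456789012345678901234567890")
#' @export
big <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9]+$", x))
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    ends <- seq(n, 1, by = -4)  # chunk end positions, right to left
    digs <- vapply(ends, function(e)
      as.integer(substr(x, max(1L, e - 3L), e)), 1L)
    return(.big_trim(structure(digs, class = "bigint")))
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x),
            x < 2^53)
  d <- integer(0)
  repeat {
    d <- c(d, as.integer(x %% .BIG_BASE))
    x <- floor(x / .BIG_BASE)
    if (x == 0) break
  }
  structure(d, class = "bigint")
}

.big_trim <- function(a) {
  d <- unclass(a)
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  structure(d, class = "bigint")
}

.big_add <- function(a, b) {
  da <- unclass(a); db <- unclass(b)
  n <- max(length(da), length(db))
  da <- c(da, integer(n - length(da)))
  db <- c(db, integer(n - length(db)))
  s <- da + db
  carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% .BIG_BASE
    s[i] <- s[i] %% .BIG_BASE
  }
  if (carry > 0L) s <- c(s, carry)
  structure(as.integer(s), class = "bigint")
}

.big_mul <- function(a, b) {
  da <- as.double(unclass(a)); db <- as.double(unclass(b))
  if ((length(da) == 1L && da == 0) || (length(db) == 1L && db == 0)) {
    return(big(0))
  }
  res <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    if (da[i] == 0) next
    res[i:(i + length(db) - 1L)] <-
      res[i:(i + length(db) - 1L)] + da[i] * db
    # keep partial sums well below 2^53: base^2 * 64 terms ~ 6.4e9, safe,
    # but normalise periodically for very long operands
    if (i %% 512L == 0L) {
      carry <- 0
      for (k in seq_along(res)) {
        res[k] <- res[k] + carry
        carry <- floor(res[k] / .BIG_BASE)
        res[k] <- res[k] %% .BIG_BASE
      }
      stopifnot(carry == 0)
    }
  }
  carry <- 0
  for (k in seq_along(res)) {
    res[k] <- res[k] + carry
    carry <- floor(res[k] / .BIG_BASE)
    res[k] <- res[k] %% .BIG_BASE
  }
  stopifnot(carry == 0)
  .big_trim(structure(as.integer(res), class = "bigint"))
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (.Generic %in% c("+", "*", "==", "<", ">", "<=", ">=", "!=")) {
    a <- big(e1); b <- big(e2)
    switch(.Generic,
      "+" = .big_add(a, b),
      "*" = .big_mul(a, b),
      "==" = .big_cmp(a, b) == 0L,
      "!=" = .big_cmp(a, b) != 0L,
      "<"  = .big_cmp(a, b) < 0L,
      ">"  = .big_cmp(a, b) > 0L,
      "<=" = .big_cmp(a, b) <= 0L,
      ">=" = .big_cmp(a, b) >= 0L)
  } else {
    stop("operation '", .Generic, "' not defined for bigint")
  }
}

.big_cmp <- function(a, b) {
  da <- unclass(.big_trim(a)); db <- unclass(.big_trim(b))
  if (length(da) != length(db)) {
    return(if (length(da) < length(db)) -1L else 1L)
  }
  for (i in rev(seq_along(da))) {
    if (da[i] != db[i]) return(if (da[i] < db[i]) -1L else 1L)
  }
  0L
}

#' Integer power of a big integer
#' @param a `bigint` or coercible.
#' @param k non-negative integer exponent.
#' @return `bigint`.
#' @export
big_pow <- function(a, k) {
  a <- big(a)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  out <- big(1)
  for (i in seq_len(k)) out <- .big_mul(out, a)
  out
}

#' Exact factorial
#' @param n non-negative integer.
#' @return `bigint`.
#' @export
big_factorial <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  out <- big(1)
  for (i in seq_len(n)) out <- .big_mul(out, big(i))
  out
}

#' Exact binomial coefficients via Pascal's rule
#'
#' Addition-only recurrence, so no division on big integers is needed.
#' @param n non-negative integer.
#' @return list of `n + 1` `bigint`s: choose(n, 0..n).
#' @export
big_choose_row <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  row <- list(big(1))
  if (n == 0L) return(row)
  for (r in seq_len(n)) {
    nxt <- vector("list", r + 1L)
    nxt[[1]] <- big(1); nxt[[r + 1L]] <- big(1)
    if (r > 1L) {
      for (k in 2:r) nxt[[k]] <- .big_add(row[[k - 1L]], row[[k]])
    }
    row <- nxt
  }
  row
}

#' Decimal string of a big integer
#' @param x a `bigint`.
#' @param ... unused.
#' @return character scalar.
#' @export
format.bigint <- function(x, ...) {
  d <- rev(unclass(.big_trim(x)))
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  s <- format(x)
  cat("<bigint> ", s, "  (~", big_sci(x), ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' Approximate double value of a big integer (may overflow to Inf)
#' @param x a `bigint`.
#' @param ... unused.
#' @export
as.double.bigint <- function(x, ...) {
  d <- as.double(unclass(x))
  sum(d * .BIG_BASE^(seq_along(d) - 1))
}

#' Scientific-notation rendering of a big integer
#'
#' Presentation layer only; the underlying value stays exact.
#' @param x `bigint`.
#' @param sig significant figures (default 2).
#' @return string like `"2.4e18"`.
#' @export
big_sci <- function(x, sig = 2L) {
  s <- format(big(x))
  expo <- nchar(s) - 1L
  mant <- as.numeric(paste0(substr(s, 1, 1), ".",
                            substr(s, 2, min(nchar(s), 17L))))
  mant <- signif(mant, sig)
  if (mant >= 10) {  # rounding pushed into the next decade
    mant <- mant / 10
    expo <- expo + 1L
  }
  paste0(format(mant, trim = TRUE), "e", expo)
}
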