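# Combinatorics of alternate genetic codes: the reception-seating model,
# reduction factors, multiplicative selection bookkeeping, and an
# exploratory codon-packet allocation counter.  All counting is exact.

#' Seating arrangements of the reception-seating model
#'
#' With `p` seating sections of `q` heads each (p*q guests), random seating
#' within the constraint that each affinity group occupies one section
#' admits exactly `p! * (q!)^p` arrangements.  One section of 20 guests
#' gives 20! (about 2.4e18); five sections of four give 955,514,880
#' (about 9.6e8) -- the collapse in admissible arrangements that the model
#' maps onto the pruning of alternate genetic codes by biosynthetic
#' affinity grouping.
#'
#' @param p number of seating sections (>= 1).
#' @param q heads per section (>= 1).
#' @return exact count as a [big()] integer.
#' @examples
#' format(seating_arrangements(1, 20))  # "2432902008176640000"
#' @export
seating_arrangements <- function(p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (is.na(p) || is.na(q) || p < 1L || q < 1L) {
    stop("p and q must be positive integers")
  }
  .big_mul(big_factorial(p), big_pow(big_factorial(q), p))
}

#' Reduction factor between two exact counts
#'
#' The exact rational `constrained / unconstrained`, kept as a numerator /
#' denominator pair of big integers and rendered in scientific notation at
#' a chosen number of significant figures for report parity with rounded
#' published prints (e.g. 955514880 / 20! = 3.93e-10, printed 4e-10 at one
#' significant figure).
#'
#' @param constrained,unconstrained exact counts ([big()] or coercible);
#'   `unconstrained` must be positive.
#' @param sig significant figures for rendering (default 2).
#' @return object of class `reduction_factor`: `numerator`, `denominator`
#'   (bigints), `value` (double approximation), `rendered` (string).
#' @export
reduction_factor <- function(constrained, unconstrained, sig = 2L) {
  num <- big(constrained); den <- big(unconstrained)
  if (den == big(0)) stop("zero denominator")
  value <- .big_ratio(num, den)
  structure(
    list(numerator = num, denominator = den, value = value,
         rendered = .sci_render(value, sig)),
    class = "reduction_factor")
}

# Double approximation of num/den robust to magnitudes beyond 1e308:
# compare decimal digit strings.
.big_ratio <- function(num, den) {
  sn <- format(num); sd <- format(den)
  if (sn == "0") return(0)
  mant <- function(s) as.numeric(paste0("0.", substr(s, 1, 15)))
  (mant(sn) / mant(sd)) * 10^(nchar(sn) - nchar(sd))
}

.sci_render <- function(x, sig) {
  if (x == 0) return("0")
  expo <- floor(log10(x))
  mant <- signif(x / 10^expo, sig)
  if (mant >= 10) {
    mant <- mant / 10; expo <- expo + 1
  }
  if (mant == 1) paste0("1e", expo)
  else paste0(format(mant, trim = TRUE), "e", expo)
}

#' @export
print.reduction_factor <- function(x, ...) {
  cat("<reduction_factor> ", x$rendered,
      "  (", format(x$numerator), " / ", format(x$denominator), ")\n",
      sep = "")
  invisible(x)
}

#' Combined selection from multiplicative factors
#'
#' Multiplies named selection factors exactly when each is an exact power
#' of ten times a small integer mantissa (the form in which such factors
#' are printed): coevolutionary subdivision 1e-11, error minimization
#' 1e-6 and stereochemical selection 4e-4 combine to exactly 4e-21.
#'
#' @param factors named numeric vector of positive factors.
#' @return list with `factors`, `mantissa`, `exponent` (product =
#'   mantissa * 10^exponent exactly), `product` (double), `rendered`.
#' @examples
#' combined_selection(c(coevolution = 1e-11, error_min = 1e-6,
#'                      stereochemistry = 4e-4))$rendered  # "4e-21"
#' @export
combined_selection <- function(factors) {
  stopifnot(is.numeric(factors), length(factors) >= 1L)
  if (any(factors <= 0)) stop("all selection factors must be positive")
  mant_total <- 1
  expo_total <- 0L
  for (f in factors) {
    e <- floor(log10(f))
    m <- f / 10^e
    m_int <- round(m, 9)
    if (abs(m_int - round(m_int)) > 1e-9) {
      stop("factor ", f, " is not an exact small-mantissa power of ten")
    }
    mant_total <- mant_total * round(m_int)
    expo_total <- expo_total + as.integer(e)
  }
  while (mant_total >= 10) {
    mant_total <- mant_total / 10
    expo_total <- expo_total + 1L
  }
  list(factors = factors, mantissa = mant_total, exponent = expo_total,
       product = mant_total * 10^expo_total,
       rendered = .sci_render(mant_total * 10^expo_total, 2L))
}

#' Count codon-packet allocations of codons to amino acids
#'
#' Exact number of ways to assign `n_codons` distinct codons to `n_aa`
#' distinct amino acids so that every amino acid receives between
#' `min_size` and `max_size` codons, by the big-integer recursion
#' `f(c, a) = sum_s choose(c, s) * f(c - s, a - 1)`.
#'
#' This is an exploratory counter for the verbal "1-6 codon packets to 20
#' amino acids" description of code space; the published order-of-magnitude
#' counts rest on a reception-seating model whose combinatorial details are
#' not restated here, and this distinct-codon count is not expected to
#' match them (documented in the methods vignette).
#'
#' @param n_codons,n_aa positive integers.
#' @param min_size,max_size per-amino-acid packet bounds; infeasible bounds
#'   (`n_aa * min_size > n_codons` or `n_aa * max_size < n_codons`) raise
#'   an error.
#' @return exact count as a [big()] integer.
#' @examples
#' format(packet_allocation_count(4, 2, 1, 3))  # "14"
#' @export
packet_allocation_count <- function(n_codons, n_aa, min_size, max_size) {
  n_codons <- as.integer(n_codons); n_aa <- as.integer(n_aa)
  min_size <- as.integer(min_size); max_size <- as.integer(max_size)
  stopifnot(n_codons >= 1L, n_aa >= 1L, min_size >= 0L,
            max_size >= min_size)
  if (n_aa * min_size > n_codons || n_aa * max_size < n_codons) {
    stop("infeasible packet bounds: ", n_aa, " amino acids x [",
         min_size, ",", max_size, "] codons cannot absorb ", n_codons,
         " codons")
  }
  # Pascal rows up to n_codons, computed once.
  choose_rows <- lapply(0:n_codons, big_choose_row)
  # f[c+1, a+1] = number of allocations of c codons to a amino acids.
  f <- matrix(list(NULL), n_codons + 1L, n_aa + 1L)
  f[[1L, 1L]] <- big(1)
  for (c in seq_len(n_codons)) f[[c + 1L, 1L]] <- big(0)
  for (a in seq_len(n_aa)) {
    for (c in 0:n_codons) {
      hi <- min(max_size, c)
      if (hi < min_size) {
        f[[c + 1L, a + 1L]] <- big(0)
        next
      }
      acc <- big(0)
      for (s in min_size:hi) {
        prev <- f[[c - s + 1L, a]]
        if (prev == big(0)) next
        acc <- .big_add(acc, .big_mul(choose_rows[[c + 1L]][[s + 1L]],
                                      prev))
      }
      f[[c + 1L, a + 1L]] <- acc
    }
  }
  f[[n_codons + 1L, n_aa + 1L]]
}
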