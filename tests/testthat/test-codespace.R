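# Exact combinatorics: big integers, seating model, reduction factors,
# selection bookkeeping, packet-allocation DP.

test_that("big-integer arithmetic agrees with doubles below 2^53", {
  set.seed(5)
  for (i in 1:30) {
    a <- sample.int(1e6, 1); b <- sample.int(1e6, 1)
    expect_equal(format(big(a) + big(b)), as.character(a + b))
    expect_equal(format(big(a) * big(b)),
                 sprintf("%.0f", as.double(a) * b))
  }
  expect_equal(format(big("00123")), "123")
  expect_true(big(10) > big(9))
  expect_true(big("100000000000000000000") > big(2^52))
})

test_that("factorials are exact (known decimal expansions)", {
  expect_equal(format(big_factorial(0)), "1")
  expect_equal(format(big_factorial(10)), "3628800")
  expect_equal(format(big_factorial(20)), "2432902008176640000")
  expect_equal(format(big_factorial(25)), "15511210043330985984000000")
  # doubles are exact up to 18!
  for (n in c(5, 12, 18)) {
    expect_equal(format(big_factorial(n)), sprintf("%.0f", factorial(n)))
  }
})

test_that("Pascal-row binomials match choose()", {
  for (n in c(0, 1, 7, 20)) {
    row <- big_choose_row(n)
    expect_equal(vapply(row, function(x) as.double(x), 1),
                 choose(n, 0:n))
  }
})

test_that("seating arrangements realise p!(q!)^p", {
  expect_equal(format(seating_arrangements(1, 20)), "2432902008176640000")
  expect_equal(format(seating_arrangements(5, 4)), "955514880")
  expect_equal(as.double(seating_arrangements(2, 2)), 8)  # 2! * (2!)^2
  for (n in c(3, 10, 25)) {
    expect_equal(format(seating_arrangements(1, n)),
                 format(big_factorial(n)))
  }
  expect_error(seating_arrangements(0, 4), "positive")
})

test_that("reduction factors render at the requested precision", {
  rf <- reduction_factor(seating_arrangements(5, 4),
                         seating_arrangements(1, 20), sig = 3)
  expect_equal(rf$value, 955514880 / 2432902008176640000,
               tolerance = 1e-12)
  expect_equal(rf$rendered, "3.93e-10")
  expect_equal(reduction_factor(seating_arrangements(5, 4),
                                seating_arrangements(1, 20),
                                sig = 1)$rendered, "4e-10")
  expect_equal(reduction_factor(big(7), big(7))$value, 1)
  expect_error(reduction_factor(big(1), big(0)), "zero denominator")
})

test_that("combined selection multiplies exact decimal factors", {
  cs <- combined_selection(c(subdivision = 1e-11, error_min = 1e-6,
                             stereo = 4e-4))
  expect_equal(cs$mantissa, 4)
  expect_equal(cs$exponent, -21L)
  expect_equal(cs$rendered, "4e-21")
  expect_equal(combined_selection(c(1, 1, 1))$product, 1)
  # survivors among 2e19 alternatives: order unity or below
  expect_lt(cs$product * 2e19, 1)
  expect_error(combined_selection(c(1e-3, -1)), "positive")
})

test_that("packet-allocation DP matches exhaustive enumeration", {
  # enumerate every assignment of c distinct codons to a distinct amino
  # acids; count those respecting per-amino-acid packet bounds
  brute <- function(n_c, n_a, lo, hi) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_a)), n_c)))
    counts <- vapply(seq_len(n_a), function(a) rowSums(grid == a),
                     numeric(nrow(grid)))
    counts <- matrix(counts, nrow = nrow(grid))
    sum(apply(counts >= lo & counts <= hi, 1, all))
  }
  for (n_c in c(1, 3, 5, 8)) {
    for (n_a in 1:4) {
      for (lo in 0:1) {
        hi <- 4L
        if (n_a * lo > n_c || n_a * hi < n_c) {
          expect_error(packet_allocation_count(n_c, n_a, lo, hi),
                       "infeasible")
          next
        }
        expect_equal(as.double(packet_allocation_count(n_c, n_a, lo, hi)),
                     brute(n_c, n_a, lo, hi),
                     info = sprintf("c=%d a=%d lo=%d", n_c, n_a, lo))
      }
    }
  }
  # closed forms
  expect_equal(format(packet_allocation_count(4, 2, 1, 3)), "14")
  expect_equal(format(packet_allocation_count(5, 5, 1, 1)), "120")
  expect_equal(as.double(packet_allocation_count(6, 3, 0, 6)), 3^6)
})

test_that("scientific rendering keeps the exact value intact", {
  x <- seating_arrangements(1, 20)
  expect_equal(big_sci(x, 2), "2.4e18")
  expect_equal(big_sci(big(955514880), 2), "9.6e8")
  # rendering is presentation-only: the exact digits are unchanged
  expect_equal(format(x), "2432902008176640000")
})
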