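# Base-difference statistics: edit-distance core, regions, matrices,
# alloacceptor index, group means.

test_that("delta of identical sequences is 0 and of a 1-sub pair is 1", {
  s <- random_dna(72, seed = 1)
  expect_equal(pairwise_delta(s, s)$delta, 0L)
  s2 <- mutate_at(s, 35, if (substr(s, 35, 35) == "A") "G" else "A")
  d <- pairwise_delta(s, s2)
  expect_equal(d$delta, 1L)
  expect_equal(d$aligned_length, 72L)
  expect_equal(d$normalized, 1 / 72)
})

test_that("delta equals an independent DP edit-distance oracle", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_dna(sample(40:90, 1))
    b <- random_dna(sample(40:90, 1))
    expect_equal(pairwise_delta(a, b)$delta,
                 as.integer(adist(a, b)))
  }
  # related pairs (mutated copies), where co-optimal paths are common
  for (i in 1:30) {
    a <- random_dna(72)
    b <- mutate_at(a, sample(72, 5), sample(c("A", "C", "G", "T"), 5,
                                            replace = TRUE))
    b <- paste0(substr(b, 1, 30), substr(b, 33, 72))  # 2-nt deletion
    expect_equal(pairwise_delta(a, b)$delta, as.integer(adist(a, b)))
  }
})

test_that("delta is a metric on sequences", {
  set.seed(7)
  for (i in 1:25) {
    x <- random_dna(sample(30:60, 1))
    y <- random_dna(sample(30:60, 1))
    z <- random_dna(sample(30:60, 1))
    dxy <- pairwise_delta(x, y)$delta
    dyz <- pairwise_delta(y, z)$delta
    dxz <- pairwise_delta(x, z)$delta
    expect_gte(dxy, 0L)
    expect_equal(dxy, pairwise_delta(y, x)$delta)   # symmetry
    expect_lte(dxz, dxy + dyz)                      # triangle inequality
  }
  expect_equal(pairwise_delta("ACGT", "ACGT")$delta, 0L)
  expect_gt(pairwise_delta("ACGT", "ACGA")$delta, 0L)
  expect_error(pairwise_delta("", "ACGT"), "empty")
})

test_that("region delta counts only in-region columns and partitions", {
  a <- make_gene(anticodon = "GAG", seed = 3)
  # two diffs inside the anticodon loop (34, 36), three in the stems
  b_seq <- mutate_at(a$sequence, 34, if (substr(a$sequence, 34, 34) == "T")
    "C" else "T")
  b_seq <- mutate_at(b_seq, 36, if (substr(a$sequence, 36, 36) == "T")
    "C" else "T")
  for (p in c(5, 12, 60)) {
    b_seq <- mutate_at(b_seq, p, if (substr(a$sequence, p, p) == "A")
      "C" else "A")
  }
  b <- trna_gene("Tst", "Leu", "TAG", b_seq, anticodon_start = 34L)
  full <- pairwise_delta(a, b)
  expect_equal(full$delta, 5L)
  loop <- region_delta(a, b, c(31, 39))
  expect_equal(loop$delta, 2L)
  rest_left <- region_delta(a, b, c(1, 30))$delta
  rest_right <- region_delta(a, b, c(40, full$aligned_length))$delta
  expect_equal(loop$delta + rest_left + rest_right, full$delta)
  # named anticodon-loop convenience region
  expect_equal(region_delta(a, b, "anticodon_loop")$delta, 2L)
  # identical sequences: zero anywhere
  expect_equal(region_delta(a, a, c(10, 20))$delta, 0L)
  expect_error(region_delta(a, b, c(0, 10)), "outside")
  expect_error(region_delta(a, b, c(1, 999)), "outside")
})

test_that("distance matrix is symmetric, zero-diagonal, consistent", {
  g1 <- make_gene(seed = 1)
  g2 <- trna_gene("Tst", "Leu", "TAG",
                  mutate_at(g1$sequence, 34, "T"), anticodon_start = 34L)
  g3 <- make_gene(aa = "Gly", anticodon = "GCC", seed = 99)
  dm <- distance_matrix(list(g1, g2, g3))
  expect_equal(dm$values, t(dm$values))
  expect_equal(diag(dm$values), setNames(rep(0, 3), dm$labels))
  expect_equal(dm$values[1, 2],
               pairwise_delta(g1, g2)$normalized)
  expect_equal(dm$values[1, 3],
               pairwise_delta(g1, g3)$normalized)
  expect_true(all(dm$values >= 0 & dm$values <= 1))
  expect_error(distance_matrix(list(g1, g2, g3),
                               labels = c("x", "x", "y")), "duplicate")
  expect_error(distance_matrix(list(g1)), "at least 2")
})

test_that("d_allo averages alloacceptor pairs and detects primitivity", {
  # identical sequences, different amino acids -> exactly 0
  s <- random_dna(72, seed = 5)
  ome0 <- trnaome("Zro", list(
    trna_gene("Zro", "Leu", "GAG", s),
    trna_gene("Zro", "Gly", "GCC", s)))
  r0 <- d_allo(ome0)
  expect_equal(r0$d_allo, 0)
  expect_equal(r0$n_pairs, 1L)

  # single alloacceptor pair: d_allo = that pair's normalized distance
  s2 <- mutate_at(s, 1:18, rep(c("A", "C"), 9))
  ome1 <- trnaome("One", list(
    trna_gene("One", "Leu", "GAG", s),
    trna_gene("One", "Gly", "GCC", s2)))
  expect_equal(d_allo(ome1)$d_allo,
               pairwise_delta(s, s2)$normalized)

  # monotone non-decreasing under incrementally substituting fresh
  # positions of one gene away from the other gene's base
  prev <- 0
  mut <- s
  s_vec <- strsplit(s, "")[[1]]
  for (p in seq(2, 70, by = 6)) {
    alt <- setdiff(c("A", "C", "G", "T"),
                   c(s_vec[p], substr(mut, p, p)))[1]
    mut <- mutate_at(mut, p, alt)
    ome <- trnaome("Mon", list(
      trna_gene("Mon", "Leu", "GAG", s),
      trna_gene("Mon", "Gly", "GCC", mut)))
    cur <- d_allo(ome)$d_allo
    expect_gte(cur + 1e-12, prev)
    prev <- cur
  }

  # copies excluded by default, included on request
  ome2 <- trnaome("Cpy", list(
    trna_gene("Cpy", "Leu", "GAG", s),
    trna_gene("Cpy", "Leu", "GAG", s2, copy_index = 2L),
    trna_gene("Cpy", "Gly", "GCC", s2)))
  expect_equal(d_allo(ome2)$n_pairs, 1L)
  expect_equal(d_allo(ome2, include_copies = TRUE)$n_pairs, 2L)

  expect_error(d_allo(trnaome("Bad", list(
    trna_gene("Bad", "Leu", "GAG", s)))), "fewer than 2")
})

test_that("group mean delta is the arithmetic mean of raw counts", {
  s <- random_dna(60, seed = 11)
  mk <- function(k) mutate_at(s, seq_len(k), rep("A", k))
  # baseline may already have A at mutated sites; compute deltas honestly
  pairs <- list(list(s, mk(4)), list(s, mk(5)), list(s, mk(6)))
  want <- sapply(pairs, function(p) pairwise_delta(p[[1]], p[[2]])$delta)
  res <- group_mean_delta(pairs)
  expect_equal(res$mean_delta, mean(want))
  expect_equal(res$n, 3L)
  one <- group_mean_delta(list(list(s, mk(4))))
  expect_equal(one$mean_delta, want[1])
  expect_error(group_mean_delta(list()), "empty")
})
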