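# Fitch-Margoliash tree fitting: closed forms, additive recovery,
# exhaustive small-instance optimality, invariance, segregation reports.

test_that("three-taxon branch lengths match the closed form", {
  m <- sym_from_upper(3, c(0.2, 0.3, 0.4), c("A", "B", "C"))
  ft <- fit_tree(m)
  # a = (dAB + dAC - dBC)/2 etc.
  expect_equal(sort(ft$tree$edge.length), c(0.05, 0.15, 0.25),
               tolerance = 1e-9)
  expect_lt(ft$fit_score, 1e-18)
  expect_error(fit_tree(m[1:2, 1:2]), "at least 3")
  asym <- m; asym[1, 2] <- 0.21
  expect_error(fit_tree(asym), "symmetric")
})

test_that("additive matrices are recovered with zero residual", {
  cases <- list(
    list(nwk = "((A:1,B:2):1,(C:3,D:4):0);", tips = c("A", "B", "C", "D")),
    list(nwk = "(((A:.1,B:.2):.05,C:.3):.05,(D:.2,E:.1):.1);",
         tips = c("A", "B", "C", "D", "E")),
    list(nwk = "((A:.4,(B:.1,C:.1):.2):.1,(D:.3,(E:.2,F:.1):.1):.2);",
         tips = c("A", "B", "C", "D", "E", "F")))
  for (cs in cases) {
    m <- additive_matrix(cs$nwk, cs$tips)
    ft <- fit_tree(m)
    expect_lt(ft$fit_score, 1e-18)
    expect_lt(max(abs(tree_distances(ft) - m)), 1e-9)
  }
})

test_that("no exhaustively enumerated topology beats the fitted tree", {
  set.seed(101)
  grid <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  # rejection-sample grid-valued *metric* matrices so instances resemble
  # real normalized distances
  draw_metric <- function(n) {
    repeat {
      m <- sym_from_upper(n, sample(grid, choose(n, 2), replace = TRUE),
                          LETTERS[1:n])
      ok <- TRUE
      for (i in 1:(n - 1)) for (j in (i + 1):n) for (k in seq_len(n)) {
        if (k != i && k != j && m[i, j] > m[i, k] + m[k, j]) ok <- FALSE
      }
      if (ok) return(m)
    }
  }
  for (rep in 1:40) {
    n <- if (rep <= 30) 4L else 5L
    m <- draw_metric(n)
    ft <- fit_tree(m)
    topos <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = LETTERS[1:n])
    best <- min(vapply(topos, function(tp) fm_score(tp, m)$score, 1))
    expect_lte(ft$fit_score, best + 1e-9)
  }
})

test_that("result is invariant to input label order up to isomorphism", {
  m <- additive_matrix("((A:1,B:2):1,(C:3,D:4):0);", c("A", "B", "C", "D"))
  perm <- c("C", "A", "D", "B")
  f1 <- fit_tree(m)
  f2 <- fit_tree(m[perm, perm])
  expect_equal(newick_string(f1), newick_string(f2))
})

test_that("duplication pairs at delta = 1 come out as sisters", {
  # codon-box fixture: two genes one anticodon substitution apart, a third
  # isoacceptor ~10 substitutions away, an outgroup further still
  base <- random_dna(72, seed = 202)
  g1 <- base
  g2 <- mutate_at(base, 35, if (substr(base, 35, 35) == "A") "G" else "A")
  g3 <- mutate_at(base, seq(2, 42, by = 4),
                  rep(c("A", "T"), length.out = 11))
  g4 <- mutate_at(base, seq(1, 71, by = 3),
                  rep(c("C", "G"), length.out = 24))
  dm <- distance_matrix(list(g1, g2, g3, g4),
                        labels = c("dupA", "dupB", "iso3", "out"))
  ft <- fit_tree(dm)
  tight <- cluster_tightness(ft, list(pair = c("dupA", "dupB")))
  expect_true(tight$monophyletic)
  # the pair should be the closest leaves on the tree
  td <- tree_distances(ft)
  expect_equal(unname(td["dupA", "dupB"]), min(td[upper.tri(td)]))
})

test_that("segregated and interleaved groups are told apart", {
  m4 <- additive_matrix("((A1:1,A2:1):2,(B1:1,B2:1):2);",
                        c("A1", "A2", "B1", "B2"))
  ft <- fit_tree(m4)
  ct <- cluster_tightness(ft, list(A = c("A1", "A2"), B = c("B1", "B2")))
  expect_true(all(ct$monophyletic))
  ct2 <- cluster_tightness(ft, list(mixed1 = c("A1", "B1"),
                                    mixed2 = c("A2", "B2")))
  expect_false(any(ct2$monophyletic))
  expect_error(cluster_tightness(ft, list(g = c("A1", "nope"))), "unknown")
})

test_that("identical gene copies (zero distances) are handled", {
  m <- sym_from_upper(4, c(0, 0.5, 0.5, 0.5, 0.5, 0.2),
                      c("c1", "c2", "x", "y"))
  ft <- fit_tree(m)
  expect_true(all(ft$tree$edge.length >= 0))
  td <- tree_distances(ft)
  expect_lt(td["c1", "c2"], 0.1)
})
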