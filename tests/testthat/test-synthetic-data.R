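# Duplication-divergence generator: determinism, truth-record
# consistency, GC bias, depth contrasts.

test_that("generation is byte-identical for equal seeds", {
  cfg <- generator_config(seed = 17, depths = 5)
  a <- generate_trnaome(cfg)
  b <- generate_trnaome(cfg)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_trna_fasta(a$ome, fa); write_trna_fasta(b$ome, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- generate_trnaome(generator_config(seed = 18, depths = 5))
  expect_false(identical(a$ome, c2$ome))
})

test_that("a 0-sub duplication differs from its parent only in the anticodon", {
  cfg <- generator_config(seed = 3)
  res <- generate_trnaome(cfg)
  root <- res$ome$genes[[1]]   # Leu GAG
  dup <- res$ome$genes[[2]]    # Leu TAG, 0 extra subs, depth 0
  d <- pairwise_delta(root, dup)
  expect_equal(d$delta, 1L)
  expect_equal(region_delta(root, dup, c(34, 36))$delta, 1L)
})

test_that("truth record reconstructs every generated sequence", {
  cfg <- generator_config(seed = 23, depths = 2, background_sub_rate = 0.5)
  res <- generate_trnaome(cfg)
  anc <- strsplit(res$truth$ancestor, "")[[1]]
  win <- res$truth$anticodon_window
  # duplication copies the parent's pre-background sequence, so rebuild
  # the duplication-phase genealogy first, then lay background on top
  dup_phase <- list()
  for (i in seq_along(res$truth$genes)) {
    g <- res$truth$genes[[i]]
    s <- if (is.na(g$parent)) anc else dup_phase[[g$parent]]
    s[win] <- strsplit(g$anticodon, "")[[1]]
    if (nrow(g$dup_mut)) s[g$dup_mut$pos] <- g$dup_mut$to
    dup_phase[[i]] <- s
  }
  rebuilt <- list()
  for (i in seq_along(res$truth$genes)) {
    g <- res$truth$genes[[i]]
    s <- dup_phase[[i]]
    if (nrow(g$bg_mut)) s[g$bg_mut$pos] <- g$bg_mut$to
    rebuilt[[i]] <- s
    expect_equal(paste(s, collapse = ""), res$ome$genes[[i]]$sequence)
  }
  # delta recomputed from the truth sequences equals pairwise_delta:
  # an independent edit-distance oracle on the rebuilt sequences, and at
  # this sparse divergence also the plain per-position difference count
  for (i in 1:3) for (j in (i + 1):4) {
    si <- paste(rebuilt[[i]], collapse = "")
    sj <- paste(rebuilt[[j]], collapse = "")
    got <- pairwise_delta(res$ome$genes[[i]], res$ome$genes[[j]])$delta
    expect_equal(got, as.integer(adist(si, sj)))
    expect_equal(got, sum(rebuilt[[i]] != rebuilt[[j]]))
  }
})

test_that("background mutations reconstruct parent-independent lineages", {
  # depth 0: distances determined solely by anticodon rewrites + dup subs
  cfg <- generator_config(seed = 4, depths = 0)
  res <- generate_trnaome(cfg)
  expect_true(all(vapply(res$truth$genes,
                         function(g) nrow(g$bg_mut) == 0L, TRUE)))
})

test_that("ancestral GC content concentrates at the configured bias", {
  cfg <- generator_config(seed = 8, seq_length = 150)
  fracs <- vapply(1:60, function(i) {
    r <- generate_trnaome(generator_config(seed = i, seq_length = 150))
    anc <- strsplit(r$truth$ancestor, "")[[1]]
    mean(anc %in% c("G", "C"))
  }, 1)
  # 9000 positions at p = 0.7: tight binomial concentration
  expect_lt(abs(mean(fracs) - 0.7), 0.02)
})

test_that("substitution budget beyond free positions raises", {
  ev <- data.frame(parent = 1L, amino_acid = "Gly", anticodon = "GCC",
                   n_subs = 100L)
  cfg <- generator_config(seed = 1, duplication_events = ev)
  expect_error(generate_trnaome(cfg), "budget")
})

test_that("shallow-depth omes score lower d_allo than deep ones", {
  lower <- vapply(1:20, function(rep) {
    dc <- generate_domain_contrast(shallow_depth = 2, deep_depth = 20,
                                   n_species = 1, seed = 1000 + rep)
    d_allo(dc$shallow[[1]])$d_allo < d_allo(dc$deep[[1]])$d_allo
  }, TRUE)
  expect_true(all(lower))
})

test_that("d_allo recovers the generator's divergence ranking", {
  rates <- c(0.2, 0.6, 1.2, 2.5, 5)
  means <- vapply(rates, function(r) {
    mean(vapply(1:10, function(i) {
      cfg <- generator_config(seed = 300 + i, depths = 4,
                              background_sub_rate = r)
      d_allo(generate_trnaome(cfg)$ome)$d_allo
    }, 1))
  }, 1)
  expect_true(all(diff(means) > 0))
})

test_that("tree fitting recovers the duplication genealogy", {
  # deep outgroup family vs a tight delta=1 pair: the pair are sisters
  dc <- generate_domain_contrast(shallow_depth = 1, deep_depth = 15,
                                 n_species = 1, seed = 42)
  ome <- dc$shallow[[1]]
  dm <- distance_matrix(ome$genes)
  ft <- fit_tree(dm)
  labs <- dm$labels
  pair <- labs[1:2]   # root LeuCTC and its 0-sub duplicate LeuCTA
  ct <- cluster_tightness(ft, list(dup = pair))
  expect_true(ct$monophyletic)
})
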