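# Codon boxes, phase tables, chemical distances, contiguity statistic.

test_that("standard code box classification matches the canonical split", {
  bx <- classify_boxes()
  expect_equal(nrow(bx), 16L)
  one_aa <- bx$box[bx$box_class == "1aa"]
  expect_setequal(one_aa, c("CU", "GU", "UC", "CC", "AC", "GC", "CG", "GG"))
  two_aa <- bx$box[bx$box_class == "2aa-standard"]
  expect_setequal(two_aa, c("UU", "CA", "AA", "GA", "AG"))
  expect_equal(sum(bx$box_class == "other"), 3L)
  expect_equal(standard_box_count(), 13L)
})

test_that("a toy all-Gly code yields sixteen 1aa boxes", {
  toy <- standard_code()
  toy[] <- "Gly"
  bx <- classify_boxes(toy)
  expect_true(all(bx$box_class == "1aa"))
  expect_equal(standard_box_count(toy), 16L)
  expect_setequal(codon_domain(toy, "Gly"), names(toy))
})

test_that("amino-acid pair enumeration matches brute force", {
  expect_equal(amino_acid_pairs()$n_pairs, 190L)
  expect_equal(amino_acid_pairs(c("a", "b"))$n_pairs, 1L)
  six <- amino_acid_pairs(letters[1:6])
  expect_equal(six$n_pairs, 15L)
  # brute-force enumeration oracle
  brute <- sum(outer(1:6, 1:6, "<"))
  expect_equal(six$n_pairs, brute)
  expect_false(any(duplicated(apply(six$pairs, 1, paste, collapse = "-"))))
})

test_that("chemical distance extremes sit at Cys-Trp and Leu-Ile", {
  expect_equal(chemical_distance("Cys", "Trp"), 215)
  expect_equal(chemical_distance("Leu", "Ile"), 5)
  expect_equal(chemical_distance("Ala", "Ala"), 0)
  m <- grantham_matrix()
  expect_equal(m, t(m))
  off <- m[upper.tri(m)]
  expect_equal(max(off), 215)
  expect_equal(min(off), 5)
  expect_true(all(off > 0))
  expect_error(chemical_distance("Xyz", "Ala"), "non-canonical")
})

test_that("codon domains of the standard code are correct", {
  expect_setequal(codon_domain(aa = "Ser"),
                  c("UCU", "UCC", "UCA", "UCG", "AGU", "AGC"))
  expect_equal(codon_domain(aa = "Trp"), "UGG")
  expect_equal(codon_domain(aa = "Met"), "AUG")
  expect_error(codon_domain(aa = "Sec"), "not encoded")
})

test_that("phase table splits the twenty amino acids 10/10", {
  pt <- phase_table()
  p1 <- names(pt$phase)[pt$phase == 1L]
  expect_setequal(p1, c("Gly", "Ala", "Ser", "Asp", "Glu", "Val", "Leu",
                        "Ile", "Pro", "Thr"))
  expect_equal(sum(pt$phase == 2L), 10L)
  expect_setequal(pt$borderline, c("Pro", "Thr", "Phe", "Tyr"))
  expect_true(all(c("Ser", "Asp", "Glu") %in%
                    pt$precursor_product_pairs$precursor))
})

test_that("contiguity observed count matches an exhaustive codon scan", {
  code <- standard_code()
  res <- contiguity_statistic(n_perm = 99, seed = 1)
  # independent all-codon-pairs scan
  scan_contig <- function(aa1, aa2) {
    d1 <- codon_domain(code, aa1); d2 <- codon_domain(code, aa2)
    for (x in d1) for (y in d2) {
      if (sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) == 1) {
        return(TRUE)
      }
    }
    FALSE
  }
  pairs <- default_contiguity_pairs()
  brute <- sum(mapply(scan_contig, pairs$precursor, pairs$product))
  expect_equal(res$observed, brute)
  expect_equal(res$observed, 4L)       # all four precursor-product pairs
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # Ser-Cys contiguity specifically (UCU vs UGU)
  expect_true(unname(res$per_pair["Ser-Cys"]))
})

test_that("self-pairs are dropped with a warning, unencoded raise", {
  expect_warning(
    res <- contiguity_statistic(pairs = data.frame(a = c("Ser", "Ser"),
                                                   b = c("Ser", "Cys")),
                                n_perm = 9, seed = 1),
    "self-pair")
  expect_equal(res$observed, 1L)
  expect_error(
    contiguity_statistic(pairs = data.frame(a = "Ser", b = "Sec"),
                         n_perm = 9, seed = 1),
    "not encoded")
})

test_that("permutation p-values are valid (conservative) under the null", {
  # pairs drawn uniformly at random: empirical p-value distribution must
  # be approximately uniform, i.e. P(p <= a) <= a (+ Monte Carlo slack)
  set.seed(99)
  pvals <- replicate(500, {
    aa <- sample(AMINO_ACIDS, 8)
    pairs <- data.frame(a = aa[1:4], b = aa[5:8])
    contiguity_statistic(pairs = pairs, n_perm = 199,
                         seed = sample.int(1e6, 1))$p_value
  })
  for (a in c(0.05, 0.25, 0.5)) {
    expect_lte(mean(pvals <= a), a + 0.06)
  }
  expect_gte(mean(pvals), 0.45)
})

test_that("code tables round-trip through TSV", {
  tf <- tempfile(fileext = ".tsv")
  write_code_tsv(standard_code(), tf)
  back <- read_code_tsv(tf)
  expect_equal(sort(names(back)), sort(names(standard_code())))
  expect_equal(back[names(standard_code())], standard_code())
})
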