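# Shared fixture builders for the suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal valid 72-nt gene with a chosen anticodon at position 34.
make_gene <- function(species = "Tst", aa = "Leu", anticodon = "GAG",
                      seq = NULL, copy = 1L, seed = 1L) {
  if (is.null(seq)) {
    set.seed(seed)
    s <- strsplit(random_dna(72), "")[[1]]
    s[34:36] <- strsplit(anticodon, "")[[1]]
    seq <- paste(s, collapse = "")
  }
  trna_gene(species, aa, anticodon, seq, copy_index = copy,
            anticodon_start = 34L)
}

# Mutate a sequence at given positions to fixed bases.
mutate_at <- function(seq, pos, to) {
  s <- strsplit(seq, "")[[1]]
  s[pos] <- to
  paste(s, collapse = "")
}

# Symmetric matrix from an upper-triangle vector (row-by-row).
sym_from_upper <- function(n, up, labels = LETTERS[seq_len(n)]) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- up[k]
      k <- k + 1L
    }
  }
  m
}

# Additive distance matrix induced by a Newick tree on its tips.
additive_matrix <- function(newick, tips) {
  tr <- ape::unroot(ape::read.tree(text = newick))
  m <- ape::cophenetic.phylo(tr)
  m[tips, tips]
}
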