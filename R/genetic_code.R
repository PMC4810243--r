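# Genetic-code tables: codon boxes, phase classification, chemical
# distances, codon domains and the codon-domain contiguity permutation test.

.RNA_BASES <- c("U", "C", "A", "G")

#' The standard genetic code as RNA codons to three-letter amino acids
#'
#' @return named character vector of length 64; names are RNA codons
#'   (`UUU` ... `GGG`), values are three-letter amino-acid names or
#'   `"Stop"`.
#' @export
standard_code <- function() {
  gc1 <- Biostrings::GENETIC_CODE
  codons <- chartr("T", "U", names(gc1))
  aa <- ifelse(gc1 == "*", "Stop", .AA1TO3[gc1])
  stats::setNames(unname(aa), codons)
}

.check_code <- function(code) {
  if (length(code) != 64L || is.null(names(code))) {
    stop("a genetic code must map exactly 64 named codons")
  }
  names(code) <- chartr("T", "U", toupper(names(code)))
  all64 <- as.vector(outer(outer(.RNA_BASES, .RNA_BASES, paste0),
                           .RNA_BASES, paste0))
  if (!setequal(names(code), all64)) stop("codon set is not the 64 triplets")
  code
}

#' Convert codons between RNA and DNA spelling
#'
#' Code tables here are RNA-style (`U`); gene names are DNA-style (`T`).
#' These converters are the only sanctioned crossing point -- nothing is
#' coerced silently.
#' @param x character vector of triplets.
#' @return character vector.
#' @export
codon_rna <- function(x) chartr("T", "U", toupper(x))

#' @rdname codon_rna
#' @export
codon_dna <- function(x) chartr("U", "T", toupper(x))

#' Read / write a genetic code as TSV (columns codon, assignment)
#' @param path file path.
#' @return for `read_code_tsv`, a named codon vector; for `write_code_tsv`,
#'   `path` invisibly.
#' @export
read_code_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  .check_code(stats::setNames(tab$assignment, tab$codon))
}

#' @rdname read_code_tsv
#' @param code named codon vector.
#' @export
write_code_tsv <- function(code, path) {
  code <- .check_code(code)
  utils::write.table(
    data.frame(codon = names(code), assignment = unname(code)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- codon boxes -------------------------------------------------------------

#' Classify the 16 codon boxes of a genetic code
#'
#' A codon box is the four codons sharing their first two bases.  A box is
#' `1aa` when all four codons encode one amino acid, `2aa-standard` when
#' they split 2 + 2 between exactly two amino acids with no stops, and
#' `other` otherwise.  The standard code has eight 1aa boxes, five
#' 2aa-standard boxes and three other boxes (the stop-containing UAN and
#' UGN boxes and the 3+1 AUN box).
#'
#' @param code genetic code as from [standard_code()].
#' @return data.frame with one row per box: `box` (first two bases),
#'   `codons` (comma-joined), `assignments` (comma-joined), `box_class`.
#' @export
classify_boxes <- function(code = standard_code()) {
  code <- .check_code(code)
  boxes <- as.vector(outer(.RNA_BASES, .RNA_BASES, paste0))
  rows <- lapply(boxes, function(b) {
    codons <- paste0(b, .RNA_BASES)
    aa <- unname(code[codons])
    cls <- if (!any(aa == "Stop") && length(unique(aa)) == 1L) {
      "1aa"
    } else if (!any(aa == "Stop") && length(unique(aa)) == 2L &&
               all(table(aa) == 2L)) {
      "2aa-standard"
    } else "other"
    data.frame(box = b, codons = paste(codons, collapse = ","),
               assignments = paste(aa, collapse = ","), box_class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Number of standard (1aa + 2aa) codon boxes of a code
#'
#' Thirteen for the standard code: the eight family boxes plus the five
#' evenly split two-amino-acid boxes.
#' @param code genetic code.
#' @return integer.
#' @export
standard_box_count <- function(code = standard_code()) {
  sum(classify_boxes(code)$box_class %in% c("1aa", "2aa-standard"))
}

#' Codon domain of an amino acid
#'
#' All codons a code assigns to one amino acid (e.g. serine's disconnected
#' UCN and AGY domains under the standard code).
#' @param code genetic code.
#' @param aa three-letter amino-acid name.
#' @return character vector of RNA codons.
#' @export
codon_domain <- function(code = standard_code(), aa) {
  code <- .check_code(code)
  out <- names(code)[code == aa]
  if (!length(out)) stop("amino acid not encoded: ", aa)
  out
}

# --- amino-acid pair enumeration and chemical distance -----------------------

#' Enumerate unordered pairs of amino acids
#'
#' The 20 canonical amino acids give choose(20, 2) = 190 pairs.
#' @param aas character vector of items (default the 20 amino acids).
#' @return list with `n_pairs` and a two-column `pairs` matrix in
#'   deterministic (lexicographic-by-input-order) order.
#' @export
amino_acid_pairs <- function(aas = AMINO_ACIDS) {
  stopifnot(length(aas) >= 2L, !anyDuplicated(aas))
  pr <- t(utils::combn(aas, 2L))
  colnames(pr) <- c("a", "b")
  list(n_pairs = nrow(pr), pairs = pr)
}

#' Grantham (1974) chemical distance between amino acids
#'
#' Symmetric lookup in the embedded 20 x 20 constants combining
#' composition, polarity and molecular volume.  The extremes over all 190
#' pairs are Cys-Trp (215, most dissimilar) and Leu-Ile (5, least).
#'
#' @param a,b three-letter amino-acid names (vectorised).
#' @return numeric distances.
#' @examples
#' chemical_distance("Cys", "Trp")  # 215
#' @export
chemical_distance <- function(a, b) {
  m <- grantham_matrix()
  if (!all(a %in% rownames(m)) || !all(b %in% rownames(m))) {
    stop("non-canonical amino acid")
  }
  m[cbind(a, b)]
}

#' The embedded Grantham (1974) distance matrix
#' @return symmetric 20 x 20 numeric matrix, zero diagonal, three-letter
#'   row/column names.
#' @export
grantham_matrix <- function() .GRANTHAM

# Upper-triangular constants in the order Ser, Arg, Leu, Pro, Thr, Ala,
# Val, Gly, Ile, Phe, Tyr, Cys, His, Gln, Asn, Lys, Asp, Glu, Met, Trp
# (the row order of the published table).
.GRANTHAM <- local({
  ord <- c("Ser", "Arg", "Leu", "Pro", "Thr", "Ala", "Val", "Gly", "Ile",
           "Phe", "Tyr", "Cys", "His", "Gln", "Asn", "Lys", "Asp", "Glu",
           "Met", "Trp")
  up <- c(
    110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46,
    121,  65,  80, 135, 177,
    102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,
     96,  54,  91, 101,
     98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172,
    138,  15,  61,
     38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,
     87, 147,
     58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81,
    128,
     64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
    109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
    135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
     21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
     22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
    194,  83,  99, 143,  85, 160, 122,  36,  37,
    174, 154, 139, 202, 154, 170, 196, 215,
     24,  68,  32,  81,  40,  87, 115,
     46,  53,  61,  29, 101, 130,
     94,  23,  42, 142, 174,
    101,  56,  95, 110,
     45, 160, 181,
    126, 152,
     67)
  m <- matrix(0, 20, 20, dimnames = list(ord, ord))
  k <- 1L
  for (i in 1:19) {
    for (j in (i + 1):20) {
      m[i, j] <- m[j, i] <- up[k]
      k <- k + 1L
    }
  }
  m[sort(ord), sort(ord)]
})

# --- phase classification ----------------------------------------------------

#' Phase 1 / Phase 2 classification of the encoded amino acids
#'
#' Under the coevolution view of code expansion, Phase 1 amino acids were
#' prebiotically sourced (Gly, Ala, Ser, Asp, Glu, Val, Leu, Ile, Pro,
#' Thr) and Phase 2 amino acids arose by biosynthesis from Phase 1
#' precursors (Phe, Tyr, Arg, His, Trp, Asn, Gln, Lys, Cys, Met).  Pro and
#' Thr are borderline Phase 1; Phe and Tyr borderline Phase 2 (annotation
#' only, phase stays binary).
#'
#' @return list with `phase` (named integer vector over the 20 amino
#'   acids), `borderline` (character vector), and
#'   `precursor_product_pairs` (data.frame of biosynthetic precursor to
#'   product conversions, including the tRNA-dependent ones involving
#'   Sec, Sep and fMet).
#' @export
phase_table <- function() {
  phase1 <- c("Gly", "Ala", "Ser", "Asp", "Glu", "Val", "Leu", "Ile",
              "Pro", "Thr")
  phase <- stats::setNames(ifelse(AMINO_ACIDS %in% phase1, 1L, 2L),
                           AMINO_ACIDS)
  pp <- data.frame(
    precursor = c("Ser", "Ser", "Ser", "Asp", "Glu", "Sep", "Met"),
    product   = c("Cys", "Trp", "Sec", "Asn", "Gln", "Cys", "fMet"),
    stringsAsFactors = FALSE)
  list(phase = phase,
       borderline = c("Pro", "Thr", "Phe", "Tyr"),
       precursor_product_pairs = pp)
}

#' Default precursor-product pairs for contiguity testing
#'
#' The subset of the biosynthetic precursor-product list whose members are
#' both canonically encoded (the tRNA-dependent conversions involving Sec,
#' Sep and fMet have no own codon domains in the 20-amino-acid tables).
#' @return two-column data.frame (`precursor`, `product`).
#' @export
default_contiguity_pairs <- function() {
  pp <- phase_table()$precursor_product_pairs
  pp[pp$precursor %in% AMINO_ACIDS & pp$product %in% AMINO_ACIDS, ,
     drop = FALSE]
}

# --- contiguity statistic ----------------------------------------------------

.codons_contiguous <- function(dom_a, dom_b) {
  for (x in dom_a) {
    xs <- strsplit(x, "")[[1]]
    for (y in dom_b) {
      if (sum(xs != strsplit(y, "")[[1]]) == 1L) return(TRUE)
    }
  }
  FALSE
}

# Symmetric amino-acid x amino-acid indicator: do the two codon domains
# contain a codon pair one base apart?  Computed once per code; label
# permutations then reduce to lookups.
.domain_contiguity <- function(code) {
  aas <- sort(unique(unname(code[code != "Stop"])))
  doms <- lapply(stats::setNames(aas, aas),
                 function(a) names(code)[code == a])
  n <- length(aas)
  C <- matrix(FALSE, n, n, dimnames = list(aas, aas))
  for (i in seq_len(n)) {
    for (j in i:n) {
      C[i, j] <- C[j, i] <- .codons_contiguous(doms[[i]], doms[[j]])
    }
  }
  C
}

#' Codon-domain contiguity of biosynthetically related amino acids
#'
#' A precursor-product amino-acid pair is *contiguous* under a code when
#' their codon domains contain at least one codon pair differing at exactly
#' one base (e.g. serine's UCU and cysteine's UGU).  The observed statistic
#' is the number of contiguous pairs in `pairs`.  Significance is assessed
#' against a permutation null that keeps the code's codon-domain partition
#' fixed and randomly reassigns the amino-acid labels over the domains
#' (stop codons do not participate), the standard code-randomization
#' construction.  Self-pairs are contiguous by definition and are dropped
#' with a warning.
#'
#' Note the source analyses describe the enrichment qualitatively; the
#' permutation formalization here is this package's own construction.
#'
#' @param code genetic code.
#' @param pairs two-column data.frame/matrix of amino-acid pairs; default
#'   [default_contiguity_pairs()].
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return list with `observed`, `per_pair` (named logical), `p_value`
#'   (add-one estimator), `n_perm`, `null_counts`.
#' @export
contiguity_statistic <- function(code = standard_code(),
                                 pairs = default_contiguity_pairs(),
                                 n_perm = 999L, seed = 1L) {
  code <- .check_code(code)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  stopifnot(nrow(pairs) >= 1L, n_perm >= 1L)
  self <- pairs[, 1] == pairs[, 2]
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair(s): contiguous by definition")
    pairs <- pairs[!self, , drop = FALSE]
    if (!nrow(pairs)) stop("no non-degenerate pairs left")
  }
  aas <- sort(unique(unname(code[code != "Stop"])))
  bad <- setdiff(unique(as.vector(pairs)), aas)
  if (length(bad)) {
    stop("pair member(s) not encoded by this code: ",
         paste(bad, collapse = ", "))
  }
  C <- .domain_contiguity(code)
  ia <- match(pairs[, 1], aas)
  ib <- match(pairs[, 2], aas)
  per_pair <- stats::setNames(C[cbind(ia, ib)],
                              paste(pairs[, 1], pairs[, 2], sep = "-"))
  observed <- sum(per_pair)
  null_counts <- integer(n_perm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_perm)) {
    # label x moves to domain perm[x]; pair (a, b) tests domains
    # (perm[a], perm[b]) of the fixed partition
    perm <- sample(length(aas))
    null_counts[r] <- sum(C[cbind(perm[ia], perm[ib])])
  }
  list(observed = observed, per_pair = per_pair,
       p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       n_perm = n_perm, null_counts = null_counts)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
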