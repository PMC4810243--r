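#' @useDynLib trnaome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical amino-acid naming -------------------------------------------------

#' Three-letter names of the 20 canonical amino acids
#'
#' Order follows the conventional alphabetical-by-three-letter listing used
#' throughout the package (pair enumeration, chemical-distance tables).
#' @export
AMINO_ACIDS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")

# Extended identities accepted in gene headers (annotations, not part of the
# 20-amino-acid code tables).
.AA_EXTENDED <- c(AMINO_ACIDS, "Sec", "Pyl", "iMet", "Sep", "fMet")

.AA1TO3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# Nucleotide utilities --------------------------------------------------------

#' Reverse complement of DNA strings
#'
#' Vectorised, DNA alphabet (`A`, `C`, `G`, `T`).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp_dna("GAG")  # "CTC"
#' @export
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT character in: ", paste(x[bad], collapse = ", "))
  }
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

.clean_seq <- function(s) {
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) {
    stop("sequence contains characters outside A/C/G/T/U")
  }
  s
}

# TRNAGene --------------------------------------------------------------------

#' Construct a tRNA gene record
#'
#' One tRNA gene: a species tag, the amino-acid identity, the anticodon
#' (stored DNA-style), and the gene sequence.  Gene labels in comparative
#' tRNAome figures conventionally use the *complementary codon* (the codon
#' read by the gene's anticodon, e.g. `LeuCTC` for anticodon `GAG`); the
#' object stores the anticodon and derives the complementary codon on demand,
#' so both conventions are available without strand ambiguity.
#'
#' @param species_code three-letter species tag (e.g. `"Mka"`).
#' @param amino_acid three-letter amino-acid name; the 20 canonical names
#'   plus `Sec`, `Pyl`, `iMet`, `Sep`, `fMet` are accepted.
#' @param anticodon three-letter DNA string (RNA input is converted).
#' @param sequence gene sequence over `A/C/G/T/U`, 50--150 nt; uppercased and
#'   `U` mapped to `T`.
#' @param copy_index positive integer distinguishing genes of identical
#'   identity within one tRNAome.
#' @param organelle_flag logical; `TRUE` for organellar genes.
#' @param anticodon_start optional 1-based position of the anticodon triplet
#'   within `sequence` (canonical tRNA numbering puts it at 34); `NA` when
#'   unannotated.
#' @return object of class `trna_gene`.
#' @examples
#' g <- trna_gene("Mka", "Ser", "GCT", strrep("ACGT", 18))
#' complementary_codon(g)  # "AGC"
#' @export
trna_gene <- function(species_code, amino_acid, anticodon, sequence,
                      copy_index = 1L, organelle_flag = FALSE,
                      anticodon_start = NA_integer_) {
  stopifnot(is.character(species_code), nchar(species_code) == 3L)
  if (!amino_acid %in% .AA_EXTENDED) {
    stop("unknown amino acid name: ", amino_acid)
  }
  anticodon <- chartr("U", "T", toupper(anticodon))
  if (!grepl("^[ACGT]{3}$", anticodon)) {
    stop("anticodon must be a triplet over A/C/G/T: ", anticodon)
  }
  sequence <- .clean_seq(sequence)
  if (nchar(sequence) < 50L || nchar(sequence) > 150L) {
    stop("gene sequence length ", nchar(sequence), " outside 50-150 nt")
  }
  copy_index <- as.integer(copy_index)
  stopifnot(copy_index >= 1L, is.logical(organelle_flag))
  structure(
    list(species_code = species_code, amino_acid = amino_acid,
         anticodon = anticodon, sequence = sequence,
         copy_index = copy_index, organelle_flag = organelle_flag,
         anticodon_start = as.integer(anticodon_start)),
    class = "trna_gene")
}

#' Complementary codon of a tRNA gene or anticodon
#'
#' The codon read by Watson-Crick pairing with the anticodon, i.e. its
#' reverse complement in the DNA alphabet.  This is the triplet used in
#' gene names of the comparative figures (`LeuCTC` reads codon `CUC` via
#' anticodon `GAG`).
#'
#' @param x a `trna_gene` or a character vector of anticodons.
#' @return character vector of codons (DNA-style).
#' @export
complementary_codon <- function(x) {
  if (inherits(x, "trna_gene")) x <- x$anticodon
  revcomp_dna(x)
}

#' Render the paper-style label of a gene
#'
#' `<species><AminoAcid><complementary codon>`, e.g. `"MkaSerAGC"` for the
#' Methanopyrus serine gene with anticodon `GCT`.
#' @param gene a `trna_gene`.
#' @return single string.
#' @export
gene_label <- function(gene) {
  stopifnot(inherits(gene, "trna_gene"))
  paste0(gene$species_code, gene$amino_acid, complementary_codon(gene))
}

#' Parse a paper-style gene label
#'
#' Inverse of [gene_label()]: splits `"MkaSerAGC"` into species code,
#' amino-acid name and complementary codon, and recovers the anticodon by
#' reverse complement.
#'
#' @param label string `<3-letter species><amino acid name><triplet>`.
#' @return list with `species_code`, `amino_acid`, `anticodon`,
#'   `complementary_codon`.
#' @export
parse_gene_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label,
    regexec("^([A-Za-z]{3})((?:[A-Z][a-z]{2,3})|(?:[fi]Met))([ACGTU]{3})$",
            label))[[1]]
  if (length(m) != 4L) {
    stop("malformed gene label: ", label)
  }
  aa <- m[3]
  if (!aa %in% .AA_EXTENDED) stop("unknown amino acid in label: ", label)
  codon <- chartr("U", "T", m[4])
  list(species_code = m[2], amino_acid = aa,
       anticodon = revcomp_dna(codon), complementary_codon = codon)
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s  anticodon %s  %d nt  copy %d\n",
              gene_label(x), x$anticodon, nchar(x$sequence), x$copy_index))
  invisible(x)
}

# TRNAome ---------------------------------------------------------------------

#' Construct a tRNAome: the tRNA gene set of one species
#'
#' @param species_code three-letter species tag shared by all genes.
#' @param genes list of [trna_gene()] objects.
#' @param domain_label `"Archaea"`, `"Bacteria"`, `"Eukarya"` or
#'   `"unspecified"`.
#' @return object of class `trnaome`.
#' @export
trnaome <- function(species_code, genes,
                    domain_label = c("unspecified", "Archaea", "Bacteria",
                                     "Eukarya")) {
  domain_label <- match.arg(domain_label)
  stopifnot(all(vapply(genes, inherits, TRUE, "trna_gene")))
  sp <- vapply(genes, `[[`, "", "species_code")
  if (length(genes) && any(sp != species_code)) {
    stop("all genes must share species_code ", species_code)
  }
  key <- vapply(genes, function(g)
    paste(g$amino_acid, g$anticodon, g$copy_index, sep = "|"), "")
  if (anyDuplicated(key)) {
    stop("duplicate (amino_acid, anticodon, copy_index) in tRNAome ",
         species_code)
  }
  structure(list(species_code = species_code, genes = genes,
                 domain_label = domain_label),
            class = "trnaome")
}

#' @export
print.trnaome <- function(x, ...) {
  cat(sprintf("<trnaome> %s (%s): %d genes, %d amino acids\n",
              x$species_code, x$domain_label, length(x$genes),
              length(unique(vapply(x$genes, `[[`, "", "amino_acid")))))
  invisible(x)
}

#' @export
length.trnaome <- function(x) length(x$genes)

#' Tabulate a tRNAome
#'
#' @param x a `trnaome`.
#' @param ... unused.
#' @return data.frame with one row per gene: species, amino acid, anticodon,
#'   complementary codon, copy index, length, sequence.
#' @export
as.data.frame.trnaome <- function(x, ...) {
  data.frame(
    species = x$species_code,
    aa = vapply(x$genes, `[[`, "", "amino_acid"),
    anticodon = vapply(x$genes, `[[`, "", "anticodon"),
    complementary_codon = vapply(x$genes, complementary_codon, ""),
    copy_index = vapply(x$genes, `[[`, 1L, "copy_index"),
    length = vapply(x$genes, function(g) nchar(g$sequence), 1L),
    sequence = vapply(x$genes, `[[`, "", "sequence"),
    stringsAsFactors = FALSE)
}
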