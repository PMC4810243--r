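# Pairwise base-difference statistics (delta) and the alloacceptor
# distance index of tRNAome primitivity.

.gene_seq <- function(x) {
  if (inherits(x, "trna_gene")) x$sequence else .clean_seq(x)
}

.gene_lab <- function(x, default) {
  if (inherits(x, "trna_gene")) gene_label(x) else default
}

#' Base-difference count between two tRNA gene sequences
#'
#' Delta is the unit-cost global alignment (Levenshtein) distance:
#' substitutions, insertions and deletions each count one.  For equal-length
#' sequences aligning without gaps this reduces to the Hamming distance, so
#' the hallmark duplication signature -- a single base difference in the
#' anticodon between isoacceptor genes -- scores delta = 1.  Ties among
#' co-optimal alignments are broken deterministically (substitution over
#' gap, then gap in `a` over gap in `b`), which fixes the column layout used
#' by [region_delta()].
#'
#' @param a,b `trna_gene` objects or raw DNA/RNA strings (non-empty).
#' @return object of class `delta_result`: list with `gene_a`, `gene_b`
#'   (labels), `delta`, `aligned_length`, `normalized`
#'   (= delta / aligned_length), and `alignment` (gapped strings plus
#'   per-column difference indicator and source coordinates).
#' @examples
#' pairwise_delta("ACGTACGT", "ACGAACGT")$delta  # 1
#' @export
pairwise_delta <- function(a, b) {
  sa <- .gene_seq(a); sb <- .gene_seq(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  al <- .align_edit_cpp(sa, sb)
  structure(
    list(gene_a = .gene_lab(a, "a"), gene_b = .gene_lab(b, "b"),
         delta = al$delta, aligned_length = al$aligned_length,
         normalized = al$delta / al$aligned_length,
         alignment = al),
    class = "delta_result")
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("<delta> %s vs %s: delta %d / %d columns (%.4f)\n",
              x$gene_a, x$gene_b, x$delta, x$aligned_length, x$normalized))
  invisible(x)
}

#' Region-restricted base-difference count
#'
#' Counts the difference columns of the optimal pairwise alignment whose
#' 1-based column indices fall inside `region` (inclusive interval on
#' alignment coordinates).  For any partition of the columns the regional
#' counts add up to the full delta.
#'
#' `region = "anticodon_loop"` selects the 7 columns centred on the aligned
#' anticodon of gene `a`, which requires `a` to carry an annotated
#' `anticodon_start`; otherwise pass an explicit `c(from, to)`.
#'
#' @param a,b as in [pairwise_delta()].
#' @param region integer interval `c(from, to)` in alignment columns, or
#'   `"anticodon_loop"`.
#' @return `delta_result` whose `delta` counts only in-region differences;
#'   `aligned_length` is the region width.
#' @export
region_delta <- function(a, b, region) {
  full <- pairwise_delta(a, b)
  al <- full$alignment
  if (identical(region, "anticodon_loop")) {
    if (!inherits(a, "trna_gene") || is.na(a$anticodon_start)) {
      stop("'anticodon_loop' region requires gene 'a' with an annotated ",
           "anticodon_start; pass an explicit interval instead")
    }
    centre_pos <- a$anticodon_start + 1L  # middle base of the triplet
    col <- match(centre_pos, al$pos_a)
    region <- c(col - 3L, col + 3L)
  }
  region <- as.integer(region)
  if (length(region) != 2L || region[1] > region[2]) {
    stop("region must be an interval c(from, to)")
  }
  if (region[1] < 1L || region[2] > al$aligned_length) {
    stop("region [", region[1], ",", region[2],
         "] outside alignment of length ", al$aligned_length)
  }
  idx <- region[1]:region[2]
  structure(
    list(gene_a = full$gene_a, gene_b = full$gene_b,
         delta = sum(al$diff[idx]),
         aligned_length = length(idx),
         normalized = sum(al$diff[idx]) / length(idx),
         region = region, alignment = al),
    class = "delta_result")
}

#' Normalized pairwise distance matrix for a set of genes
#'
#' Entry (i, j) is `pairwise_delta(i, j)$normalized`.  Labels default to
#' paper-style gene labels (with copy suffixes) in input order.
#'
#' @param genes list of `trna_gene` objects (>= 2) or character sequences.
#' @param labels optional character vector of unique labels.
#' @return object of class `dist_matrix`: list with `labels` and symmetric
#'   zero-diagonal `values` in `[0, 1]`.
#' @export
distance_matrix <- function(genes, labels = NULL) {
  n <- length(genes)
  if (n < 2L) stop("need at least 2 genes")
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      g <- genes[[i]]
      if (inherits(g, "trna_gene")) {
        lab <- gene_label(g)
        if (g$copy_index > 1L) lab <- paste0(lab, "_", g$copy_index)
        lab
      } else paste0("seq", i)
    }, "")
  }
  if (anyDuplicated(labels)) stop("duplicate labels in gene set")
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwise_delta(genes[[i]], genes[[j]])$normalized
      v[i, j] <- v[j, i] <- d
    }
  }
  structure(list(labels = labels, values = v), class = "dist_matrix")
}

#' Write a distance matrix as TSV (labels as first row and column)
#' @param d a `dist_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  stopifnot(inherits(d, "dist_matrix"))
  tab <- cbind(label = d$labels, as.data.frame(d$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alloacceptor distance index of a tRNAome
#'
#' D_allo is the mean normalized pairwise distance over all gene pairs that
#' accept *different* amino acids (alloacceptor pairs).  Lower values mean
#' the tRNAome's alloacceptor genes have diverged less since the duplication
#' events that spawned them -- the index of tRNAome primitivity.  The mean
#' over isoacceptor pairs (same amino acid) is reported alongside when such
#' pairs exist.
#'
#' Gene copies with `copy_index > 1` are excluded by default so that copy
#' number does not weight the mean; set `include_copies = TRUE` to keep them.
#'
#' @param ome a `trnaome` with at least two distinct amino acids.
#' @param include_copies logical.
#' @return object of class `allo_index`: `species_code`, `d_allo`,
#'   `n_pairs` (alloacceptor pairs used), `d_iso`, `n_iso_pairs`.
#' @export
d_allo <- function(ome, include_copies = FALSE) {
  stopifnot(inherits(ome, "trnaome"))
  genes <- ome$genes
  if (!include_copies) {
    genes <- Filter(function(g) g$copy_index == 1L, genes)
  }
  aas <- vapply(genes, `[[`, "", "amino_acid")
  if (length(unique(aas)) < 2L) {
    stop("tRNAome ", ome$species_code,
         " has fewer than 2 distinct amino acids")
  }
  n <- length(genes)
  allo <- iso <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      nd <- pairwise_delta(genes[[i]], genes[[j]])$normalized
      if (aas[i] == aas[j]) iso <- c(iso, nd) else allo <- c(allo, nd)
    }
  }
  structure(
    list(species_code = ome$species_code,
         d_allo = mean(allo), n_pairs = length(allo),
         d_iso = if (length(iso)) mean(iso) else NA_real_,
         n_iso_pairs = length(iso)),
    class = "allo_index")
}

#' @export
print.allo_index <- function(x, ...) {
  cat(sprintf("<allo_index> %s: D_allo %.3f (%d pairs)", x$species_code,
              x$d_allo, x$n_pairs))
  if (!is.na(x$d_iso)) cat(sprintf(", D_iso %.3f (%d)", x$d_iso,
                                   x$n_iso_pairs))
  cat("\n")
  invisible(x)
}

#' Mean raw delta over a list of gene pairs
#'
#' Arithmetic mean of unnormalized base-difference counts, the statistic
#' behind per-domain averages such as comparing Asp/Glu tRNA pair
#' separation across Archaea, Bacteria and Eukarya.
#'
#' @param pairs list of 2-element lists/vectors of `trna_gene` or sequences.
#' @return list with `mean_delta`, `n`, and the individual `deltas`.
#' @export
group_mean_delta <- function(pairs) {
  if (length(pairs) == 0L) stop("empty pair list")
  deltas <- vapply(pairs, function(p) {
    stopifnot(length(p) == 2L)
    pairwise_delta(p[[1]], p[[2]])$delta
  }, 1L)
  list(mean_delta = mean(deltas), n = length(deltas), deltas = deltas)
}
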