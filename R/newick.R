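# Deterministic Newick serialization.
#
# ape's writer emits children in internal edge-matrix order, which depends
# on the history of tree surgery; analyses here need byte-identical output
# for identical trees, so the writer canonicalises child order (by the
# lexicographically smallest leaf label in each subtree) before rendering.

#' Serialize a tree to a canonical Newick string
#'
#' Children of every node are ordered by the smallest leaf label in their
#' subtree, so isomorphic trees with identical branch lengths serialize to
#' identical bytes.
#'
#' @param tree an `ape::phylo` or an `fm_tree` from [fit_tree()].
#' @return single Newick string terminated by `;`.
#' @export
newick_string <- function(tree) {
  if (inherits(tree, "fm_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label))) {
    stop("tree has an unlabeled leaf")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  len <- tree$edge.length
  has_len <- !is.null(len)
  if (has_len && any(len < 0)) stop("negative branch length")
  # undirected adjacency; serialization re-roots at the internal node
  # adjacent to the lexicographically smallest leaf, so isomorphic trees
  # render identically regardless of their internal edge orientation
  E <- tree$edge
  nb <- vector("list", n + tree$Nnode)
  for (r in seq_len(nrow(E))) {
    l <- if (has_len) len[r] else NA_real_
    nb[[E[r, 1]]] <- rbind(nb[[E[r, 1]]], c(E[r, 2], l))
    nb[[E[r, 2]]] <- rbind(nb[[E[r, 2]]], c(E[r, 1], l))
  }
  anchor <- which(tree$tip.label == min(tree$tip.label))[1]
  root <- if (n == 1L) anchor else nb[[anchor]][1, 1]
  fmt <- function(x) sprintf("%.10g", x)
  render <- function(node, parent, elen) {
    kids <- nb[[node]]
    kids <- kids[is.na(parent) | kids[, 1] != parent, , drop = FALSE]
    if (node <= n && nrow(kids) == 0L) {  # leaf
      s <- tree$tip.label[node]
      key <- s
    } else {
      sub <- lapply(seq_len(nrow(kids)), function(r)
        render(kids[r, 1], node, kids[r, 2]))
      keys <- vapply(sub, `[[`, "", "key")
      o <- order(keys, method = "radix")
      s <- paste0("(", paste(vapply(sub[o], `[[`, "", "str"),
                             collapse = ","), ")")
      key <- min(keys)
    }
    if (has_len && !is.na(elen)) s <- paste0(s, ":", fmt(elen))
    list(str = s, key = key)
  }
  paste0(render(root, NA_integer_, NA_real_)$str, ";")
}

#' Write a tree to a Newick file
#'
#' Canonical serialization via [newick_string()]; identical trees produce
#' byte-identical files.
#'
#' @param tree `phylo` or `fm_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}
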