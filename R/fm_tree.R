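# Fitch-Margoliash least-squares distance trees.
#
# The criterion is the classic weighted least squares
#   S(T, b) = sum_{i<j} w_ij (d_ij - p_ij(T, b))^2 ,  w_ij = 1 / d_ij^2 ,
# where p_ij is the path length between leaves i and j on tree T with
# branch lengths b >= 0.  Branch lengths for a fixed topology are the
# non-negative least-squares solution; topology search is stepwise addition
# in input order followed by nearest-neighbour-interchange hill climbing.

# --- topology helpers over ape's phylo representation -----------------------

.star3 <- function(labels) {
  structure(list(edge = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                 Nnode = 1L, tip.label = labels),
            class = "phylo")
}

# Attach a new tip in the middle of edge `edge_row`; tips keep ids 1..n in
# label order, internal ids shift to stay above the tip range.
.attach_tip <- function(tree, edge_row, label) {
  n <- length(tree$tip.label)
  E <- tree$edge
  E[E > n] <- E[E > n] + 1L
  u <- E[edge_row, 1]; v <- E[edge_row, 2]
  w <- n + 1L + tree$Nnode + 1L
  E <- rbind(E[-edge_row, , drop = FALSE], c(u, w), c(w, v), c(w, n + 1L))
  structure(list(edge = E, Nnode = tree$Nnode + 1L,
                 tip.label = c(tree$tip.label, label)),
            class = "phylo")
}

# Logical tip membership of the subtree below each edge's child node.
.edge_splits <- function(tree) {
  n <- length(tree$tip.label)
  E <- tree$edge
  children <- split(E[, 2], E[, 1])
  below <- function(node) {
    if (node <= n) {
      out <- logical(n); out[node] <- TRUE; return(out)
    }
    kids <- children[[as.character(node)]]
    Reduce(`|`, lapply(kids, below))
  }
  t(vapply(E[, 2], below, logical(n)))  # rows = edges, cols = tips
}

# Pair x edge incidence matrix: A[p, e] = 1 iff edge e lies on the path
# between the pair's two leaves (i.e. its split separates them).
.design_matrix <- function(tree) {
  sp <- .edge_splits(tree)
  n <- ncol(sp)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  A <- matrix(0, nrow(pr), nrow(sp))
  for (e in seq_len(nrow(sp))) {
    A[, e] <- sp[e, pr[, 1]] != sp[e, pr[, 2]]
  }
  A
}

.pair_vector <- function(m) m[upper.tri(m)][order(
  which(upper.tri(m), arr.ind = TRUE)[, 1],
  which(upper.tri(m), arr.ind = TRUE)[, 2])]

# FM weights 1/d^2 with zero-distance handling: zero (or tiny) distances
# take the weight of the smallest nonzero distance, so identical gene
# copies do not produce infinite weights.
.fm_weights <- function(dv) {
  pos <- dv[dv > 0]
  floorv <- if (length(pos)) min(pos) else 1
  1 / pmax(dv, floorv)^2
}

# Non-negative weighted least-squares branch lengths + criterion value.
.fm_fit_lengths <- function(tree, dv, w) {
  A <- .design_matrix(tree)
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(A * sw, dv * sw)
  b <- fit$x
  resid <- dv - as.vector(A %*% b)
  list(lengths = b, score = sum(w * resid^2))
}

.check_dist <- function(d) {
  stopifnot(inherits(d, "dist_matrix") || is.matrix(d))
  if (inherits(d, "dist_matrix")) {
    v <- d$values; labels <- d$labels
  } else {
    v <- d
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-12) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(diag(v) != 0)) stop("distance matrix must have a zero diagonal")
  if (anyDuplicated(labels)) stop("duplicate labels")
  list(values = v, labels = labels)
}

# --- main fit ----------------------------------------------------------------

#' Fit an unrooted tree by the Fitch-Margoliash criterion
#'
#' Stepwise addition in input order builds an initial unrooted binary
#' topology; nearest-neighbour interchanges are then applied greedily until
#' no interchange lowers the weighted least-squares score.  Branch lengths
#' at every step are constrained non-negative.  For an exactly additive
#' matrix the generating topology and branch lengths are recovered with a
#' zero residual.
#'
#' @param d `dist_matrix` or a symmetric numeric matrix with a zero
#'   diagonal, at least 3 taxa.
#' @param nni logical; run the NNI improvement phase (default `TRUE`).
#' @return object of class `fm_tree`: list with `tree` (an `ape::phylo`
#'   with branch lengths), `fit_score` (weighted residual sum of squares)
#'   and `labels`.
#' @examples
#' m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' fit_tree(m)$tree$edge.length  # 0.05 0.15 0.25
#' @export
fit_tree <- function(d, nni = TRUE) {
  dd <- .check_dist(d)
  v <- dd$values; labels <- dd$labels
  n <- length(labels)
  if (n < 3L) stop("need at least 3 taxa")
  dv_full <- .pair_vector(v)
  w_full <- .fm_weights(dv_full)

  sub_dv <- function(k) {  # pair vector/weights for taxa 1..k
    vv <- v[seq_len(k), seq_len(k)]
    dv <- .pair_vector(vv)
    list(dv = dv, w = .fm_weights(dv))
  }

  tree <- .star3(labels[1:3])
  if (n > 3L) {
    for (k in 4:n) {
      s <- sub_dv(k)
      best <- NULL; best_score <- Inf
      for (e in seq_len(nrow(tree$edge))) {
        cand <- .attach_tip(tree, e, labels[k])
        sc <- .fm_fit_lengths(cand, s$dv, s$w)$score
        if (sc < best_score - 1e-15) {
          best <- cand; best_score <- sc
        }
      }
      tree <- best
    }
  }

  fit <- .fm_fit_lengths(tree, dv_full, w_full)
  if (nni && n > 3L) {
    repeat {
      nbrs <- phangorn::nni(tree)
      shared_tips <- attr(nbrs, "TipLabel")  # compressed multiPhylo
      improved <- FALSE
      for (cand in nbrs) {
        if (!length(cand$tip.label) && !is.null(shared_tips)) {
          cand$tip.label <- shared_tips
        }
        cand$tip.label <- as.character(cand$tip.label)
        cand <- .relabel_to_tip_order(cand, labels)
        f2 <- .fm_fit_lengths(cand, dv_full, w_full)
        if (f2$score < fit$score - 1e-12) {
          tree <- cand; fit <- f2; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  tree$edge.length <- fit$lengths
  structure(list(tree = tree, fit_score = fit$score, labels = labels),
            class = "fm_tree")
}

# Renumber a phylo's tips so tip id i carries labels[i]; the pair ordering
# of the design matrix assumes this correspondence.
.relabel_to_tip_order <- function(tree, labels) {
  perm <- match(tree$tip.label, labels)
  if (anyNA(perm)) stop("tree labels do not match distance labels")
  n <- length(labels)
  E <- tree$edge
  tip_rows <- E[, 2] <= n
  E[tip_rows, 2] <- perm[E[tip_rows, 2]]
  tree$edge <- E
  tree$tip.label <- labels
  tree
}

#' @export
print.fm_tree <- function(x, ...) {
  cat(sprintf("<fm_tree> %d leaves, FM score %.6g\n",
              length(x$labels), x$fit_score))
  cat(" ", newick_string(x), "\n")
  invisible(x)
}

#' Evaluate the Fitch-Margoliash score of a topology against a matrix
#'
#' Fits non-negative branch lengths for the given topology and returns the
#' weighted residual; used for exhaustive small-instance searches.
#'
#' @param tree `phylo` whose tip labels match `d`'s labels.
#' @param d `dist_matrix` or symmetric matrix.
#' @return list with `score` and `lengths`.
#' @export
fm_score <- function(tree, d) {
  dd <- .check_dist(d)
  tree$tip.label <- as.character(tree$tip.label)
  tree <- .relabel_to_tip_order(tree, dd$labels)
  dv <- .pair_vector(dd$values)
  .fm_fit_lengths(tree, dv, .fm_weights(dv))
}

#' Leaf-to-leaf path-length matrix of a fitted tree
#' @param x an `fm_tree`.
#' @return symmetric matrix of tree distances, labels in fit order.
#' @export
tree_distances <- function(x) {
  stopifnot(inherits(x, "fm_tree"))
  m <- ape::cophenetic.phylo(x$tree)
  m[x$labels, x$labels]
}

#' Group segregation on a fitted tree
#'
#' For each group of leaf labels, reports whether the group is monophyletic
#' in the unrooted sense (some branch of the tree splits exactly the group
#' from all other leaves) and the mean leaf-to-leaf path length within the
#' group.  Used to ask whether same-identity gene branches segregate into
#' clusters, as alloacceptor pairs do in the deeply diverged codon boxes.
#'
#' @param x an `fm_tree`.
#' @param label_groups named list of character vectors of leaf labels;
#'   groups must be disjoint.
#' @return data.frame with `group`, `n`, `monophyletic`, `mean_path`.
#' @export
cluster_tightness <- function(x, label_groups) {
  stopifnot(inherits(x, "fm_tree"), is.list(label_groups))
  labs <- x$labels
  all_members <- unlist(label_groups)
  if (anyDuplicated(all_members)) stop("groups must be disjoint")
  unknown <- setdiff(all_members, labs)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  sp <- .edge_splits(x$tree)
  coph <- tree_distances(x)
  out <- lapply(names(label_groups), function(nm) {
    g <- label_groups[[nm]]
    memb <- labs %in% g
    mono <- length(g) == 1L || length(g) == length(labs) - 1L ||
      any(apply(sp, 1, function(s) all(s == memb) || all(s == !memb)))
    mp <- if (length(g) > 1L) {
      sub <- coph[g, g]
      mean(sub[upper.tri(sub)])
    } else 0
    data.frame(group = nm, n = length(g), monophyletic = mono,
               mean_path = mp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
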