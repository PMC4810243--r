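# Seeded duplication-divergence simulator of tRNA-like gene families.
#
# The generative model mirrors the cluster-dispersion picture of tRNAome
# growth: a single GC-rich ancestral sequence spawns genes through
# duplication events that rewrite mainly the anticodon triplet, after
# which each gene accumulates background substitutions in proportion to
# its divergence depth.  Every mutation is recorded in a truth record so
# downstream statistics can be checked against the genealogy.

#' Configuration of the tRNAome generator
#'
#' @param seed integer RNG seed (Mersenne-Twister stream, pinned; equal
#'   seeds give byte-identical output).
#' @param seq_length gene length in nt (default 72, canonical tRNA gene
#'   length without introns).
#' @param gc_bias probability of G or C at each ancestral position
#'   (default 0.7, the GC-rich sequence-space origin of the model).
#' @param anticodon_start 1-based start of the anticodon triplet (default
#'   34, canonical tRNA numbering).
#' @param root_aa,root_anticodon identity of the root gene.
#' @param duplication_events data.frame with columns `parent` (gene index,
#'   root = 1), `amino_acid`, `anticodon` (DNA), `n_subs` (substitutions
#'   applied right after duplication, outside the anticodon).  Genes are
#'   numbered in event order starting after the root.  `NULL` gives the
#'   default six-gene, four-amino-acid genealogy with a delta = 1
#'   isoacceptor duplication pair.
#' @param background_sub_rate expected background substitutions per gene
#'   per unit depth (default 1).
#' @param depths per-gene divergence depths (recycled; default 0).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, seq_length = 72L, gc_bias = 0.7,
                             anticodon_start = 34L,
                             root_aa = "Leu", root_anticodon = "GAG",
                             duplication_events = NULL,
                             background_sub_rate = 1,
                             depths = 0) {
  if (is.null(duplication_events)) {
    duplication_events <- data.frame(
      parent = c(1L, 1L, 3L, 1L, 5L),
      amino_acid = c("Leu", "Gly", "Gly", "Ser", "Ser"),
      anticodon = c("TAG", "GCC", "TCC", "GGA", "GCT"),
      n_subs = c(0L, 2L, 0L, 2L, 2L),
      stringsAsFactors = FALSE)
  }
  stopifnot(seq_length >= 50L, seq_length <= 150L,
            gc_bias > 0, gc_bias < 1,
            anticodon_start >= 1L, anticodon_start + 2L <= seq_length,
            background_sub_rate >= 0, all(depths >= 0))
  n_genes <- nrow(duplication_events) + 1L
  stopifnot(all(duplication_events$parent >= 1L),
            all(duplication_events$parent < 1L + seq_len(nrow(duplication_events))))
  structure(
    list(seed = as.integer(seed), seq_length = as.integer(seq_length),
         gc_bias = gc_bias, anticodon_start = as.integer(anticodon_start),
         root_aa = root_aa, root_anticodon = root_anticodon,
         duplication_events = duplication_events,
         background_sub_rate = background_sub_rate,
         depths = rep_len(depths, n_genes)),
    class = "generator_config")
}

.with_pinned_rng <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  suppressWarnings(RNGkind("Mersenne-Twister", "Inversion", "Rejection"))
  set.seed(seed)
  expr
}

.draw_ancestor <- function(len, gc_bias) {
  gc <- stats::runif(len) < gc_bias
  b <- character(len)
  b[gc] <- sample(c("G", "C"), sum(gc), replace = TRUE)
  b[!gc] <- sample(c("A", "T"), sum(!gc), replace = TRUE)
  b
}

# Apply n uniform substitutions at distinct non-anticodon positions;
# returns the mutated vector plus a mutation table.
.mutate <- function(seqv, n, ac_window) {
  free <- setdiff(seq_along(seqv), ac_window)
  if (n > length(free)) {
    stop("substitution budget ", n, " exceeds ", length(free),
         " available positions")
  }
  if (n == 0L) {
    return(list(seq = seqv,
                mut = data.frame(pos = integer(), from = character(),
                                 to = character())))
  }
  pos <- sort(sample(free, n))
  from <- seqv[pos]
  to <- vapply(from, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), "")
  seqv[pos] <- to
  list(seq = seqv, mut = data.frame(pos = pos, from = from, to = unname(to),
                                    stringsAsFactors = FALSE))
}

# Phase A: ancestor + duplication cascade (no background divergence).
.grow_family <- function(cfg) {
  anc <- .draw_ancestor(cfg$seq_length, cfg$gc_bias)
  ac_win <- cfg$anticodon_start + 0:2
  genes <- list(list(aa = cfg$root_aa, anticodon = cfg$root_anticodon,
                     parent = NA_integer_, seq = {
                       s <- anc
                       s[ac_win] <- strsplit(cfg$root_anticodon, "")[[1]]
                       s
                     },
                     dup_mut = data.frame(pos = integer(),
                                          from = character(),
                                          to = character())))
  ev <- cfg$duplication_events
  for (i in seq_len(nrow(ev))) {
    par <- genes[[ev$parent[i]]]
    s <- par$seq
    s[ac_win] <- strsplit(ev$anticodon[i], "")[[1]]
    m <- .mutate(s, ev$n_subs[i], ac_win)
    genes[[i + 1L]] <- list(aa = ev$amino_acid[i],
                            anticodon = ev$anticodon[i],
                            parent = ev$parent[i], seq = m$seq,
                            dup_mut = m$mut)
  }
  list(ancestor = paste(anc, collapse = ""), genes = genes,
       ac_window = ac_win)
}

# Phase B: per-gene background substitutions, Poisson(rate * depth).
.add_background <- function(family, rate, depths) {
  for (i in seq_along(family$genes)) {
    n_bg <- stats::rpois(1L, rate * depths[i])
    n_bg <- min(n_bg, length(family$genes[[i]]$seq) - 3L)
    m <- .mutate(family$genes[[i]]$seq, n_bg, family$ac_window)
    family$genes[[i]]$seq <- m$seq
    family$genes[[i]]$bg_mut <- m$mut
  }
  family
}

.family_to_ome <- function(family, cfg, species_code, domain_label) {
  seen <- character()
  genes <- vector("list", length(family$genes))
  for (i in seq_along(family$genes)) {
    g <- family$genes[[i]]
    id <- paste(g$aa, g$anticodon, sep = "|")
    copy <- sum(seen == id) + 1L
    seen <- c(seen, id)
    genes[[i]] <- trna_gene(species_code, g$aa, g$anticodon,
                            paste(g$seq, collapse = ""), copy_index = copy,
                            anticodon_start = cfg$anticodon_start)
  }
  trnaome(species_code, genes, domain_label = domain_label)
}

#' Generate one synthetic tRNAome with its truth record
#'
#' @param cfg a [generator_config()].
#' @param species_code three-letter tag for the generated species.
#' @param domain_label domain annotation.
#' @return list with `ome` (a `trnaome`) and `truth`: the ancestor
#'   sequence, per-gene genealogy (`parent`, `anticodon`), and every
#'   duplication-phase and background mutation (position, from, to).
#' @export
generate_trnaome <- function(cfg, species_code = "Syn",
                             domain_label = "unspecified") {
  stopifnot(inherits(cfg, "generator_config"))
  .with_pinned_rng(cfg$seed, {
    family <- .grow_family(cfg)
    family <- .add_background(family, cfg$background_sub_rate, cfg$depths)
  })
  ome <- .family_to_ome(family, cfg, species_code, domain_label)
  truth <- list(ancestor = family$ancestor,
                anticodon_window = family$ac_window,
                genes = lapply(family$genes, function(g)
                  g[c("aa", "anticodon", "parent", "dup_mut", "bg_mut",
                      "seq")]))
  list(ome = ome, truth = truth)
}

#' Paired shallow- and deep-divergence tRNAome sets
#'
#' For each synthetic species one duplication genealogy is grown, then
#' background divergence is laid on top twice -- once at `shallow_depth`
#' and once at `deep_depth` -- giving paired tRNAome sets that differ only
#' in post-duplication divergence.  Shallow sets emulate primitivity
#' (recent dispersion, low alloacceptor distances); deep sets emulate
#' long-diverged lineages.
#'
#' @param shallow_depth,deep_depth divergence depths,
#'   `shallow_depth < deep_depth` (defaults 2 and 20: a 10x substitution
#'   budget contrast).
#' @param n_species number of synthetic species per set.
#' @param seed integer seed.
#' @param background_sub_rate substitutions per gene per depth unit.
#' @return list with `shallow`, `deep` (lists of `trnaome`) and `truths`.
#' @export
generate_domain_contrast <- function(shallow_depth = 2, deep_depth = 20,
                                     n_species = 5L, seed = 1L,
                                     background_sub_rate = 1) {
  stopifnot(shallow_depth < deep_depth, n_species >= 1L)
  codes <- paste0("S", letters[ceiling(seq_len(n_species) / 26)],
                  letters[(seq_len(n_species) - 1L) %% 26L + 1L])
  shallow <- deep <- vector("list", n_species)
  truths <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    cfg <- generator_config(seed = seed + i,
                            background_sub_rate = background_sub_rate)
    .with_pinned_rng(cfg$seed, {
      fam <- .grow_family(cfg)
      fam_s <- .add_background(fam, background_sub_rate,
                               rep(shallow_depth, length(fam$genes)))
      fam_d <- .add_background(fam, background_sub_rate,
                               rep(deep_depth, length(fam$genes)))
    })
    shallow[[i]] <- .family_to_ome(fam_s, cfg, codes[i], "unspecified")
    deep[[i]] <- .family_to_ome(fam_d, cfg, codes[i], "unspecified")
    truths[[i]] <- list(species = codes[i], ancestor = fam$ancestor)
  }
  names(shallow) <- names(deep) <- codes
  list(shallow = shallow, deep = deep, truths = truths)
}

#' Generate an anticodon-usage fixture for a wobble stage
#'
#' Builds a tRNAome whose per-box anticodon inventory realises the given
#' stage's first-base ensemble in every standard box of the code:
#' `{U}` for Stages I and V, `{G, U}` for II, `{G, U, C}` for III and
#' `{G, U, C, A}` for IV.  Stage V fixtures carry the organelle flag.
#'
#' @param stage `"I"`, `"II"`, `"III"`, `"IV"` or `"V"`.
#' @param code genetic code.
#' @param seed integer seed for the backbone sequences.
#' @param species_code species tag.
#' @return a `trnaome`.
#' @export
generate_wobble_fixture <- function(stage = c("I", "II", "III", "IV", "V"),
                                    code = standard_code(), seed = 1L,
                                    species_code = "Fix") {
  stage <- match.arg(stage)
  first_bases <- switch(stage,
                        I = "U", V = "U",
                        II = c("G", "U"),
                        III = c("G", "U", "C"),
                        IV = c("G", "U", "C", "A"))
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  boxes <- classify_boxes(code)
  std <- boxes$box[boxes$box_class %in% c("1aa", "2aa-standard")]
  genes <- list()
  .with_pinned_rng(seed, {
    for (b in std) {
      b1 <- substr(b, 1, 1); b2 <- substr(b, 2, 2)
      for (fb in first_bases) {
        codon <- paste0(b, comp[fb])           # codon read Watson-Crick
        aa <- unname(code[codon])
        if (aa == "Stop") next                 # cannot occur in std boxes
        anticodon <- codon_dna(paste0(fb, comp[b2], comp[b1]))
        backbone <- .draw_ancestor(72L, 0.7)
        backbone[34:36] <- strsplit(anticodon, "")[[1]]
        genes[[length(genes) + 1L]] <-
          trna_gene(species_code, aa, anticodon,
                    paste(backbone, collapse = ""),
                    organelle_flag = stage == "V", anticodon_start = 34L)
      }
    }
  })
  trnaome(species_code, genes)
}
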