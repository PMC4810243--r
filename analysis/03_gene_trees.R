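#!/usr/bin/env Rscript
# Fitch-Margoliash gene trees for the simulated families: do delta = 1
# duplication pairs sit as sisters, and do same-identity genes segregate
# by species at deep divergence?

suppressMessages(library(trnaome))
out <- "results"
shallow <- read_trna_fasta(file.path(out, "omes_shallow.fasta"))
deep <- read_trna_fasta(file.path(out, "omes_deep.fasta"))

fit_set <- function(set, tag) {
  genes <- unlist(lapply(set, `[[`, "genes"), recursive = FALSE)
  dm <- distance_matrix(genes)
  write_dist_tsv(dm, file.path(out, paste0("distances_", tag, ".tsv")))
  ft <- fit_tree(dm)
  write_newick(ft, file.path(out, paste0("tree_", tag, ".nwk")))
  list(dm = dm, ft = ft)
}

sh <- fit_set(shallow, "shallow")
dp <- fit_set(deep, "deep")
cat("FM fit scores: shallow", signif(sh$ft$fit_score, 3),
    "/ deep", signif(dp$ft$fit_score, 3), "\n")

# sisterhood of the per-species Leu duplication pairs in the shallow tree
pairs <- lapply(names(shallow), function(sp)
  paste0(sp, "Leu", c("CTC", "CTA")))
names(pairs) <- paste0(names(shallow), "_LeuPair")
ct <- cluster_tightness(sh$ft, pairs)
write.table(ct, file.path(out, "cluster_tightness_shallow.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sum(ct$monophyletic), "of", nrow(ct),
    "Leu duplication pairs are sisters in the shallow tree\n")

# species segregation in the deep tree
sp_groups <- lapply(names(deep), function(sp)
  vapply(deep[[sp]]$genes, function(g) {
    lab <- gene_label(g)
    if (g$copy_index > 1L) lab <- paste0(lab, "_", g$copy_index)
    lab
  }, ""))
names(sp_groups) <- names(deep)
ct2 <- cluster_tightness(dp$ft, sp_groups)
write.table(ct2, file.path(out, "cluster_tightness_deep.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sum(ct2$monophyletic), "of", nrow(ct2),
    "species form clean clusters in the deep tree;",
    "mean within-species path",
    round(mean(ct2$mean_path), 3), "\n")
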