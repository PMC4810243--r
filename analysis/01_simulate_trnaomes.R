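#!/usr/bin/env Rscript
# Simulate the study's synthetic tRNAomes: duplication-divergence families
# from a GC-rich ancestor, in paired shallow- and deep-divergence sets.
# Writes FASTA inputs for the downstream distance/tree analyses.

suppressMessages(library(trnaome))
out <- "results"
dir.create(out, showWarnings = FALSE)

contrast <- generate_domain_contrast(shallow_depth = 2, deep_depth = 20,
                                     n_species = 5, seed = 20260927)
write_trna_fasta(contrast$shallow, file.path(out, "omes_shallow.fasta"))
write_trna_fasta(contrast$deep, file.path(out, "omes_deep.fasta"))
write_trnaome_tsv(contrast$shallow, file.path(out, "omes_shallow.tsv"))
write_trnaome_tsv(contrast$deep, file.path(out, "omes_deep.tsv"))

cat("Simulated", length(contrast$shallow), "species x 6 genes per set\n")
cat("Each family: Leu (CTC/CTA), Gly (GGC/GGA), Ser (TCC/AGC) genes from\n")
cat("one ancestor; shallow set ~2 background substitutions per gene,\n")
cat("deep set ~20 (10x the substitution budget).\n")
cat("Wrote omes_shallow.fasta / omes_deep.fasta under", out, "\n")
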