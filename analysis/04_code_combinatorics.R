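#!/usr/bin/env Rscript
# Genetic-code bookkeeping: the reception-seating counts, the reduction
# and selection factors, the 190 amino-acid pairs with their chemical
# distance extremes, codon-box structure, and the codon-domain contiguity
# permutation test for biosynthetically related amino-acid pairs.

suppressMessages(library(trnaome))
out <- "results"
dir.create(out, showWarnings = FALSE)

single <- seating_arrangements(1, 20)
grouped <- seating_arrangements(5, 4)
rf_seating <- reduction_factor(grouped, single, sig = 1)
rf_codes <- reduction_factor(big("200000000"),
                             big("20000000000000000000"), sig = 1)
sel <- combined_selection(c(coevolution_subdivision = 1e-11,
                            error_minimization = 1e-6,
                            stereochemistry = 4e-4))

cat("Seating arrangements, one section of 20: ", big_sci(single), "\n")
cat("Seating arrangements, five sections of 4:", big_sci(grouped), "\n")
cat("Seating reduction factor:", rf_seating$rendered, "\n")
cat("Alternate-code reduction (2e8 / 2e19):", rf_codes$rendered, "\n")
cat("Combined selection (subdivision x error-min x stereochemistry):",
    sel$rendered, "\n")
cat("Expected surviving codes out of 2e19:",
    signif(sel$product * 2e19, 2), "(order unity or below)\n")

pr <- amino_acid_pairs()
d <- chemical_distance(pr$pairs[, 1], pr$pairs[, 2])
cat(pr$n_pairs, "amino-acid pairs; chemical distance max",
    max(d), paste0("(", paste(pr$pairs[which.max(d), ], collapse = "-"),
                   "),"),
    "min", min(d),
    paste0("(", paste(pr$pairs[which.min(d), ], collapse = "-"), ")\n"))

bx <- classify_boxes()
cat("Codon boxes:", sum(bx$box_class == "1aa"), "x 1aa,",
    sum(bx$box_class == "2aa-standard"), "x 2aa,",
    standard_box_count(), "standard boxes in total\n")

ct <- contiguity_statistic(n_perm = 9999, seed = 20260927)
cat("Codon-domain contiguity: ", ct$observed, "of",
    length(ct$per_pair), "precursor-product pairs one base apart;",
    "permutation p =", signif(ct$p_value, 3), "\n")

# exploratory distinct-codon packet count (different model from the
# published reception-seating order of magnitude; see methods vignette)
pk <- packet_allocation_count(64, 20, 1, 6)
cat("Distinct-codon 1-6-packet allocations (exploratory):",
    big_sci(pk), "\n")

report <- list(
  seating_single = big_sci(single), seating_grouped = big_sci(grouped),
  seating_reduction = rf_seating$rendered,
  code_reduction = rf_codes$rendered,
  combined_selection = sel$rendered,
  n_aa_pairs = pr$n_pairs, chem_max = max(d), chem_min = min(d),
  boxes_1aa = sum(bx$box_class == "1aa"),
  boxes_2aa = sum(bx$box_class == "2aa-standard"),
  standard_boxes = standard_box_count(),
  contiguity_observed = ct$observed, contiguity_p = ct$p_value,
  packet_allocations = big_sci(pk))
jsonlite::write_json(report, file.path(out, "code_combinatorics.json"),
                     auto_unbox = TRUE, pretty = TRUE)
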