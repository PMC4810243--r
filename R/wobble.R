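# Wobble-stage classification of anticodon usage per codon box.
#
# Stages of wobble evolution, by the first-anticodon-base classes a codon
# box employs:
#   I   {U}            superwobble, single UNN reads all four codons
#   II  {G, U}         the anticodon-duo of primitive Archaea (Mka)
#   III {G, U, C}      the trio used by the majority of Archaea
#   IV  contains A(I)  the INN-extended ensemble of Bacteria and Eukarya
#   V   {U}            secondary single-UNN simplification in organelles
#                      and reduced bacterial genomes (1aa boxes)
# I and V share the same sequence signature; an organelle/reduced-genome
# hint disambiguates, otherwise the box is reported "I/V-ambiguous".

#' Per-box anticodon inventory of a tRNAome
#'
#' Maps each gene's anticodon to its Watson-Crick codon (the complementary
#' codon) and files it under that codon's box.  Only the code's standard
#' (1aa and 2aa) boxes are staged; non-standard boxes are reported
#' descriptively.
#'
#' @param ome a `trnaome`.
#' @param code genetic code (RNA codons).
#' @return object of class `wobble_inventory`: data.frame `boxes` with
#'   `box`, `box_class`, `anticodons` (comma-joined DNA anticodons),
#'   `first_bases` (comma-joined classes among G,U,C,A), `covered`.
#' @export
anticodon_inventory <- function(ome, code = standard_code()) {
  stopifnot(inherits(ome, "trnaome"))
  if (!length(ome$genes)) stop("empty tRNAome")
  boxes <- classify_boxes(code)
  acs <- unique(vapply(ome$genes, `[[`, "", "anticodon"))
  codons <- codon_rna(revcomp_dna(acs))
  box_of <- substr(codons, 1, 2)
  rows <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes$box[i]
    in_box <- acs[box_of == b]
    fb <- unique(substr(chartr("T", "U", in_box), 1, 1))
    fb <- fb[order(match(fb, c("G", "U", "C", "A")))]
    data.frame(box = b, box_class = boxes$box_class[i],
               anticodons = paste(sort(in_box), collapse = ","),
               first_bases = paste(fb, collapse = ","),
               covered = length(in_box) > 0L, stringsAsFactors = FALSE)
  })
  structure(list(species_code = ome$species_code,
                 boxes = do.call(rbind, rows)),
            class = "wobble_inventory")
}

# Stage of one box from its set of first-anticodon-base classes.
.box_stage <- function(first_bases, organelle_hint = NA) {
  fb <- sort(first_bases)
  if (!length(fb)) return(NA_character_)
  if ("A" %in% fb) return("IV")
  if (identical(fb, "U")) {
    if (isTRUE(organelle_hint)) return("V-candidate")
    if (identical(organelle_hint, FALSE)) return("I")
    return("I/V-ambiguous")
  }
  if (identical(fb, c("G", "U"))) return("II")
  if (identical(fb, c("C", "G", "U"))) return("III")
  "nonstandard"
}

# Monotone severity index used by the ordering property: staged sets map
# to their stage number, other combinations to their class count.
.stage_index <- function(first_bases) {
  st <- .box_stage(first_bases, organelle_hint = FALSE)
  switch(st,
         "I" = 1L, "II" = 2L, "III" = 3L, "IV" = 4L,
         length(first_bases))
}

#' Classify a tRNAome's wobble profile into Stages I-V
#'
#' @param inventory a `wobble_inventory` from [anticodon_inventory()].
#' @param organelle_hint `TRUE` for organellar / reduced genomes (single-U
#'   boxes become Stage V candidates), `FALSE` for cellular genomes
#'   (Stage I), `NA` to report the ambiguity.
#' @return object of class `wobble_profile`: per-box data.frame (`box`,
#'   `box_class`, `first_bases`, `stage`) plus an organism summary with
#'   `modal_stage`, `uniform` (one stage across all covered standard
#'   boxes), `n_standard_covered`, and `organism_label`
#'   (`"Mka-like primitive Archaea"` for a uniform Stage II profile).
#' @export
classify_wobble <- function(inventory, organelle_hint = NA) {
  stopifnot(inherits(inventory, "wobble_inventory"))
  bx <- inventory$boxes
  if (!any(bx$covered)) stop("empty anticodon inventory")
  std <- bx$box_class %in% c("1aa", "2aa-standard")
  stage <- rep(NA_character_, nrow(bx))
  for (i in which(std & bx$covered)) {
    fb <- strsplit(bx$first_bases[i], ",")[[1]]
    stage[i] <- .box_stage(fb, organelle_hint)
  }
  stage[!std & bx$covered] <- "non-standard box"
  bx$stage <- stage
  staged <- stage[std & bx$covered]
  modal <- if (length(staged)) {
    tab <- table(staged)
    names(tab)[which.max(tab)]
  } else NA_character_
  uniform <- length(unique(staged)) == 1L && length(staged) > 0L
  label <- if (uniform && identical(unique(staged), "II")) {
    "Mka-like primitive Archaea"
  } else NA_character_
  structure(
    list(species_code = inventory$species_code, boxes = bx,
         modal_stage = modal, uniform = uniform,
         n_standard_covered = sum(std & bx$covered),
         organism_label = label),
    class = "wobble_profile")
}

#' @export
print.wobble_profile <- function(x, ...) {
  cat(sprintf("<wobble_profile> %s: modal stage %s, %s, %d standard boxes covered\n",
              x$species_code, x$modal_stage,
              if (x$uniform) "uniform" else "mixed", x$n_standard_covered))
  if (!is.na(x$organism_label)) cat("  ", x$organism_label, "\n")
  invisible(x)
}

#' TSV export of a wobble profile's per-box table
#' @param profile a `wobble_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wobble_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "wobble_profile"))
  utils::write.table(profile$boxes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
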