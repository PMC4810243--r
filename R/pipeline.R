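# End-to-end analysis pipeline: FASTA -> distances -> tree -> cluster
# report + alloacceptor index + wobble profile, with a reproducibility
# manifest.

#' Run the comparative tRNAome pipeline on a FASTA input
#'
#' Reads tRNA gene sets, computes the normalized pairwise distance matrix
#' over all genes, fits the Fitch-Margoliash tree, scores per-species
#' cluster tightness, computes each species' alloacceptor index (when it
#' has two or more amino acids) and wobble profile, and writes five
#' outputs under `out_dir`:
#' `distances.tsv`, `tree.nwk`, `dallo.tsv`, `wobble.tsv`, and
#' `manifest.json` (package version, seed, input checksum, output
#' checksums).  Any stage failure aborts and removes partial outputs.
#'
#' @param input_fasta FASTA of tRNA genes (paper-label headers).
#' @param out_dir output directory, created if needed.
#' @param header_dialect passed to [read_trna_fasta()].
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input was generated).
#' @param include_copies passed to [d_allo()].
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(input_fasta, out_dir,
                         header_dialect = "paperlabel", seed = 1L,
                         include_copies = FALSE) {
  if (!file.exists(input_fasta)) stop("input not found: ", input_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("distances.tsv", "tree.nwk", "dallo.tsv",
                                "wobble.tsv", "manifest.json"))
  names(paths) <- c("distances", "tree", "dallo", "wobble", "manifest")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  omes <- stage("read", read_trna_fasta(input_fasta, header_dialect))
  if (!length(omes)) stop("pipeline stage 'read' failed: no records")
  genes <- unlist(lapply(omes, `[[`, "genes"), recursive = FALSE)

  dm <- stage("distances", distance_matrix(genes))
  write_dist_tsv(dm, paths["distances"])

  tr <- stage("tree", {
    if (length(genes) >= 3L) fit_tree(dm) else NULL
  })
  if (!is.null(tr)) write_newick(tr, paths["tree"])

  dallo_tab <- stage("dallo", {
    rows <- lapply(omes, function(o) {
      aas <- unique(vapply(o$genes, `[[`, "", "amino_acid"))
      if (length(aas) < 2L) return(NULL)
      a <- d_allo(o, include_copies = include_copies)
      data.frame(species = a$species_code, d_allo = a$d_allo,
                 n_pairs = a$n_pairs, d_iso = a$d_iso,
                 n_iso_pairs = a$n_iso_pairs, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(dallo_tab, paths["dallo"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  wobble_tab <- stage("wobble", {
    rows <- lapply(omes, function(o) {
      pr <- classify_wobble(anticodon_inventory(o))
      cbind(species = o$species_code,
            pr$boxes[pr$boxes$covered, , drop = FALSE])
    })
    do.call(rbind, rows)
  })
  utils::write.table(wobble_tab, paths["wobble"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- paths[names(paths) != "manifest"]
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    package = "trnaome",
    version = as.character(utils::packageVersion("trnaome")),
    seed = seed,
    input = unname(input_fasta),
    input_md5 = unname(tools::md5sum(input_fasta)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  ok <- TRUE
  invisible(list(omes = omes, distances = dm, tree = tr,
                 dallo = dallo_tab, wobble = wobble_tab,
                 manifest = manifest, paths = paths))
}
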