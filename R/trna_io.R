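# FASTA input/output and tabular export for tRNA gene sets.

#' Read tRNA gene sets from a FASTA file
#'
#' Parses one FASTA file into one `trnaome` per species found.  Two header
#' dialects are supported and must be declared (unknown dialects fail rather
#' than guess):
#'
#' * `"paperlabel"` -- headers like `>MkaSerAGC`: three-letter species code,
#'   amino-acid name, then the *complementary codon* of the gene (figure
#'   naming convention); the anticodon is recovered by reverse complement.
#'   An optional `_<k>` suffix gives an explicit copy index.
#' * `"keyvalue"` -- headers of `key=value` pairs separated by whitespace,
#'   e.g. `>species=Mka aa=Ser anticodon=GCT copy=2 organelle=0`.
#'
#' Sequences are uppercased with `U` mapped to `T`.  Records repeating an
#' (amino acid, anticodon) identity within a species get consecutive copy
#' indices in file order.
#'
#' @param path FASTA file.
#' @param header_dialect `"paperlabel"` (default) or `"keyvalue"`.
#' @param domain_label domain annotation applied to every resulting tRNAome.
#' @return named list of `trnaome` objects (names = species codes), in
#'   order of first appearance.  An empty file yields an empty list with a
#'   warning.
#' @export
read_trna_fasta <- function(path, header_dialect = c("paperlabel", "keyvalue"),
                            domain_label = "unspecified") {
  header_dialect <- match.arg(header_dialect)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("no FASTA records in ", path)
    return(structure(list(), names = character()))
  }
  headers <- names(seqs)
  genes <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    h <- trimws(headers[i])
    fields <- tryCatch(
      .parse_header(h, header_dialect),
      error = function(e) stop("record ", i, " ('", h, "'): ",
                               conditionMessage(e), call. = FALSE))
    sq <- tryCatch(
      .clean_seq(as.character(seqs[[i]])),
      error = function(e) stop("record ", i, " ('", h, "'): ",
                               conditionMessage(e), call. = FALSE))
    genes[[i]] <- c(fields, list(sequence = sq))
  }
  species <- vapply(genes, `[[`, "", "species_code")
  out <- list()
  for (sp in unique(species)) {
    gl <- genes[species == sp]
    seen <- character()
    built <- vector("list", length(gl))
    for (k in seq_along(gl)) {
      g <- gl[[k]]
      id <- paste(g$amino_acid, g$anticodon, sep = "|")
      copy <- if (is.null(g$copy_index)) sum(seen == id) + 1L
              else g$copy_index
      seen <- c(seen, id)
      built[[k]] <- trna_gene(g$species_code, g$amino_acid, g$anticodon,
                              g$sequence, copy_index = copy,
                              organelle_flag = isTRUE(g$organelle_flag))
    }
    out[[sp]] <- trnaome(sp, built, domain_label = domain_label)
  }
  out
}

.parse_header <- function(h, dialect) {
  h <- sub("^>", "", h)
  if (dialect == "paperlabel") {
    h <- strsplit(h, "[ \t]")[[1]][1]  # ignore trailing comment
    copy <- NULL
    m <- regmatches(h, regexec("^(.*)_([0-9]+)$", h))[[1]]
    if (length(m) == 3L) {
      copy <- as.integer(m[3])
      h <- m[2]
    }
    p <- parse_gene_label(h)
    list(species_code = p$species_code, amino_acid = p$amino_acid,
         anticodon = p$anticodon, copy_index = copy, organelle_flag = FALSE)
  } else {
    kv <- strsplit(h, "[ \t;]+")[[1]]
    kv <- kv[nzchar(kv)]
    parts <- regmatches(kv, regexec("^([A-Za-z_]+)=(.+)$", kv))
    if (any(lengths(parts) != 3L)) stop("malformed key=value header")
    keys <- vapply(parts, `[`, "", 2)
    vals <- vapply(parts, `[`, "", 3)
    need <- c("species", "aa", "anticodon")
    if (!all(need %in% keys)) {
      stop("keyvalue header missing field(s): ",
           paste(setdiff(need, keys), collapse = ", "))
    }
    v <- function(k) vals[match(k, keys)]
    list(species_code = v("species"), amino_acid = v("aa"),
         anticodon = chartr("U", "T", toupper(v("anticodon"))),
         copy_index = if ("copy" %in% keys) as.integer(v("copy")) else NULL,
         organelle_flag = "organelle" %in% keys && v("organelle") %in%
           c("1", "TRUE", "true", "yes"))
  }
}

#' Write tRNAomes to FASTA
#'
#' Headers use the paper-label dialect, with `_<copy>` suffixes for copy
#' indices above 1, so [read_trna_fasta()] round-trips every field.
#'
#' @param omes a `trnaome` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trna_fasta <- function(omes, path) {
  if (inherits(omes, "trnaome")) omes <- list(omes)
  genes <- unlist(lapply(omes, `[[`, "genes"), recursive = FALSE)
  labels <- vapply(genes, function(g) {
    lab <- gene_label(g)
    if (g$copy_index > 1L) lab <- paste0(lab, "_", g$copy_index)
    lab
  }, "")
  x <- Biostrings::BStringSet(vapply(genes, `[[`, "", "sequence"))
  names(x) <- labels
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export a tRNAome table as TSV
#'
#' Columns: species, aa, anticodon, complementary_codon, length, sequence.
#' @param omes a `trnaome` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trnaome_tsv <- function(omes, path) {
  if (inherits(omes, "trnaome")) omes <- list(omes)
  tab <- do.call(rbind, lapply(omes, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
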