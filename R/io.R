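# Plain-text readers/writers for the pipeline's external interfaces.
# All tabular intermediates are TSV for diffability; no binary formats.

#' Write contigs to FASTA
#' @param contigs A data frame with `contig_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(setNames(contigs$sequence,
                                         contigs$contig_id))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read contigs from FASTA
#' @param path FASTA file.
#' @return A tibble `contig_id`, `sequence`, `length`.
#' @export
read_contigs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    contig_id = vapply(strsplit(names(x), " "), `[`, "", 1),
    sequence = unname(as.character(x)),
    length = Biostrings::width(x)
  )
}

#' Write proteins to FASTA (ids `<contig>_<orf_index>`)
#' @param proteins A data frame with `protein_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                        proteins$protein_id))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read proteins from FASTA
#' @param path FASTA file; ids are expected as `<contig>_<orf_index>`.
#' @return A tibble `protein_id`, `contig_id`, `orf_index`, `sequence`.
#' @export
read_proteins_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(x), " "), `[`, "", 1)
  tibble(
    protein_id = ids,
    contig_id = sub("_[0-9]+$", "", ids),
    orf_index = as.integer(sub("^.*_", "", ids)),
    sequence = unname(as.character(x))
  )
}

#' Write a tibble as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the package
#' @param path TSV file.
#' @return A tibble.
#' @export
read_tsv_file <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE,
                              check.names = FALSE))
}
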