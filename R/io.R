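#' Read ASVs from a FASTA file
#' @param path FASTA of nucleotide ASV sequences.
#' @return data.frame with columns `id`, `nt_seq`.
#' @export
read_asv_fasta <- function(path) {
  x <- readDNAStringSet(path)
  data.frame(id = names(x), nt_seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write ASVs to a FASTA file
#' @param asvs data.frame with `id`, `nt_seq`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_asv_fasta <- function(asvs, path) {
  writeXStringSet(DNAStringSet(stats::setNames(asvs$nt_seq, asvs$id)), path)
  invisible(path)
}

#' Read a feature-by-sample count table (TSV, first column = feature id)
#' @param path TSV path.
#' @return integer matrix with feature rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as TSV
#' @param counts matrix with feature rownames.
#' @param path output path.
#' @param id_col name of the feature-id column (default `feature`).
#' @return invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path, id_col = "feature") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read degenerate primers from a TSV (columns name, seq, orientation, head)
#' @param path TSV path.
#' @return named list of [degenerate_primer()] objects.
#' @export
read_primer_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "seq", "orientation") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i)
    degenerate_primer(df$name[i], df$seq[i], df$orientation[i],
                      head = if ("head" %in% names(df) && nzchar(df$head[i]))
                        df$head[i] else NULL))
  stats::setNames(out, df$name)
}
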