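# FASTA and TSV input/output.

#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased; any symbol outside A/C/G/T is rejected with an
#' error listing the offending sequence and positions.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (k in seq_along(seqs)) {
    ch <- strsplit(seqs[[k]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T"))
    if (length(bad) > 0L)
      stop(sprintf("sequence '%s': non-ACGT symbol(s) at position(s) %s (%s)",
                   names(seqs)[k], paste(head(bad, 10L), collapse = ", "),
                   paste(unique(ch[head(bad, 10L)]), collapse = ", ")))
  }
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write MEMs to a TSV file
#'
#' Graph MEMs (a \code{path} column is present) are written with columns
#' query_id, qstart, qend, path (node ids joined by \code{">"}), i, j,
#' length, mem_class; string MEMs with columns query_id, qstart, qend,
#' tstart, tend, length.
#'
#' @param mems a MEM data frame as returned by the finders.
#' @param path output file.
#' @export
write_mems_tsv <- function(mems, path) {
  cols <- if ("path" %in% names(mems))
    c("query_id", "qstart", "qend", "path", "i", "j", "length", "mem_class")
  else
    c("query_id", "qstart", "qend", "tstart", "tend", "length")
  if (!"query_id" %in% names(mems)) mems$query_id <- 1L
  write.table(mems[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
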