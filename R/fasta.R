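#' Read a protein FASTA file as a named character vector
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' Sequences are wrapped at 60 columns; output is byte-deterministic for a
#' given input.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    body <- gsub("(.{60})", "\\1\n", seqs[[i]])
    body <- sub("\n$", "", body)
    writeLines(c(paste0(">", names(seqs)[i]), body), con, sep = "\n")
  }
  invisible(path)
}
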