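#' Extract open reading frames from a nucleotide sequence
#'
#' Scans all six reading frames. Within each frame the codon string is split
#' at stop codons; every stop-free segment of at least `min_len` codons is
#' translated with the standard genetic code (sequence ends also delimit
#' segments, so terminal partial ORFs are reported). Segments whose
#' nucleotides contain `N` are skipped.
#'
#' @param genome Nucleotide sequence string over `{A,C,G,T,N}`
#'   (case-insensitive).
#' @param min_len Minimum ORF length in codons (amino acids).
#' @return Tibble with columns `strand` (`"+"`/`"-"`), `frame` (1-3),
#'   `start`, `end` (0-based half-open nucleotide coordinates on the
#'   reported strand) and `protein`.
#' @examples
#' extract_orfs("ATGAAATAA", min_len = 2)
#' @export
extract_orfs <- function(genome, min_len = 30L) {
  genome <- toupper(genome)
  if (grepl("[^ACGTN]", genome)) {
    pos <- regexpr("[^ACGTN]", genome)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(genome, pos, pos), pos))
  }
  code <- Biostrings::GENETIC_CODE
  strands <- list(
    "+" = genome,
    "-" = as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  )
  out <- list()
  for (strand in names(strands)) {
    s <- strands[[strand]]
    n <- nchar(s)
    for (frame in 1:3) {
      n_codons <- (n - frame + 1L) %/% 3L
      if (n_codons < 1) next
      starts <- frame + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, starts, starts + 2L)
      aa <- code[codons]                      # NA for codons containing N
      aa[is.na(aa)] <- "?"
      # segment boundaries: stops and sequence ends
      is_stop <- aa == "*"
      seg_id <- cumsum(is_stop)
      for (seg in split(seq_len(n_codons), seg_id)) {
        seg <- seg[!is_stop[seg]]
        if (length(seg) < min_len) next
        prot <- paste(aa[seg], collapse = "")
        if (grepl("?", prot, fixed = TRUE)) next
        out[[length(out) + 1L]] <- tibble::tibble(
          strand = strand, frame = frame,
          start = starts[seg[1]] - 1L,
          end = starts[seg[length(seg)]] + 2L,
          protein = prot
        )
      }
    }
  }
  if (!length(out))
    return(tibble::tibble(strand = character(), frame = integer(),
                          start = integer(), end = integer(),
                          protein = character()))
  dplyr::bind_rows(out)
}
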