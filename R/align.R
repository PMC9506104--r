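#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman (Gotoh) alignment. Returns the single optimal
#' local alignment, or `NULL` when no cell scores above zero (e.g. sequences
#' over disjoint residue sets with all-negative cross scores).
#'
#' @param query,subject Protein sequence strings (residues must be rows of
#'   the scheme's substitution matrix; an invalid residue raises an error
#'   naming its position).
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble with `raw_score`, `identity_pct` (identical
#'   aligned columns over all alignment columns, in percent), `length`
#'   (alignment columns), 0-based half-open spans `q_start`/`q_end`/
#'   `s_start`/`s_end`, and the gapped `aligned_query`/`aligned_subject`
#'   strings — or `NULL` when the optimal score is 0.
#' @examples
#' smith_waterman("HEAGAWGHEE", "PAWHEAE", scoring_scheme("BLOSUM50", 8, 8))
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme()) {
  mat <- scheme$matrix
  qi <- encode_protein(query, mat, "query")
  si <- encode_protein(subject, mat, "subject")
  res <- sw_align_cpp(qi, si, mat, scheme$gap_open, scheme$gap_extend)
  if (res$score == 0) return(NULL)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  ops <- res$ops
  aq <- character(length(ops)); as_ <- character(length(ops))
  i <- res$q_start; j <- res$s_start
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      i <- i + 1L; j <- j + 1L; aq[k] <- qc[i]; as_[k] <- sc[j]
    } else if (ops[k] == 1L) {
      i <- i + 1L; aq[k] <- qc[i]; as_[k] <- "-"
    } else {
      j <- j + 1L; aq[k] <- "-"; as_[k] <- sc[j]
    }
  }
  ident <- sum(aq == as_ & aq != "-")
  tibble::tibble(
    raw_score = as.integer(res$score),
    identity_pct = 100 * ident / length(ops),
    length = length(ops),
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    aligned_query = paste(aq, collapse = ""),
    aligned_subject = paste(as_, collapse = "")
  )
}

# Score-only Smith-Waterman, used by the search loop.
sw_score <- function(qi, si, scheme) {
  sw_score_cpp(qi, si, scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Convert a raw alignment score to a bit score
#'
#' Karlin-Altschul normalization: `S' = (lambda * S - ln K) / ln 2`, making
#' scores comparable across scoring systems and search-space sizes.
#'
#' @param raw_score Raw (substitution-matrix sum) local alignment score.
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Bit score (vectorized over `raw_score`).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$k_param)) / log(2)
}

#' Expected number of chance alignments at a bit score
#'
#' `E = m * n * 2^(-S')` for query length m and database length n: the
#' expected count of alignments of at least that bit score in a search of
#' that size against the random background model. Linear in `db_len`, so
#' doubling the database doubles E.
#'
#' @param bits Bit score.
#' @param query_len,db_len Positive lengths (residues) of the query and the
#'   searched database.
#' @return E-value (vectorized over `bits`).
#' @export
e_value <- function(bits, query_len, db_len) {
  stopifnot(query_len > 0, db_len > 0)
  query_len * db_len * 2^(-bits)
}

# BLAST-style finite-size correction: the expected span of a high-scoring
# alignment, l = ln(K m n) / H, is subtracted from the query and from each
# database sequence before the E-value is computed, so that short sequences
# do not overstate the usable search space. Floors keep lengths positive.
effective_lengths <- function(query_len, db_len, n_db_seqs, scheme) {
  l <- log(scheme$k_param * query_len * db_len) / scheme$h_param
  l <- max(l, 0)
  m_eff <- max(query_len - l, 1 / scheme$k_param)
  n_eff <- max(db_len - n_db_seqs * l, 1 / scheme$k_param)
  list(m = m_eff, n = n_eff)
}
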