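#' The 20-letter amino-acid alphabet
#'
#' Standard residues accepted in catalog and subject sequences; `X` is also
#' tolerated wherever a substitution matrix defines scores for it.
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.builtin_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  storage.mode(m) <- "integer"
  m
}

#' Build a protein scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters (lambda, K, H) used to convert raw local
#' alignment scores into bit scores and E-values. A gap of length k costs
#' `gap_open + k * gap_extend` (NCBI convention), so defaults 11/1 charge 12
#' for a single-residue gap. The default lambda = 0.267, K = 0.041 and
#' H = 0.14 are the standard gapped estimates for BLOSUM62 with 11/1
#' penalties.
#'
#' @param matrix Substitution matrix: `"BLOSUM62"`, `"BLOSUM50"`, or a
#'   symmetric integer matrix with residue dimnames (e.g. from
#'   [read_score_matrix()]).
#' @param gap_open Positive integer gap-opening cost.
#' @param gap_extend Positive integer per-residue gap-extension cost;
#'   must not exceed `gap_open`.
#' @param lambda,k_param,h_param Karlin-Altschul scale, prefactor and
#'   relative entropy (nats) for the chosen matrix/gap combination.
#' @return An object of class `scoring_scheme`.
#' @examples
#' sch <- scoring_scheme()
#' sch$matrix["W", "W"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267,
                           k_param = 0.041, h_param = 0.14) {
  if (is.character(matrix)) {
    name <- match.arg(matrix, c("BLOSUM62", "BLOSUM50", "BLOSUM80", "PAM250"))
    mat <- .builtin_matrix(name)
  } else {
    mat <- matrix
    storage.mode(mat) <- "integer"
    name <- "custom"
  }
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat)))
    stop("substitution matrix must have identical row and column residue names")
  if (!isTRUE(all.equal(mat, t(mat))))
    stop("substitution matrix must be symmetric")
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            lambda > 0, k_param > 0, h_param > 0)
  structure(
    list(matrix = mat, matrix_name = name,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, k_param = k_param, h_param = h_param),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$matrix_name,
      " gap ", x$gap_open, "/", x$gap_extend,
      "  lambda=", x$lambda, " K=", x$k_param, " H=", x$h_param, "\n", sep = "")
  invisible(x)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (`#` comments, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return A symmetric integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, comment.char = "#",
                            row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  if (!identical(rownames(m), colnames(m)))
    stop("malformed matrix file: row and column labels differ")
  m
}

# Encode a protein string as 0-based indices into a substitution matrix,
# erroring with the 1-based position of the first invalid residue.
encode_protein <- function(seq, mat, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[pos], pos, what))
  }
  idx - 1L
}

# Validate a protein sequence against the 20-letter alphabet (+ optional X).
validate_protein <- function(seq, allow_x = TRUE, what = "sequence") {
  ok <- aa_alphabet()
  if (allow_x) ok <- c(ok, "X")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop(sprintf("%s is empty", what))
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what))
  invisible(TRUE)
}
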