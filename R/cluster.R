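.DIST_CAP <- 10  # distance assigned when the correction diverges (p too high)

.kimura_correct <- function(p) {
  arg <- 1 - p - p^2 / 5
  ifelse(arg <= 0, .DIST_CAP, -log(arg))
}

# p-distances from a character matrix (rows = sequences) over columns where
# both members of a pair are non-gap. With fallback = TRUE a pair with zero
# comparable columns gets the capped maximum distance instead of an error
# (used inside bootstrap replicates, where resampling can drop all shared
# columns).
.dist_from_char_matrix <- function(m, correction = "kimura",
                                   fallback = FALSE) {
  n <- nrow(m)
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        if (!fallback)
          stop(sprintf("no comparable (gap-free) columns between '%s' and '%s'",
                       labels[i], labels[j]))
        dij <- .DIST_CAP
      } else {
        p <- mean(m[i, ok] != m[j, ok])
        dij <- if (correction == "kimura") .kimura_correct(p) else p
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Pairwise distances between protein sequences
#'
#' For aligned input (equal-length gapped sequences) the p-distance is
#' computed over columns where both sequences are gap-free, optionally with
#' the Kimura correction `d = -ln(1 - p - p^2/5)` (capped at 10 where the
#' correction diverges). For unaligned input each pair is aligned locally
#' with [smith_waterman()] and the alignment identity is converted to a
#' p-distance first.
#'
#' @param seqs Named character vector of >= 3 sequences.
#' @param aligned `TRUE`/`FALSE`; default auto-detects from the presence of
#'   `-` characters or equal lengths.
#' @param correction `"kimura"` or `"none"` (plain p-distance).
#' @param scheme Scoring scheme used for the unaligned case.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distance <- function(seqs, aligned = NULL,
                              correction = c("kimura", "none"),
                              scheme = scoring_scheme()) {
  correction <- match.arg(correction)
  stopifnot(length(seqs) >= 3, !is.null(names(seqs)))
  if (is.null(aligned))
    aligned <- any(grepl("-", seqs, fixed = TRUE)) &&
      length(unique(nchar(seqs))) == 1
  if (aligned) {
    if (length(unique(nchar(seqs))) != 1)
      stop("aligned input must have equal-length sequences")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
    return(.dist_from_char_matrix(m, correction))
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- smith_waterman(seqs[[i]], seqs[[j]], scheme)
      if (is.null(aln)) {
        dij <- .DIST_CAP
      } else {
        p <- 1 - aln$identity_pct / 100
        dij <- if (correction == "kimura") .kimura_correct(p) else p
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# Align two profiles (lists with $ids, $seqs of equal-length gapped strings)
# under the scheme; returns the merged profile.
.merge_profiles <- function(a, b, scheme) {
  mat <- scheme$matrix
  alpha <- rownames(mat)
  freq <- function(p) {
    chars <- do.call(rbind, strsplit(p$seqs, "", fixed = TRUE))
    f <- matrix(0, length(alpha), ncol(chars),
                dimnames = list(alpha, NULL))
    for (a_ in alpha) f[a_, ] <- colSums(chars == a_)
    f / nrow(chars)  # gap mass simply dilutes the column
  }
  fa <- freq(a); fb <- freq(b)
  cost <- t(fa) %*% mat %*% fb
  ops <- profile_nw_cpp(cost, scheme$gap_open, scheme$gap_extend)
  gapify <- function(seqs, consume_op) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    vapply(chars, function(x) {
      out <- character(length(ops)); i <- 0L
      for (k in seq_along(ops)) {
        if (ops[k] == 0L || ops[k] == consume_op) {
          i <- i + 1L; out[k] <- x[i]
        } else out[k] <- "-"
      }
      paste(out, collapse = "")
    }, "")
  }
  list(ids = c(a$ids, b$ids),
       seqs = c(gapify(a$seqs, 1L), gapify(b$seqs, 2L)))
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive scheme: a neighbor-joining guide tree is built from
#' pairwise local-alignment distances, midpoint-rooted, and profiles are
#' merged leaf-to-root by global profile-profile alignment (column scores
#' are frequency-weighted substitution scores; affine gap penalties from the
#' scheme). Every input sequence is recoverable from the alignment by
#' removing gaps.
#'
#' @param seqs Named character vector of >= 2 protein sequences.
#' @param scheme A [scoring_scheme()].
#' @return Named character vector of equal-length gapped sequences, in the
#'   input order.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (length(seqs) == 2) {
    prof <- .merge_profiles(list(ids = names(seqs)[1], seqs = seqs[[1]]),
                            list(ids = names(seqs)[2], seqs = seqs[[2]]),
                            scheme)
    return(setNames(prof$seqs, prof$ids))
  }
  d <- pairwise_distance(seqs, aligned = FALSE, correction = "none",
                         scheme = scheme)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- tryCatch(phangorn::midpoint(tr), error = function(e) tr)
  tr <- ape::reorder.phylo(tr, "postorder")
  profiles <- vector("list", max(tr$edge))
  for (i in seq_along(tr$tip.label))
    profiles[[i]] <- list(ids = tr$tip.label[i], seqs = seqs[[tr$tip.label[i]]])
  # postorder edge table: children of each internal node appear before it
  for (node in unique(tr$edge[, 1])) {
    children <- tr$edge[tr$edge[, 1] == node, 2]
    prof <- profiles[[children[1]]]
    for (ch in children[-1])
      prof <- .merge_profiles(prof, profiles[[ch]], scheme)
    profiles[[node]] <- prof
  }
  root <- tr$edge[nrow(tr$edge), 1]
  out <- setNames(profiles[[root]]$seqs, profiles[[root]]$ids)
  out[names(seqs)]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via `ape::nj()`); negative branch
#' length estimates are clamped to zero. On an additive matrix the output
#' topology reproduces the generating tree exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and labels as
#'   dimnames (>= 4 labels for a resolved unrooted topology).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels as dimnames")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicate trees containing that bipartition.
#' Deterministic for a fixed seed.
#'
#' @param alignment Named character vector of equal-length gapped sequences
#'   (>= 4 sequences).
#' @param n_reps Number of bootstrap replicates (default 50).
#' @param seed Integer RNG seed.
#' @param correction Distance correction, as in [pairwise_distance()].
#' @return The original NJ `phylo` tree with `node.label` set to integer
#'   support percentages and a numeric `support` attribute.
#' @export
bootstrap_support <- function(alignment, n_reps = 50L, seed = 1L,
                              correction = c("kimura", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(alignment) >= 4, n_reps >= 1,
            length(unique(nchar(alignment))) == 1)
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  ref <- nj_tree(.dist_from_char_matrix(m, correction, fallback = TRUE))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- nj_tree(.dist_from_char_matrix(m[, cols, drop = FALSE],
                                                correction, fallback = TRUE))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  ref$node.label <- as.character(round(support))
  attr(ref, "support") <- support
  ref
}

#' Extract the subtree nearest a set of reference leaves
#'
#' Returns the minimal subtree spanning the reference leaves plus, for each
#' reference, its `k` nearest non-reference leaves by path length (ties at
#' the cutoff broken by label order).
#'
#' @param tree An `ape::phylo` tree.
#' @param reference_ids Leaf labels of the references (must be in the tree).
#' @param k Number of nearest leaves to keep per reference; `k = 0` spans
#'   the references only, `k >=` leaf count returns the whole tree.
#' @return The pruned `phylo` subtree.
#' @export
subtree_near_reference <- function(tree, reference_ids, k) {
  miss <- setdiff(reference_ids, tree$tip.label)
  if (length(miss))
    stop("reference(s) not in tree: ", paste(miss, collapse = ", "))
  others <- setdiff(tree$tip.label, reference_ids)
  if (k >= length(others))
    return(tree)
  keep <- reference_ids
  if (k > 0) {
    D <- ape::cophenetic.phylo(tree)
    for (r in reference_ids) {
      dr <- D[r, others]
      sel <- others[order(dr, others)][seq_len(k)]
      keep <- union(keep, sel)
    }
  }
  if (length(keep) < 2)
    stop("subtree needs >= 2 leaves; add references or increase k")
  ape::keep.tip(tree, keep)
}
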