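test_that("pairwise distances: identity, Kimura correction, error cases", {
  seqs <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKTAYIAKQW")
  d <- pairwise_distance(seqs, aligned = TRUE, correction = "none")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.1)
  dk <- pairwise_distance(seqs, aligned = TRUE, correction = "kimura")
  expect_equal(dk["a", "b"], 0)                       # p = 0 limit
  expect_equal(dk["a", "c"], -log(1 - 0.1 - 0.01 / 5))  # ~0.1076
  expect_true(isSymmetric(dk))
  # a pair sharing no gap-free column errors, naming the pair
  gap <- c(a = "MK--", b = "--TA", c = "MKTA")
  expect_error(pairwise_distance(gap, aligned = TRUE), "'a' and 'b'")
})

test_that("neighbor joining recovers random additive topologies exactly", {
  for (seed in 1:10) {
    gen <- random_additive_matrix(sample(6:10, 1), seed)
    rec <- nj_tree(gen$d)
    expect_equal(ape::dist.topo(gen$tree, rec), 0,
                 ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
  # 4-taxon additive matrix from ((A,B),(C,D)) with unit branches
  d4 <- matrix(c(0, 2, 3, 3,
                 2, 0, 3, 3,
                 3, 3, 0, 2,
                 3, 3, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"),
                               c("A", "B", "C", "D")))
  tr <- nj_tree(d4)
  # the AB|CD bipartition must be present: A,B form a cherry
  mrca <- ape::getMRCA(tr, c("A", "B"))
  desc <- ape::extract.clade(tr, mrca)$tip.label
  expect_setequal(desc, c("A", "B"))
  bad <- d4; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
})

test_that("label order does not change the recovered topology", {
  gen <- random_additive_matrix(8, 42)
  perm <- sample(rownames(gen$d))
  rec1 <- nj_tree(gen$d)
  rec2 <- nj_tree(gen$d[perm, perm])
  expect_equal(ape::dist.topo(rec1, rec2), 0, ignore_attr = TRUE)
})

test_that("equidistant matrices resolve with zero-length internal edges", {
  n <- 5
  d <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(tr$edge.length[internal] < 1e-8))
  expect_true(all(tr$edge.length >= 0))
})

test_that("progressive MSA round-trips inputs and handles base cases", {
  sch <- scoring_scheme()
  # 2 sequences: global alignment of the pair
  two <- c(x = "MKTAYIAKQR", y = "MKTAYAKQR")
  aln2 <- progressive_msa(two, sch)
  expect_length(unique(nchar(aln2)), 1)
  expect_equal(gsub("-", "", aln2), two)
  # identical triplet stays gap-free
  tri <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKTAYIAKQR")
  aln3 <- progressive_msa(tri, sch)
  expect_false(any(grepl("-", aln3)))
  # 5 variants at ~90% identity: width >= reference length, full round-trip
  ref <- random_protein(60, seed = 8)
  vars <- setNames(vapply(1:5, function(i)
    mutate_sequence(ref, 0.9, seed = i), ""), paste0("v", 1:5))
  aln5 <- progressive_msa(vars, sch)
  expect_length(unique(nchar(aln5)), 1)
  expect_gte(unique(nchar(aln5)), 60)
  expect_equal(gsub("-", "", aln5)[names(vars)], vars)
})

test_that("bootstrap supports separate planted clades and are deterministic", {
  ref <- random_protein(120, seed = 15)
  far <- mutate_sequence(ref, 0.8, seed = 500)       # 20% between clades
  seqs <- setNames(
    c(vapply(1:3, function(i) mutate_sequence(ref, 0.98, seed = i), ""),
      vapply(4:6, function(i) mutate_sequence(far, 0.98, seed = i), "")),
    c("A1", "A2", "A3", "B1", "B2", "B3"))
  aln <- progressive_msa(seqs)
  tr <- bootstrap_support(aln, n_reps = 50, seed = 9)
  supp <- attr(tr, "support")
  expect_true(all(supp >= 0 & supp <= 100))
  # support of the A|B bipartition
  mrca <- ape::getMRCA(tr, c("A1", "A2", "A3"))
  clade_support <- if (is.null(mrca)) NA else {
    tips <- ape::extract.clade(tr, mrca)$tip.label
    if (setequal(tips, c("A1", "A2", "A3")) ||
        setequal(tips, c("B1", "B2", "B3")))
      supp[mrca - length(tr$tip.label)] else NA
  }
  if (is.na(clade_support)) {
    mrca <- ape::getMRCA(tr, c("B1", "B2", "B3"))
    tips <- ape::extract.clade(tr, mrca)$tip.label
    clade_support <- supp[mrca - length(tr$tip.label)]
  }
  expect_gte(clade_support, 90)
  # determinism and the single-replicate degenerate case
  tr2 <- bootstrap_support(aln, n_reps = 50, seed = 9)
  expect_equal(attr(tr2, "support"), supp)
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 2)
  expect_true(all(attr(tr1, "support") %in% c(0, 100)))
})

test_that("nearest-reference subtrees follow the k-nearest rule", {
  # plant hits H1..H3 on short branches next to reference R
  nwk <- "((R:0.1,(H1:0.05,(H2:0.05,H3:0.05):0.05):0.05):1.0,((F1:0.2,F2:0.2):0.8,(F3:0.2,F4:0.2):0.8):1.0);"
  tr <- ape::read.tree(text = nwk)
  sub <- subtree_near_reference(tr, "R", k = 3)
  expect_setequal(sub$tip.label, c("R", "H1", "H2", "H3"))
  # k = 0 spans the references only
  sub0 <- subtree_near_reference(tr, c("R", "F1"), k = 0)
  expect_setequal(sub0$tip.label, c("R", "F1"))
  # k >= leaf count returns the whole tree
  all_ <- subtree_near_reference(tr, "R", k = 50)
  expect_setequal(all_$tip.label, tr$tip.label)
  expect_error(subtree_near_reference(tr, "missing", k = 1), "missing")
  # output always contains every reference
  sub2 <- subtree_near_reference(tr, c("R", "F4"), k = 1)
  expect_true(all(c("R", "F4") %in% sub2$tip.label))
})
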