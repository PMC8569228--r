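mk_msa <- function(...) {
  seqs <- c(...)
  rows <- do.call(rbind, strsplit(seqs, ""))
  rownames(rows) <- names(seqs)
  structure(rows, class = c("evasin_msa", "matrix", "array"))
}

test_that("identity distance follows sqrt(1 - identity) with pairwise deletion", {
  msa <- mk_msa(a = "ACDE", b = "ACDF")
  expect_equal(identity_distance(msa)["a", "b"], sqrt(1 - 3 / 4)) # = 0.5
  msa2 <- mk_msa(a = "AC-E", b = "ACDE")
  expect_equal(identity_distance(msa2)["a", "b"], 0) # compared = 3, all match
  msa3 <- mk_msa(a = "ACDE", b = "ACDE")
  expect_equal(identity_distance(msa3)["a", "b"], 0)
  expect_warning(d <- identity_distance(mk_msa(a = "AC--", b = "--DE")),
                 "no comparable")
  expect_equal(d["a", "b"], 1)
  expect_error(identity_distance(mk_msa(a = "ACDE")), "at least 2")
})

test_that("identity distance agrees with seqinr's dist.alignment", {
  skip_if_not_installed("seqinr")
  set.seed(3)
  seqs <- setNames(vapply(1:5, function(i) random_seq(30), character(1)),
                   paste0("s", 1:5))
  msa <- progressive_align(seqs)
  D <- identity_distance(msa)
  aln <- seqinr::as.alignment(
    nb = nrow(msa),
    nam = rownames(msa),
    seq = tolower(apply(msa, 1, paste, collapse = ""))
  )
  Dref <- as.matrix(seqinr::dist.alignment(aln, matrix = "identity"))
  expect_equal(D[rownames(Dref), colnames(Dref)], Dref,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  depths <- setNames(tr$edge.length[order(tr$edge[, 2])][1:3], tr$tip.label)
  expect_equal(unname(depths[c("a", "b", "c")]), c(2, 3, 7))
})

test_that("NJ recovers the known additive four-taxon tree exactly", {
  ids <- c("A", "B", "C", "D")
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  # topology AB|CD
  bp <- evasinclass:::tree_bipartitions(tr)
  expect_true("A|B" %in% bp | "C|D" %in% bp)
  # path lengths reproduce D
  P <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(P, D, tolerance = 1e-12)
  # leaf edges 2,3,4,5 and internal edge 1
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 2, 3, 4, 5))
})

test_that("NJ reproduces random additive matrices and their topology", {
  for (seed in 1:10) {
    ad <- random_additive(sample(5:12, 1), seed)
    tr <- nj_tree(ad$D)
    P <- ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)]
    expect_lt(max(abs(P - ad$D)), 1e-9)
    # independent cross-check: ape's NJ finds the same unrooted topology
    ref <- ape::nj(ad$D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("star matrices resolve deterministically with zero internal edges", {
  ids <- letters[1:5]
  D <- matrix(1, 5, 5, dimnames = list(ids, ids)); diag(D) <- 0
  tr1 <- nj_tree(D)
  tr2 <- nj_tree(D)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # internal edges all zero
  internal <- tr1$edge[, 2] > length(tr1$tip.label)
  expect_true(all(abs(tr1$edge.length[internal]) < 1e-12))
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "symmetric")
  D2 <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D2), "non-negative")
})

test_that("two-taxon trees get a single split edge and midpoint halves it", {
  D <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), 6)
  r <- midpoint_root_tree(tr)
  expect_equal(r$edge.length, c(3, 3))
})

test_that("midpoint root minimizes the maximum root-to-leaf depth", {
  # chain: leaves A and B span the longest path (6); C hangs off the middle
  tr <- ape::read.tree(text = "(A:1,C:1,B:5);")
  r <- midpoint_root_tree(tr)
  ntip <- length(r$tip.label)
  depths <- ape::dist.nodes(r)[ntip + 1, seq_len(ntip)]
  expect_equal(max(depths), 3)
  set.seed(11)
  for (rep in 1:30) {
    t0 <- ape::rtree(sample(4:10, 1)); t0$node.label <- NULL
    r0 <- midpoint_root_tree(t0)
    n0 <- length(r0$tip.label)
    achieved <- max(ape::dist.nodes(r0)[n0 + 1, seq_len(n0)])
    expect_lte(achieved, oracle_min_max_depth(t0) + 1e-9)
  }
})

test_that("degenerate trees for midpoint rooting error usefully", {
  flat <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_error(midpoint_root_tree(flat), "zero")
  noLen <- ape::read.tree(text = "(A,B,C);")
  expect_error(midpoint_root_tree(noLen), "branch lengths")
})

test_that("bootstrap supports are deterministic, bounded, and signal-consistent", {
  # every column separates {a,b} from {c,d,e}: the true bipartition must get
  # support 1 in every replicate
  msa <- mk_msa(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                c = "GGGGGGGGGG", d = "GGGGGGGGGG", e = "GGGGGGGGGC")
  tr <- bootstrap_support(msa, n_reps = 50, seed = 9)
  sup <- tr$support[!is.na(tr$support)]
  expect_true(all(sup >= 0 & sup <= 1))
  # canonical key for the {a,b} vs {c,d,e} bipartition is the side without "a"
  keys <- evasinclass:::tree_bipartitions(tr)
  ab <- which(keys == "c|d|e")
  expect_length(ab, 1L)
  expect_equal(unname(tr$support[ab]), 1)
  # same seed, same supports; n_reps = 0 leaves the tree undecorated
  tr2 <- bootstrap_support(msa, n_reps = 50, seed = 9)
  expect_identical(tr$support, tr2$support)
  plain <- bootstrap_support(msa, n_reps = 0, seed = 9)
  expect_null(plain$support)
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  msa <- mk_msa(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                c = "GGGGGGGGGG", d = "GGGGGGGGGG", e = "GGGGGGGGGC")
  tr <- midpoint_root_tree(bootstrap_support(msa, n_reps = 40, seed = 2))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_identical(ape::write.tree(back), ape::write.tree(tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  sup1 <- sort(tr$support[!is.na(tr$support)])
  sup2 <- sort(back$support[!is.na(back$support)])
  expect_equal(sup1, sup2)
})
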