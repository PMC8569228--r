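# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately share no code with the implementation.

# Gotoh local alignment score (gap of length L costs open + L * extend)
oracle_local_score <- function(a, b, mat, gap_open, gap_extend) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_extend, H[i + 1, j] - gap_open - gap_extend)
      F[i + 1, j + 1] <- max(F[i, j + 1] - gap_extend, H[i, j + 1] - gap_open - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + mat[ra[i], rb[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Gotoh global alignment score
oracle_global_score <- function(a, b, mat, gap_open, gap_extend) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  H <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in seq_len(m)) {
    E[1, j + 1] <- -(gap_open + gap_extend * j)
    H[1, j + 1] <- E[1, j + 1]
  }
  for (i in seq_len(n)) {
    F[i + 1, 1] <- -(gap_open + gap_extend * i)
    H[i + 1, 1] <- F[i + 1, 1]
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_extend, H[i + 1, j] - gap_open - gap_extend)
      F[i + 1, j + 1] <- max(F[i, j + 1] - gap_extend, H[i, j + 1] - gap_open - gap_extend)
      H[i + 1, j + 1] <- max(H[i, j] + mat[ra[i], rb[j]], E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  H[n + 1, m + 1]
}

# every anchor tuple compatible with the motif, by exhaustive enumeration of
# anchor-position subsets (combn), independent of the scanner's DFS
oracle_motif_tuples <- function(sequence, motif) {
  res <- strsplit(sequence, "")[[1]]
  k <- length(motif$anchors)
  if (length(unique(motif$anchors)) != 1) stop("oracle assumes uniform anchors")
  pos <- which(res == motif$anchors[1])
  if (length(pos) < k) return(list())
  out <- list()
  for (idx in utils::combn(length(pos), k, simplify = FALSE)) {
    tup <- pos[idx]
    gaps <- diff(tup) - 1L
    if (all(gaps >= motif$gap_min & gaps <= motif$gap_max)) {
      out[[length(out) + 1L]] <- tup
    }
  }
  out
}

# maximum root-to-leaf depth if the root is placed on `edge` at distance
# `x` from the child end
oracle_point_depth <- function(tree, edge_row, x, Dn) {
  ntip <- length(tree$tip.label)
  u <- tree$edge[edge_row, 1] # parent
  v <- tree$edge[edge_row, 2] # child
  len <- tree$edge.length[edge_row]
  max(vapply(seq_len(ntip), function(leaf) {
    min(x + Dn[v, leaf], (len - x) + Dn[u, leaf])
  }, numeric(1)))
}

# minimal achievable max-depth over a discretized set of candidate root
# points on every edge
oracle_min_max_depth <- function(tree, steps = 20) {
  Dn <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[e]
    for (x in seq(0, len, length.out = steps + 1)) {
      best <- min(best, oracle_point_depth(tree, e, x, Dn))
    }
  }
  best
}

# random amino-acid sequence; `p_cys` controls cysteine density
random_seq <- function(n, p_cys = 0) {
  aa <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V"), "C")
  prob <- c(rep((1 - p_cys) / 19, 19), p_cys)
  paste(sample(c(aa, "C"), n, replace = TRUE, prob = prob), collapse = "")
}

# additive distance matrix from a random tree, with its source tree
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$node.label <- NULL
  D <- ape::cophenetic.phylo(tr)
  ids <- sort(rownames(D))
  list(tree = tr, D = D[ids, ids])
}

blosum62 <- evasinclass::substitution_matrix("BLOSUM62")

# small synthetic config that keeps unit tests fast
quick_config <- function(seed, ...) {
  synthetic_config(n_class1 = 8, n_class2 = 8, motif_class1 = "cys6",
                   motif_class2 = "none", mature_length = 60,
                   seed = seed, ...)
}
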