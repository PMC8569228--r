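#' Square-root identity distances from an alignment
#'
#' For each pair of rows, compared positions are the columns where both rows
#' are non-gap (pairwise deletion; `"complete"` restricts to columns with no
#' gap in any row) and the distance is `sqrt(1 - matches / compared)`. Pairs
#' with no comparable positions get distance 1 with a warning.
#'
#' @param msa An `evasin_msa` with at least 2 rows.
#' @param deletion Gap handling: `"pairwise"` (default) or `"complete"`.
#' @return Symmetric distance matrix with zero diagonal, ids as dimnames.
#' @export
identity_distance <- function(msa, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (nrow(msa) < 2) abort("Distance matrix needs at least 2 aligned rows.")
  rows <- unclass(msa)
  if (deletion == "complete") {
    keep <- colSums(rows == "-") == 0
    rows <- rows[, keep, drop = FALSE]
  }
  n <- nrow(rows)
  D <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- rows[i, ] != "-" & rows[j, ] != "-"
      compared <- sum(both)
      if (compared == 0) {
        if (!warned) {
          warn("Pair(s) with no comparable columns; distance set to 1.")
          warned <- TRUE
        }
        d <- 1
      } else {
        d <- sqrt(1 - sum(rows[i, both] == rows[j, both]) / compared)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

validate_distance <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("Distance matrix must be square.")
  if (is.null(rownames(D))) abort("Distance matrix needs row/column names.")
  if (max(abs(D - t(D))) > 1e-8) abort("Distance matrix must be symmetric.")
  if (any(D < 0)) abort("Distance matrix must be non-negative.")
  if (any(abs(diag(D)) > 1e-12)) abort("Distance matrix diagonal must be zero.")
  invisible(D)
}

fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined, with branch lengths from
#' the standard two-point formulas. Q ties are broken by the smallest index
#' pair in the current matrix order. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sibling edge. On additive
#' matrices the tree's path lengths reproduce the input exactly.
#'
#' @param D Symmetric named distance matrix.
#' @return An unrooted `ape::phylo` (trifurcating root node) for n >= 3; for
#'   n = 2 a single-edge tree split evenly across the root.
#' @export
#' @examples
#' D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' tr <- nj_tree(D) # leaf branches 2, 3, 7
nj_tree <- function(D) {
  validate_distance(D)
  ids <- rownames(D)
  n <- length(ids)
  if (n < 2) abort("Need at least 2 taxa.")
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", ids[1], fmt_len(D[1, 2] / 2),
                   ids[2], fmt_len(D[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  frag <- ids
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    best <- NULL
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        q <- (r - 2) * D[i, j] - R[i] - R[j]
        if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { li <- 0; lj <- D[i, j] }
    if (lj < 0) { lj <- 0; li <- D[i, j] }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li), frag[j], fmt_len(lj))
    m <- setdiff(seq_len(r), c(i, j))
    dnew <- (D[i, m] + D[j, m] - D[i, j]) / 2
    D2 <- rbind(cbind(D[m, m, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[m], newfrag)
    D <- D2
    dimnames(D) <- NULL
  }
  l1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt_len(l1), frag[2], fmt_len(l2), frag[3], fmt_len(l3))
  ape::read.tree(text = txt)
}

# ---- bipartition bookkeeping ------------------------------------------------

# canonical key for the bipartition induced by a set of tip labels: the side
# NOT containing the reference (lexicographically smallest) label, sorted
bipartition_key <- function(tips, all_tips, ref) {
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  if (length(side) < 2 || length(side) > length(all_tips) - 2) return(NA_character_)
  paste(sort(side), collapse = "|")
}

# keys of all internal-edge bipartitions of a tree (named by node number)
tree_bipartitions <- function(tree) {
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  nodes <- seq_len(tree$Nnode) + length(tree$tip.label)
  keys <- vapply(seq_along(pp), function(k) {
    bipartition_key(labels[pp[[k]]], all_tips, ref)
  }, character(1))
  setNames(keys, nodes)
}

#' Bootstrap support by alignment-column resampling
#'
#' Resamples alignment columns with replacement (same column count),
#' recomputes the identity distance and neighbour-joining tree for each
#' replicate, and scores every internal edge of `tree` by the fraction of
#' replicates containing the same leaf bipartition. Works on rooted or
#' unrooted target trees (bipartitions ignore rooting).
#'
#' @param msa The `evasin_msa` the tree was built from (>= 4 rows).
#' @param tree Tree to decorate; defaults to the NJ tree of `msa`.
#' @param n_reps Number of bootstrap replicates (0 leaves the tree
#'   unchanged, supports absent).
#' @param seed RNG seed for the column resampling.
#' @param deletion Passed to [identity_distance()].
#' @return `tree` with a numeric `support` vector (per internal node, NA for
#'   edges that are not internal bipartitions, e.g. the root) and matching
#'   `node.label` percentages.
#' @export
bootstrap_support <- function(msa, tree = NULL, n_reps = 100, seed = NULL,
                              deletion = "pairwise") {
  tree <- tree %||% nj_tree(identity_distance(msa, deletion))
  if (n_reps == 0) return(tree)
  if (nrow(msa) < 4) abort("Bootstrap needs an alignment with >= 4 rows.")
  rows <- unclass(msa)
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(rows), ncol(rows), replace = TRUE)
      rep_rows <- rows[, cols, drop = FALSE]
      keep <- colSums(rep_rows != "-") > 0
      rep_msa <- structure(rep_rows[, keep, drop = FALSE],
                           class = c("evasin_msa", "matrix", "array"))
      rep_tree <- suppressWarnings(nj_tree(identity_distance(rep_msa, deletion)))
      for (key in unique(stats::na.omit(tree_bipartitions(rep_tree)))) {
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  })
  keys <- tree_bipartitions(tree)
  support <- vapply(keys, function(k) {
    if (is.na(k)) NA_real_ else (counts[[k]] %||% 0L) / n_reps
  }, numeric(1))
  tree$support <- unname(support)
  tree$node.label <- ifelse(is.na(support), "", sprintf("%g", support * 100))
  tree
}

# ---- midpoint rooting -------------------------------------------------------

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' Places the root halfway along the longest path between two leaves, which
#' minimizes the maximum root-to-leaf distance. Ties among equally long
#' paths are broken by the lexicographically smallest leaf-label pair. If the
#' midpoint falls exactly on a node, a zero-length root edge is introduced.
#' Bootstrap supports attached by [bootstrap_support()] are re-mapped onto
#' the rooted tree by bipartition.
#'
#' @param tree An unrooted `ape::phylo` with branch lengths.
#' @return A rooted `ape::phylo` (degree-2 root).
#' @export
midpoint_root_tree <- function(tree) {
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (sum(tree$edge.length) <= 0) {
    abort("All branch lengths are zero: midpoint undefined. Inspect the distance matrix.")
  }
  ntip <- length(tree$tip.label)
  if (ntip == 2) {
    total <- sum(tree$edge.length)
    tree$edge.length <- rep(total / 2, 2)
    return(tree)
  }
  support_map <- NULL
  if (!is.null(tree$support)) {
    keys <- tree_bipartitions(tree)
    support_map <- setNames(tree$support, keys)
    support_map <- support_map[!is.na(names(support_map))]
  }
  Dn <- ape::dist.nodes(tree)
  best <- NULL
  labels <- tree$tip.label
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      d <- Dn[i, j]
      key <- sort(c(labels[i], labels[j]))
      if (is.null(best) || d > best$d + 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(d = d, key = key, i = i, j = j)
      }
    }
  }
  path <- ape::nodepath(tree, best$i, best$j)
  cum <- c(0, cumsum(Dn[cbind(path[-length(path)], path[-1])]))
  half <- best$d / 2
  k <- which(cum >= half - 1e-12)[1]
  node_a <- path[k - 1]; node_b <- path[k] # midpoint on edge node_a -- node_b
  # identify the child end of that edge
  parent_of <- function(v) tree$edge[tree$edge[, 2] == v, 1]
  if (length(parent_of(node_b)) == 1 && parent_of(node_b) == node_a) {
    child <- node_b; from_child <- cum[k] - half
  } else {
    child <- node_a; from_child <- half - cum[k - 1]
  }
  edge_len <- tree$edge.length[tree$edge[, 2] == child]
  # phytools measures `position` from the rootward (parent) end of the edge
  rooted <- phytools::reroot(tree, node.number = child,
                             position = edge_len - from_child)
  rooted$node.label <- NULL
  if (!is.null(support_map)) {
    keys2 <- tree_bipartitions(rooted)
    support <- unname(vapply(keys2, function(kk) {
      if (is.na(kk) || is.null(support_map[[kk]]) || is.na(support_map[kk])) {
        NA_real_
      } else {
        support_map[[kk]]
      }
    }, numeric(1)))
    rooted$support <- support
    rooted$node.label <- ifelse(is.na(support), "", sprintf("%g", support * 100))
  }
  rooted
}

#' Write and read Newick with percentage support labels
#'
#' `write_newick()` writes the tree with bootstrap supports rendered as
#' internal-node labels in percent; `read_newick()` parses them back into a
#' `support` vector of fractions.
#'
#' @param tree An `ape::phylo`, optionally with a `support` vector.
#' @param path File path.
#' @return `read_newick()` returns the tree; `write_newick()` the path,
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$support) && is.null(tree$node.label)) {
    tree$node.label <- ifelse(is.na(tree$support), "", sprintf("%g", tree$support * 100))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label)) / 100
    tree$support <- sup
  }
  tree
}
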