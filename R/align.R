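#' Multiple sequence alignment container
#'
#' An `evasin_msa` is a character matrix of aligned residues: one row per
#' sequence (rownames are ids), one column per alignment position, gaps as
#' `"-"`. De-gapping any row reproduces the input sequence exactly.
#'
#' @param rows Character matrix of single residues.
#' @return An `evasin_msa`.
#' @keywords internal
new_msa <- function(rows) {
  stopifnot(is.matrix(rows), !is.null(rownames(rows)))
  if (ncol(rows) > 0 && any(colSums(rows != "-") == 0)) {
    abort("MSA has an all-gap column.")
  }
  structure(rows, class = c("evasin_msa", "matrix", "array"))
}

#' @export
print.evasin_msa <- function(x, ...) {
  cat(sprintf("<evasin_msa: %d sequences x %d columns>\n", nrow(x), ncol(x)))
  shown <- head(seq_len(nrow(x)), 10)
  for (i in shown) {
    s <- paste(x[i, ], collapse = "")
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", rownames(x)[i], s))
  }
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Remove gaps from MSA rows
#' @param msa An `evasin_msa`.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  setNames(apply(msa, 1, function(r) paste(r[r != "-"], collapse = "")),
           rownames(msa))
}

#' Write an alignment as gapped FASTA
#' @param msa An `evasin_msa`.
#' @param path Output file.
#' @export
write_msa_fasta <- function(msa, path) {
  x <- Biostrings::AAStringSet(setNames(apply(msa, 1, paste, collapse = ""),
                                        rownames(msa)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a gapped FASTA alignment
#' @param path Aligned FASTA file.
#' @return An `evasin_msa`.
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(x))) > 1) {
    abort("Aligned FASTA rows have unequal lengths.")
  }
  rows <- do.call(rbind, lapply(as.character(x), split_residues))
  rownames(rows) <- sub("\\s.*$", "", names(x))
  new_msa(rows)
}

# ---- profile-profile affine-gap dynamic programming (Gotoh) -----------------

# average-linkage column score: mean substitution score over residue pairs,
# residue-vs-gap pairs contributing 0
profile_counts <- function(rows, alphabet) {
  counts <- matrix(0, length(alphabet), ncol(rows),
                   dimnames = list(alphabet, NULL))
  for (a in alphabet) counts[a, ] <- colSums(rows == a)
  counts
}

profile_align <- function(A, B, mat, gap_open, gap_extend) {
  alphabet <- rownames(mat)
  la <- ncol(A); lb <- ncol(B)
  na_ <- nrow(A); nb_ <- nrow(B)
  CA <- profile_counts(A, alphabet)
  CB <- profile_counts(B, alphabet)
  M <- (t(CA) %*% mat %*% CB) / (na_ * nb_)

  NEG <- -1e18
  H <- matrix(NEG, la + 1, lb + 1)
  E <- matrix(NEG, la + 1, lb + 1) # ends with gap column in A (consumes B)
  F_ <- matrix(NEG, la + 1, lb + 1) # ends with gap column in B (consumes A)
  H[1, 1] <- 0
  if (lb > 0) {
    E[1, 2:(lb + 1)] <- -(gap_open + gap_extend * seq_len(lb))
    H[1, ] <- pmax(H[1, ], E[1, ])
  }
  if (la > 0) {
    F_[2:(la + 1), 1] <- -(gap_open + gap_extend * seq_len(la))
    H[, 1] <- pmax(H[, 1], F_[, 1])
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_extend,
                             H[i + 1, j] - gap_open - gap_extend)
      F_[i + 1, j + 1] <- max(F_[i, j + 1] - gap_extend,
                              H[i, j + 1] - gap_open - gap_extend)
      H[i + 1, j + 1] <- max(H[i, j] + M[i, j], E[i + 1, j + 1], F_[i + 1, j + 1])
    }
  }

  # traceback; tie preference: aligned pair, then gap in the first profile
  eps <- 1e-9
  cols_a <- integer(0); cols_b <- integer(0) # 0 encodes a gap column
  i <- la; j <- lb
  state <- "H"
  while (i > 0 || j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (i > 0 && j > 0 && abs(h - (H[i, j] + M[i, j])) < eps) {
        cols_a <- c(cols_a, i); cols_b <- c(cols_b, j)
        i <- i - 1; j <- j - 1
      } else if (j > 0 && abs(h - E[i + 1, j + 1]) < eps) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols_a <- c(cols_a, 0L); cols_b <- c(cols_b, j)
      stay <- j > 1 && abs(E[i + 1, j + 1] - (E[i + 1, j] - gap_extend)) < eps
      j <- j - 1
      if (!stay) state <- "H"
    } else { # F
      cols_a <- c(cols_a, i); cols_b <- c(cols_b, 0L)
      stay <- i > 1 && abs(F_[i + 1, j + 1] - (F_[i, j + 1] - gap_extend)) < eps
      i <- i - 1
      if (!stay) state <- "H"
    }
  }
  cols_a <- rev(cols_a); cols_b <- rev(cols_b)
  take <- function(P, idx) {
    out <- matrix("-", nrow(P), length(idx))
    nz <- idx > 0
    out[, nz] <- P[, idx[nz], drop = FALSE]
    out
  }
  rows <- rbind(take(A, cols_a), take(B, cols_b))
  rownames(rows) <- c(rownames(A), rownames(B))
  list(rows = rows, score = H[la + 1, lb + 1])
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment of two sequences; ties resolved by
#' preferring an aligned residue pair over a gap, then a gap in the first
#' sequence. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param a,b Amino-acid strings.
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `a_aligned`, `b_aligned`, `score`, and `identity`
#'   (matching columns / alignment length).
#' @export
pairwise_global <- function(a, b, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  assert_scalar_string(a, "a")
  assert_scalar_string(b, "b")
  if (!nzchar(a) || !nzchar(b)) abort("Sequences must be non-empty.")
  mat <- substitution_matrix(matrix)
  a <- toupper(a); b <- toupper(b)
  check_alphabet(a, mat); check_alphabet(b, mat)
  A <- matrix(split_residues(a), nrow = 1, dimnames = list("a", NULL))
  B <- matrix(split_residues(b), nrow = 1, dimnames = list("b", NULL))
  al <- profile_align(A, B, mat, gap_open, gap_extend)
  ra <- al$rows[1, ]; rb <- al$rows[2, ]
  list(
    a_aligned = paste(ra, collapse = ""),
    b_aligned = paste(rb, collapse = ""),
    score = al$score,
    identity = sum(ra == rb & ra != "-") / length(ra)
  )
}

# ---- UPGMA guide tree -------------------------------------------------------

#' Build a UPGMA guide tree for progressive alignment
#'
#' Clusters sequences by average linkage on normalized pairwise alignment
#' distances (1 - identity of the global pairwise alignment). Ties are broken
#' by the lexicographically smallest pair of cluster representative ids, so
#' the merge order is deterministic.
#'
#' @param seqs Named character vector or record tibble.
#' @inheritParams pairwise_global
#' @return A `guide_tree`: nested merge list (leaves are ids, internal nodes
#'   `list(left, right, height)`) with a `merges` tibble attribute.
#' @export
guide_tree <- function(seqs, matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  seqs <- as_named_sequences(seqs)
  n <- length(seqs)
  if (n < 2) abort("Guide tree needs at least 2 sequences.")
  ids <- names(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- pairwise_global(seqs[[i]], seqs[[j]], matrix, gap_open, gap_extend)$identity
      D[i, j] <- D[j, i] <- 1 - pid
    }
  }
  upgma_tree(D)
}

# average-linkage agglomeration with deterministic lexicographic tie-break
upgma_tree <- function(D) {
  ids <- rownames(D)
  nodes <- as.list(ids)
  reps <- ids # lexicographic representative (smallest member id)
  sizes <- rep(1L, length(ids))
  merges <- list()
  while (length(nodes) > 1) {
    k <- length(nodes)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        key <- sort(c(reps[i], reps[j]))
        cand <- list(d = D[i, j], key = key, i = i, j = j)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    node <- list(left = nodes[[i]], right = nodes[[j]], height = best$d / 2)
    merges[[length(merges) + 1L]] <- tibble(
      step = length(merges) + 1L,
      left = paste(tree_ids(nodes[[i]]), collapse = ","),
      right = paste(tree_ids(nodes[[j]]), collapse = ","),
      distance = best$d
    )
    newd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nodes <- c(nodes[keep], list(node))
    reps <- c(reps[keep], min(best$key))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    dimnames(D) <- NULL
  }
  structure(nodes[[1]], class = "guide_tree",
            merges = dplyr::bind_rows(merges))
}

tree_ids <- function(node) {
  if (is.character(node)) return(node)
  c(tree_ids(node$left), tree_ids(node$right))
}

#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: pairwise identity distances feed a
#' UPGMA guide tree, and profiles are merged bottom-up with affine-gap
#' profile-profile alignment under average-linkage column scores. Gaps, once
#' introduced, are never removed ("once a gap, always a gap").
#'
#' @param seqs Named character vector of (mature) sequences, or a record
#'   tibble with `id` and `mature_sequence`.
#' @inheritParams pairwise_global
#' @param tree Optional precomputed [guide_tree()].
#' @return An `evasin_msa`, rows in input order.
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5, tree = NULL) {
  seqs <- as_named_sequences(seqs)
  if (length(seqs) == 0) abort("No sequences to align.")
  mat <- substitution_matrix(matrix)
  for (s in seqs) check_alphabet(s, mat)
  if (length(seqs) == 1) {
    rows <- matrix(split_residues(seqs[[1]]), nrow = 1,
                   dimnames = list(names(seqs), NULL))
    return(new_msa(rows))
  }
  tree <- tree %||% guide_tree(seqs, matrix, gap_open, gap_extend)
  build <- function(node) {
    if (is.character(node)) {
      return(matrix(split_residues(seqs[[node]]), nrow = 1,
                    dimnames = list(node, NULL)))
    }
    profile_align(build(node$left), build(node$right),
                  mat, gap_open, gap_extend)$rows
  }
  rows <- build(unclass(tree))
  rows <- rows[names(seqs), , drop = FALSE] # restore input order
  new_msa(rows)
}
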