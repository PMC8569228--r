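#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#' With `seed = NULL` the expression runs on the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# derive a stage seed from a top-level seed; keeps values within 32-bit range
derive_seed <- function(seed, stage_index) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) * 97L + stage_index * 1009L) %% 2147483647L
}

# draw one element from a vector (safe for length-1 vectors, unlike sample())
sample_one <- function(x) {
  x[sample.int(length(x), 1L)]
}

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", name))
  }
  invisible(x)
}

# uppercase amino-acid sequence split into residues
split_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

join_residues <- function(residues) {
  paste(residues, collapse = "")
}

#' Load a substitution matrix by name
#'
#' Retrieves one of the protein substitution matrices shipped with
#' Biostrings (BLOSUM and PAM families).
#'
#' @param name Matrix name, e.g. `"BLOSUM62"` (case-insensitive).
#' @return A numeric substitution matrix with residue dimnames.
#' @export
#' @examples
#' m <- substitution_matrix("BLOSUM62")
#' m["C", "C"]
substitution_matrix <- function(name = "BLOSUM62") {
  assert_scalar_string(name, "name")
  name <- toupper(name)
  available <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                 "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% available) {
    abort(sprintf("Unknown substitution matrix '%s'. Available: %s.",
                  name, paste(available, collapse = ", ")))
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

# residues of `sequence` not covered by the matrix alphabet
check_alphabet <- function(sequence, matrix, allow_map_unknown = FALSE) {
  res <- unique(split_residues(sequence))
  unknown <- setdiff(res, rownames(matrix))
  if (length(unknown) > 0 && !allow_map_unknown) {
    abort(sprintf("Unknown residue(s) for substitution matrix: %s.",
                  paste(unknown, collapse = ", ")))
  }
  unknown
}
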