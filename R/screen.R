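#' Configuration for the homology screen
#'
#' Parameters of the local-alignment screen used in place of a full blastp
#' search: substitution matrix, affine gap penalties, Karlin-Altschul
#' statistics and the E-value keep threshold.
#'
#' @param matrix Substitution matrix name (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param karlin_k,karlin_lambda Karlin-Altschul `K` and `lambda`
#'   (natural-log units); defaults are typical of gapped BLOSUM62 statistics.
#' @param evalue_threshold Candidates are kept iff their best E-value is
#'   strictly below this threshold.
#' @param search_space_m,search_space_n Effective query/database lengths;
#'   `NULL` uses the actual lengths of each compared pair.
#' @return A `screen_config` list.
#' @export
screen_config <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          karlin_k = 0.041, karlin_lambda = 0.267,
                          evalue_threshold = 1e-4,
                          search_space_m = NULL, search_space_n = NULL) {
  if (gap_open <= 0 || gap_extend <= 0) abort("Gap penalties must be positive.")
  if (karlin_k <= 0 || karlin_lambda <= 0) abort("Karlin-Altschul K and lambda must be positive.")
  if (evalue_threshold <= 0) abort("`evalue_threshold` must be positive.")
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         karlin_k = karlin_k, karlin_lambda = karlin_lambda,
         evalue_threshold = evalue_threshold,
         search_space_m = search_space_m, search_space_n = search_space_n),
    class = "screen_config"
  )
}

#' Smith-Waterman local alignment of two sequences
#'
#' Optimal local alignment under affine gap penalties. When every pairing
#' scores negatively the optimal local alignment is empty: score 0 and an
#' empty span.
#'
#' @param a,b Amino-acid strings.
#' @param config A [screen_config()].
#' @param map_unknown Map residues missing from the matrix to a neutral
#'   score of 0 instead of erroring.
#' @return One-row tibble: `score`, `evalue`, span columns `a_start`,
#'   `a_end`, `b_start`, `b_end` (1-based inclusive; NA for an empty span)
#'   and the aligned strings `a_aligned`, `b_aligned`.
#' @export
#' @examples
#' sw_align("CCK", "CCK")$score # 9 + 9 + 5 on the BLOSUM62 diagonal
sw_align <- function(a, b, config = screen_config(), map_unknown = FALSE) {
  assert_scalar_string(a, "a")
  assert_scalar_string(b, "b")
  mat <- substitution_matrix(config$matrix)
  a <- toupper(a); b <- toupper(b)
  unk <- unique(c(check_alphabet(a, mat, map_unknown), check_alphabet(b, mat, map_unknown)))
  if (length(unk) > 0) {
    # extend the matrix with neutral rows/columns for the unknown residues
    ext <- matrix(0, nrow(mat) + length(unk), ncol(mat) + length(unk),
                  dimnames = list(c(rownames(mat), unk), c(colnames(mat), unk)))
    ext[rownames(mat), colnames(mat)] <- mat
    mat <- ext
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend
  )
  score <- Biostrings::score(pa)
  if (score <= 0) {
    out <- tibble(score = 0, a_start = NA_integer_, a_end = NA_integer_,
                  b_start = NA_integer_, b_end = NA_integer_,
                  a_aligned = "", b_aligned = "")
  } else {
    out <- tibble(
      score = score,
      a_start = Biostrings::start(Biostrings::pattern(pa)),
      a_end = Biostrings::end(Biostrings::pattern(pa)),
      b_start = Biostrings::start(Biostrings::subject(pa)),
      b_end = Biostrings::end(Biostrings::subject(pa)),
      a_aligned = as.character(Biostrings::alignedPattern(pa)),
      b_aligned = as.character(Biostrings::alignedSubject(pa))
    )
  }
  out$evalue <- karlin_evalue(out$score, config,
                              m = config$search_space_m %||% nchar(a),
                              n = config$search_space_n %||% nchar(b))
  out
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score at least `S` between random sequences of lengths `m`
#' and `n`.
#'
#' @param score Alignment score(s) in matrix units.
#' @param config A [screen_config()] carrying `K` and `lambda`.
#' @param m,n Effective query and database/sequence lengths.
#' @return E-value(s), monotone decreasing in the score.
#' @export
karlin_evalue <- function(score, config = screen_config(), m = NULL, n = NULL) {
  m <- m %||% config$search_space_m
  n <- n %||% config$search_space_n
  if (is.null(m) || is.null(n)) {
    abort("Search space (m, n) must be set in the config or passed explicitly.")
  }
  config$karlin_k * m * n * exp(-config$karlin_lambda * score)
}

#' Screen candidates against a query set
#'
#' Aligns every candidate mature sequence against every query; a candidate
#' is kept iff its best (smallest) E-value is strictly below the configured
#' threshold. The best-scoring query labels the candidate (`query_class`
#' when the query table carries a `class` column), mirroring separate
#' class-A and class-B searches.
#'
#' @param candidates Record tibble with `id` and `mature_sequence` (or a
#'   named character vector).
#' @param queries Tibble with `id`, `sequence` and optionally `class`, or a
#'   named character vector.
#' @param config A [screen_config()].
#' @return List with `kept` (candidate ids passing the screen), `hits`
#'   (best hit per candidate: `id`, `query`, `query_class`, `score`,
#'   `evalue`, `kept`).
#' @export
screen_candidates <- function(candidates, queries, config = screen_config()) {
  cand <- as_named_sequences(candidates)
  if (length(cand) == 0 || (is.data.frame(queries) && nrow(queries) == 0)) {
    abort("Both candidate and query sets must be non-empty.")
  }
  if (is.data.frame(queries)) {
    qseq <- setNames(toupper(queries$sequence), queries$id)
    qclass <- if ("class" %in% names(queries)) setNames(queries$class, queries$id) else NULL
  } else {
    qseq <- as_named_sequences(queries)
    qclass <- NULL
  }
  if (length(qseq) == 0) abort("Both candidate and query sets must be non-empty.")
  hits <- purrr::map_dfr(names(cand), function(cid) {
    per_query <- purrr::map_dfr(names(qseq), function(qid) {
      al <- sw_align(cand[[cid]], qseq[[qid]], config)
      tibble(id = cid, query = qid, score = al$score, evalue = al$evalue)
    })
    best <- per_query[order(per_query$evalue, per_query$query), ][1, ]
    best
  })
  hits$query_class <- if (is.null(qclass)) NA_character_ else unname(qclass[hits$query])
  hits$kept <- hits$evalue < config$evalue_threshold
  list(
    kept = hits$id[hits$kept],
    hits = hits[, c("id", "query", "query_class", "score", "evalue", "kept")]
  )
}

#' Collapse records with identical mature sequences
#'
#' Distinct-sequence rule: byte-identical mature sequences collapse to one
#' representative, the lexicographically smallest id.
#'
#' @param records Record tibble with `id` and `mature_sequence`.
#' @return List with `distinct` (representative rows, input order of first
#'   appearance of each representative) and `collapse_map` (tibble `id` ->
#'   `representative`).
#' @export
deduplicate_records <- function(records) {
  seqs <- as_named_sequences(records)
  rep_of <- tapply(names(seqs), unname(seqs), function(ids) min(ids))
  map <- tibble(
    id = names(seqs),
    representative = as.character(rep_of[unname(seqs)])
  )
  keep_ids <- unique(map$representative)
  distinct_rows <- if (is.data.frame(records)) {
    records[records$id %in% keep_ids, , drop = FALSE]
  } else {
    tibble(id = keep_ids, mature_sequence = unname(seqs[keep_ids]))
  }
  list(distinct = distinct_rows, collapse_map = map)
}
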