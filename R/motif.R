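#' Compile a PROSITE-style cysteine-spacing pattern
#'
#' Parses patterns of the form `"C-x(3)-C-x(6,10)-C"`: fixed anchor residues
#' separated by `x(n)` or `x(n,m)` gaps of arbitrary residues. This is the
#' pattern language used to describe evasin cysteine frameworks; `x` matches
#' any residue, including cysteine, so extra cysteines inside a gap never
#' block a match. Whitespace anywhere in the pattern is ignored.
#'
#' @param pattern Pattern string.
#' @param name Motif name; defaults to the normalized pattern string.
#' @return A `motif_definition` object: anchors, gap ranges, span bounds.
#' @seealso [cys6_motif()], [cys8_motif()], [scan_motif()]
#' @export
#' @examples
#' m <- parse_prosite("C-x(3)-C")
#' m$min_span # 6 residues: two anchors + a gap of exactly 3
parse_prosite <- function(pattern, name = NULL) {
  assert_scalar_string(pattern, "pattern")
  cleaned <- gsub("[[:space:]]+", "", pattern)
  tokens <- strsplit(cleaned, "-", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    abort("Empty pattern.")
  }
  anchors <- character()
  gaps <- list()
  pending_gap <- NULL # accumulated gap since last anchor
  seen_anchor <- FALSE
  for (tok in tokens) {
    if (grepl("^[A-Z]$", tok) && tok != "x" && tok != "X") {
      if (seen_anchor) {
        gaps[[length(gaps) + 1L]] <- pending_gap %||% c(0L, 0L)
      } else if (!is.null(pending_gap)) {
        abort(sprintf("Pattern may not start with a gap token (before anchor '%s').", tok))
      }
      anchors <- c(anchors, tok)
      pending_gap <- NULL
      seen_anchor <- TRUE
    } else if (grepl("^[xX]\\(\\d+(,\\d+)?\\)$", tok)) {
      nums <- as.integer(strsplit(gsub("^[xX]\\(|\\)$", "", tok), ",")[[1]])
      rng <- if (length(nums) == 1L) c(nums, nums) else nums
      if (rng[1] > rng[2]) {
        abort(sprintf("Malformed gap token '%s': min exceeds max.", tok))
      }
      pending_gap <- (pending_gap %||% c(0L, 0L)) + rng
    } else {
      abort(sprintf("Malformed pattern token '%s'.", tok))
    }
  }
  if (!is.null(pending_gap)) {
    abort("Pattern may not end with a gap token.")
  }
  if (length(anchors) < 2L) {
    abort("A motif needs at least 2 anchor residues.")
  }
  gap_min <- vapply(gaps, `[`, integer(1), 1L)
  gap_max <- vapply(gaps, `[`, integer(1), 2L)
  normalized <- paste(
    c(rbind(anchors[-length(anchors)],
            ifelse(gap_min == gap_max,
                   sprintf("x(%d)", gap_min),
                   sprintf("x(%d,%d)", gap_min, gap_max))),
      anchors[length(anchors)]),
    collapse = "-"
  )
  structure(
    list(
      name = name %||% normalized,
      anchors = anchors,
      gap_min = gap_min,
      gap_max = gap_max,
      min_span = length(anchors) + sum(gap_min),
      max_span = length(anchors) + sum(gap_max),
      pattern = normalized
    ),
    class = "motif_definition"
  )
}

#' @export
format.motif_definition <- function(x, ...) {
  sprintf("<motif_definition %s: %s (span %d-%d)>",
          x$name, x$pattern, x$min_span, x$max_span)
}

#' @export
print.motif_definition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Built-in evasin cysteine-framework motifs
#'
#' `cys6_motif()` is the six-cysteine knottin framework characteristic of
#' CXC-chemokine-binding (class B) evasins; `cys8_motif()` is the
#' eight-cysteine framework of the four-disulfide core of CC-chemokine-binding
#' (class A1) evasins.
#'
#' @return A `motif_definition`.
#' @export
cys6_motif <- function() {
  parse_prosite("C-x(3)-C-x(6,10)-C-x(3,6)-C-x(1)-C-x(10,11)-C", name = "cys6")
}

#' @rdname cys6_motif
#' @export
cys8_motif <- function() {
  parse_prosite("C-x(14,17)-C-x(3)-C-x(11,16)-C-x(17,20)-C-x(4)-C-x(4,5)-C-x(8)-C",
                name = "cys8")
}

# resolve "cys6"/"cys8"/motif_definition to a motif_definition
as_motif <- function(motif) {
  if (inherits(motif, "motif_definition")) {
    return(motif)
  }
  if (is.character(motif) && length(motif) == 1L) {
    return(switch(motif,
      cys6 = cys6_motif(),
      cys8 = cys8_motif(),
      parse_prosite(motif)
    ))
  }
  abort("`motif` must be a motif_definition, a built-in name, or a pattern string.")
}

#' Scan a sequence for all occurrences of a spacing motif
#'
#' Enumerates every tuple of anchor positions compatible with the motif's gap
#' ranges, in leftmost-start then shortest-gap order. Overlapping matches at
#' distinct start anchors, and alternative gap choices from the same start,
#' are all reported.
#'
#' @param sequence A single amino-acid string (upper-case).
#' @param motif A `motif_definition`, a built-in name (`"cys6"`, `"cys8"`),
#'   or a pattern string.
#' @return A tibble with one row per match: `motif`, `start`, `end`
#'   (1-based, inclusive) and a list-column `anchors` of anchor positions.
#' @export
#' @examples
#' seq <- paste0("C", "AAA", "C") # minimal C-x(3)-C
#' scan_motif(seq, "C-x(3)-C")
scan_motif <- function(sequence, motif) {
  assert_scalar_string(sequence, "sequence")
  motif <- as_motif(motif)
  res <- split_residues(toupper(sequence))
  n <- length(res)
  k <- length(motif$anchors)
  hits <- list()
  if (n >= motif$min_span) {
    starts <- which(res == motif$anchors[1])
    for (s in starts) {
      hits <- c(hits, match_from(res, n, motif, k, c(s)))
    }
  }
  tibble(
    motif = rep(motif$name, length(hits)),
    start = vapply(hits, `[`, integer(1), 1L),
    end = vapply(hits, function(h) h[length(h)], integer(1)),
    anchors = hits
  )
}

# depth-first enumeration of anchor tuples; gaps tried in increasing order
match_from <- function(res, n, motif, k, positions) {
  depth <- length(positions)
  if (depth == k) {
    return(list(positions))
  }
  p <- positions[depth]
  out <- list()
  for (g in motif$gap_min[depth]:motif$gap_max[depth]) {
    q <- p + g + 1L
    if (q > n) break
    if (res[q] == motif$anchors[depth + 1L]) {
      out <- c(out, match_from(res, n, motif, k, c(positions, q)))
    }
  }
  out
}

#' Profile sequences for cysteine counts and framework motifs
#'
#' Produces the per-sequence annotation columns drawn as heatmap rings around
#' the classification trees: total cysteine count and presence/absence of
#' each framework motif.
#'
#' @param records A tibble with `id` and `mature_sequence` columns, or a
#'   named character vector of sequences.
#' @param motifs List of motifs (definitions or built-in names); defaults to
#'   the Cys6 and Cys8 frameworks.
#' @return A tibble with `id`, `cys_count`, and one logical `has_<name>`
#'   column per motif.
#' @export
profile_motifs <- function(records, motifs = list(cys6_motif(), cys8_motif())) {
  seqs <- as_named_sequences(records)
  motifs <- lapply(motifs, as_motif)
  out <- tibble(
    id = names(seqs),
    cys_count = stringr::str_count(unname(seqs), stringr::fixed("C"))
  )
  for (m in motifs) {
    out[[paste0("has_", m$name)]] <-
      vapply(unname(seqs), function(s) nrow(scan_motif(s, m)) > 0L, logical(1),
             USE.NAMES = FALSE)
  }
  out
}

# accept a records tibble (id + mature_sequence/sequence) or named character
as_named_sequences <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records)) || anyNA(names(records)) || any(!nzchar(names(records)))) {
      abort("Character input must be a named vector of sequences.")
    }
    return(toupper(records))
  }
  if (is.data.frame(records)) {
    seq_col <- intersect(c("mature_sequence", "sequence", "raw_sequence"),
                         names(records))[1]
    if (is.na(seq_col) || !"id" %in% names(records)) {
      abort("Records must have an `id` column and a sequence column.")
    }
    return(setNames(toupper(records[[seq_col]]), records$id))
  }
  abort("Unsupported records input.")
}
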