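#' Read precursor proteins from FASTA into a record table
#'
#' One row per FASTA entry, in file order. `key=value` pairs in the header
#' (e.g. `genus=Ixodes species=ricinus`) are parsed into columns; the first
#' whitespace-delimited token is the record id. Sequences are upper-cased.
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `genus`, `species`, `lineage` (NA when absent),
#'   `raw_sequence`, and bookkeeping columns `protein_start`, `mature_start`,
#'   `mature_sequence`, `status` initialised to NA/"raw".
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  validate_fasta_lines(path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0) {
    warn(sprintf("Empty FASTA file: %s", path))
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate record id(s) in %s: %s", path, paste(dup, collapse = ", ")))
  }
  attr_of <- function(header, key) {
    m <- stringr::str_match(header, paste0("\\b", key, "=(\\S+)"))[, 2]
    m
  }
  tibble(
    id = ids,
    genus = attr_of(headers, "genus"),
    species = attr_of(headers, "species"),
    lineage = attr_of(headers, "lineage"),
    raw_sequence = unname(toupper(as.character(x))),
    protein_start = NA_integer_,
    mature_start = NA_integer_,
    mature_sequence = NA_character_,
    status = rep("raw", length(x))
  )
}

# minimal structural FASTA validation with line numbers (Biostrings' own
# parser reports errors without location)
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) return(invisible(TRUE))
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf("Malformed FASTA at line %d of %s: expected '>' header.", first, path))
  }
  hdrs <- which(startsWith(lines, ">"))
  for (h in hdrs) {
    if (!nzchar(trimws(sub("^>", "", lines[h])))) {
      abort(sprintf("Malformed FASTA at line %d of %s: empty header.", h, path))
    }
    nxt <- if (h == length(lines)) "" else lines[h + 1]
    if (h == length(lines) || startsWith(nxt, ">") || !nzchar(trimws(nxt))) {
      abort(sprintf("Malformed FASTA at line %d of %s: header without sequence.", h, path))
    }
  }
  invisible(TRUE)
}

#' Locate the protein start (first methionine)
#'
#' The first Met in each raw sequence marks the protein start site; records
#' without any Met are flagged `no_met`.
#'
#' @param records Record tibble from [read_protein_fasta()].
#' @return The tibble with `protein_start` and `status` updated.
#' @export
locate_protein_start <- function(records) {
  pos <- stringr::str_locate(records$raw_sequence, stringr::fixed("M"))[, "start"]
  records$protein_start <- as.integer(pos)
  records$status <- ifelse(is.na(pos), "no_met", records$status)
  records
}

#' Signal-peptide cleavage providers
#'
#' A cleavage provider is a function `(sequence_from_met, id) -> offset`
#' returning the 1-based offset of the first mature residue within the
#' Met-initiated protein, or `NA` when no signal peptide is predicted.
#'
#' `cleavage_table()` backs the contract with a table of known cleavage
#' positions (e.g. exported from a signal-peptide predictor): `mature_start`
#' is the 1-based position of the first mature residue in the raw precursor
#' sequence. Records absent from the table are treated as having no signal
#' peptide.
#'
#' `cleavage_heuristic()` predicts a cleavage site when the residues
#' immediately after the initiator Met form an uninterrupted hydrophobic run
#' (A/I/L/V/F/M/W) of at least `min_run` residues; the mature protein starts
#' right after the run. The run search is capped at `window` residues.
#'
#' @param table A TSV path or a data frame with columns `id`, `mature_start`.
#' @param min_run Minimum hydrophobic run length for a signal peptide.
#' @param window Maximum signal-peptide length considered.
#' @return A function of class `cleavage_provider`.
#' @export
cleavage_table <- function(table) {
  if (is.character(table)) {
    table <- readr::read_tsv(table, show_col_types = FALSE)
  }
  if (!all(c("id", "mature_start") %in% names(table))) {
    abort("Cleavage table needs columns `id` and `mature_start`.")
  }
  lookup <- setNames(as.integer(table$mature_start), table$id)
  structure(
    function(sequence, id, protein_start = 1L) {
      ms <- unname(lookup[id])
      if (is.na(ms)) return(NA_integer_)
      ms - protein_start + 1L
    },
    class = c("cleavage_provider", "function"),
    provider = "table"
  )
}

#' @rdname cleavage_table
#' @export
cleavage_heuristic <- function(min_run = 8L, window = 40L) {
  structure(
    function(sequence, id, protein_start = 1L) {
      res <- split_residues(sequence)
      if (length(res) < 2L || res[1] != "M") return(NA_integer_)
      run <- 0L
      i <- 2L
      while (i <= min(length(res), window) && res[i] %in% HYDROPHOBIC) {
        run <- run + 1L
        i <- i + 1L
      }
      if (run >= min_run) i else NA_integer_
    },
    class = c("cleavage_provider", "function"),
    provider = "heuristic"
  )
}

#' Derive mature proteins via a cleavage provider
#'
#' Consults the provider on each Met-initiated protein. On a predicted
#' cleavage the record gets `mature_start` (1-based in the raw sequence) and
#' `mature_sequence`; with no signal peptide the record is flagged
#' `no_signal`. Records already flagged (e.g. `no_met`) pass through
#' untouched.
#'
#' @param records Record tibble after [locate_protein_start()].
#' @param provider A [cleavage_table()] or [cleavage_heuristic()] provider.
#' @return Updated record tibble.
#' @export
derive_mature <- function(records, provider) {
  stopifnot(inherits(provider, "cleavage_provider"))
  for (i in seq_len(nrow(records))) {
    if (records$status[i] != "raw") next
    ps <- records$protein_start[i]
    if (is.na(ps)) abort("`protein_start` missing; run locate_protein_start() first.")
    protein <- substr(records$raw_sequence[i], ps, nchar(records$raw_sequence[i]))
    off <- provider(protein, records$id[i], protein_start = ps)
    if (is.na(off)) {
      records$status[i] <- "no_signal"
      next
    }
    if (off < 2L || off > nchar(protein)) {
      abort(sprintf("Cleavage offset %d out of range for record %s (protein length %d).",
                    off, records$id[i], nchar(protein)))
    }
    records$mature_start[i] <- ps + off - 1L
    records$mature_sequence[i] <- substr(records$raw_sequence[i],
                                         records$mature_start[i],
                                         nchar(records$raw_sequence[i]))
    records$status[i] <- "ok"
  }
  records
}

#' Apply the record filters (signal peptide and stop codons)
#'
#' Keeps records with a derived mature protein free of stop codons; drops
#' records with no Met, no signal peptide, or a `*` anywhere in the mature
#' sequence. Stop codons upstream of the mature start never drop a record —
#' the filter applies to the predicted mature protein only.
#'
#' @param records Record tibble after [derive_mature()].
#' @return List with `kept` (status `ok`) and `dropped` (tibble `id`,
#'   `reason`).
#' @export
filter_records <- function(records) {
  records$status <- ifelse(
    records$status == "ok" & stringr::str_detect(records$mature_sequence, stringr::fixed("*")),
    "internal_stop", records$status
  )
  kept <- records |> filter(.data$status == "ok")
  dropped <- records |>
    filter(.data$status != "ok") |>
    select("id", reason = "status")
  counts <- table(records$status)
  inform(sprintf("filter_records: %d kept, %d dropped (%s)",
                 nrow(kept), nrow(dropped),
                 paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", ")))
  list(kept = kept, dropped = dropped)
}
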