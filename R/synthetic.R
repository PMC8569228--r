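#' Configuration for the synthetic evasin dataset generator
#'
#' Describes a two-lineage synthetic dataset: each lineage descends from its
#' own ancestral mature protein, members accumulate substitutions within the
#' lineage, and the two ancestors differ at a higher between-lineage rate, so
#' that a neighbour-joining tree rooted at its midpoint recovers the lineage
#' split. Cysteine-framework motifs can be planted in either lineage; decoy
#' records exercise the ingest and homology filters.
#'
#' @param n_class1,n_class2 Number of sequences per lineage.
#' @param motif_class1,motif_class2 Motif planted in each lineage: `"cys8"`,
#'   `"cys6"` or `"none"`.
#' @param mature_length Mature-protein length in residues.
#' @param signal_length Signal-peptide length including the initiator Met.
#' @param substitution_rate_within Expected substitutions per non-anchor site
#'   between a lineage member and its ancestor.
#' @param substitution_rate_between Expected substitutions per non-anchor site
#'   between the two lineage ancestors; must exceed the within rate.
#' @param n_decoy_no_signal,n_decoy_stop,n_decoy_unrelated Decoy counts:
#'   records lacking a signal peptide, records with a stop codon in the
#'   mature region, and records unrelated to either lineage.
#' @param genus_class1,species_class1,lineage_class1 Taxonomy attached to
#'   lineage-1 records (defaults: Rhipicephalus sanguineus, Metastriate).
#' @param genus_class2,species_class2,lineage_class2 Taxonomy for lineage 2
#'   (defaults: Ixodes ricinus, Prostriate).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_class1 = 10, n_class2 = 10,
                             motif_class1 = "cys8", motif_class2 = "none",
                             mature_length = 90, signal_length = 20,
                             substitution_rate_within = 0.05,
                             substitution_rate_between = 0.40,
                             n_decoy_no_signal = 1, n_decoy_stop = 1,
                             n_decoy_unrelated = 1,
                             genus_class1 = "Rhipicephalus",
                             species_class1 = "sanguineus",
                             lineage_class1 = "Metastriate",
                             genus_class2 = "Ixodes",
                             species_class2 = "ricinus",
                             lineage_class2 = "Prostriate",
                             seed = NULL) {
  cfg <- list(
    n_class1 = as.integer(n_class1), n_class2 = as.integer(n_class2),
    motif_class1 = motif_class1, motif_class2 = motif_class2,
    mature_length = as.integer(mature_length),
    signal_length = as.integer(signal_length),
    substitution_rate_within = substitution_rate_within,
    substitution_rate_between = substitution_rate_between,
    n_decoy_no_signal = as.integer(n_decoy_no_signal),
    n_decoy_stop = as.integer(n_decoy_stop),
    n_decoy_unrelated = as.integer(n_decoy_unrelated),
    genus_class1 = genus_class1, species_class1 = species_class1,
    lineage_class1 = lineage_class1,
    genus_class2 = genus_class2, species_class2 = species_class2,
    lineage_class2 = lineage_class2,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  counts <- c(cfg$n_class1, cfg$n_class2, cfg$n_decoy_no_signal,
              cfg$n_decoy_stop, cfg$n_decoy_unrelated)
  if (any(counts < 0)) abort("All counts must be >= 0.")
  rates <- c(cfg$substitution_rate_within, cfg$substitution_rate_between)
  if (any(rates < 0 | rates > 1)) abort("Substitution rates must lie in [0, 1].")
  if (cfg$substitution_rate_within >= cfg$substitution_rate_between) {
    abort("Within-lineage rate must be below the between-lineage rate (planted-partition recoverability).")
  }
  for (m in c(cfg$motif_class1, cfg$motif_class2)) {
    if (identical(m, "none")) next
    span <- as_motif(m)$max_span
    if (cfg$mature_length < span) {
      abort(sprintf("mature_length %d is below the maximal span (%d) of motif '%s'.",
                    cfg$mature_length, span, m))
    }
  }
  if (cfg$signal_length < 2L) abort("signal_length must be >= 2 (Met + at least one residue).")
  structure(cfg, class = "synthetic_config")
}

#' Generate a mature sequence with one planted motif occurrence
#'
#' Samples anchor spacings uniformly within each gap range, places the motif
#' at a random offset, and fills every non-anchor position from the 19-letter
#' non-cysteine alphabet, so the planted anchor tuple is the only possible
#' match.
#'
#' @param length Sequence length in residues.
#' @param motif Motif definition or built-in name.
#' @param seed Optional RNG seed.
#' @return List with `sequence` (string) and `anchors` (integer positions).
#' @export
#' @examples
#' p <- plant_motif(40, "cys6", seed = 1)
#' nrow(scan_motif(p$sequence, "cys6")) # exactly one hit
plant_motif <- function(length, motif, seed = NULL) {
  motif <- as_motif(motif)
  length <- as.integer(length)
  if (length < motif$min_span) {
    abort(sprintf("Sequence length %d is below the minimal span of motif '%s' (%d residues required).",
                  length, motif$name, motif$min_span))
  }
  with_seed(seed, plant_motif_impl(length, motif))
}

plant_motif_impl <- function(length, motif) {
  k <- length(motif$anchors)
  gaps <- motif$gap_min
  # sample gaps uniformly, shrinking from the last gap if the span overflows
  for (i in seq_along(gaps)) {
    gaps[i] <- sample_one(motif$gap_min[i]:motif$gap_max[i])
  }
  over <- (k + sum(gaps)) - length
  i <- length(gaps)
  while (over > 0 && i >= 1) {
    give <- min(over, gaps[i] - motif$gap_min[i])
    gaps[i] <- gaps[i] - give
    over <- over - give
    i <- i - 1L
  }
  span <- k + sum(gaps)
  offset <- if (length > span) sample_one(0:(length - span)) else 0L
  anchors <- offset + cumsum(c(1L, gaps + 1L))
  res <- sample(AA19_NOCYS, length, replace = TRUE)
  res[anchors] <- motif$anchors
  list(sequence = join_residues(res), anchors = anchors)
}

# build a mature body for one lineage ancestor; position 1 is pinned to a
# polar residue (unless it is a motif anchor) so the cleavage heuristic can
# recover the exact signal/mature boundary
make_ancestor <- function(cfg, motif_name) {
  if (identical(motif_name, "none")) {
    res <- sample(AA19_NOCYS, cfg$mature_length, replace = TRUE)
    anchors <- integer(0)
  } else {
    p <- plant_motif_impl(cfg$mature_length, as_motif(motif_name))
    res <- split_residues(p$sequence)
    anchors <- p$anchors
  }
  if (!1L %in% anchors) res[1] <- sample(POLAR, 1L)
  list(res = res, anchors = anchors)
}

# substitute residues at `rate` per site, never touching anchors; position 1
# stays polar when mutated
mutate_body <- function(res, rate, anchors) {
  if (rate <= 0) return(res)
  free <- setdiff(seq_along(res), anchors)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) {
    pool <- if (i == 1L) setdiff(POLAR, res[i]) else setdiff(AA19_NOCYS, res[i])
    res[i] <- sample(pool, 1L)
  }
  res
}

evolve_core <- function(cfg) {
  anc1 <- make_ancestor(cfg, cfg$motif_class1)
  if (identical(cfg$motif_class1, cfg$motif_class2)) {
    res2 <- mutate_body(anc1$res, cfg$substitution_rate_between, anc1$anchors)
    anc2 <- list(res = res2, anchors = anc1$anchors)
  } else {
    # strip lineage-1 anchors, plant the lineage-2 framework, then diverge
    res2 <- anc1$res
    res2[anc1$anchors] <- sample(AA19_NOCYS, length(anc1$anchors), replace = TRUE)
    if (identical(cfg$motif_class2, "none")) {
      anchors2 <- integer(0)
    } else {
      p <- plant_motif_impl(cfg$mature_length, as_motif(cfg$motif_class2))
      anchors2 <- p$anchors
      res2[anchors2] <- "C"
    }
    if (!1L %in% anchors2) res2[1] <- sample(POLAR, 1L)
    res2 <- mutate_body(res2, cfg$substitution_rate_between, anchors2)
    anc2 <- list(res = res2, anchors = anchors2)
  }
  members <- function(anc, n, lineage, motif_name) {
    purrr::map(seq_len(n), function(i) {
      res <- mutate_body(anc$res, cfg$substitution_rate_within, anc$anchors)
      list(lineage = lineage, motif = motif_name,
           mature_sequence = join_residues(res), anchors = anc$anchors)
    })
  }
  list(
    ancestors = list(anc1 = anc1, anc2 = anc2),
    members = c(
      members(anc1, cfg$n_class1, cfg$lineage_class1, cfg$motif_class1),
      members(anc2, cfg$n_class2, cfg$lineage_class2, cfg$motif_class2)
    )
  )
}

#' Simulate two diverged lineages of mature evasin-like proteins
#'
#' Generates the two lineage ancestors (differing at the between-lineage
#' substitution rate on non-anchor sites) and the lineage members (each the
#' ancestor mutated at the within-lineage rate). Motif anchor cysteines are
#' never mutated.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with `lineage`, `motif`, `mature_sequence` and an
#'   `anchors` list-column; the ancestors are attached as attribute
#'   `"ancestors"` (named character vector of mature sequences).
#' @export
evolve_lineages <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ev <- with_seed(config$seed, evolve_core(config))
  out <- purrr::map_dfr(ev$members, function(m) {
    tibble(lineage = m$lineage, motif = m$motif,
           mature_sequence = m$mature_sequence, anchors = list(m$anchors))
  })
  attr(out, "ancestors") <- c(
    ancestor1 = join_residues(ev$ancestors$anc1$res),
    ancestor2 = join_residues(ev$ancestors$anc2$res)
  )
  out
}

random_signal <- function(cfg) {
  join_residues(sample(HYDROPHOBIC, cfg$signal_length - 1L, replace = TRUE))
}

#' Generate a full synthetic dataset (FASTA + cleavage + truth tables)
#'
#' Assembles precursor records (`M` + hydrophobic signal + mature body) for
#' both lineages, adds decoys (no signal peptide, internal stop codon,
#' unrelated sequence), and emits the ground truth needed to validate every
#' downstream stage. The two lineage ancestors are written as the query set
#' standing in for biochemically characterized evasins.
#'
#' @param config A [synthetic_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.fasta`, `<prefix>_queries.fasta`, `<prefix>_cleavage.tsv` and
#'   `<prefix>_truth.tsv`.
#' @return List with tibbles `records` (id, genus, species, lineage,
#'   sequence), `truth`, `cleavage`, `queries`, and `paths` (when written).
#' @export
generate_dataset <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  data <- with_seed(config$seed, generate_core(config))
  if (!is.null(out_prefix)) {
    paths <- list(
      fasta = paste0(out_prefix, ".fasta"),
      queries = paste0(out_prefix, "_queries.fasta"),
      cleavage = paste0(out_prefix, "_cleavage.tsv"),
      truth = paste0(out_prefix, "_truth.tsv")
    )
    write_records_fasta(data$records, paths$fasta)
    qs <- Biostrings::AAStringSet(setNames(data$queries$sequence, data$queries$id))
    Biostrings::writeXStringSet(qs, paths$queries)
    readr::write_tsv(data$cleavage, paths$cleavage)
    readr::write_tsv(data$truth, paths$truth)
    data$paths <- paths
  }
  data
}

generate_core <- function(cfg) {
  ev <- evolve_core(cfg)
  n_true <- cfg$n_class1 + cfg$n_class2
  n_total <- n_true + cfg$n_decoy_no_signal + cfg$n_decoy_stop + cfg$n_decoy_unrelated
  ids <- sprintf("SYN%03d", seq_len(n_total))

  rows <- vector("list", n_total)
  idx <- 0L
  add_row <- function(genus, species, lineage, sequence, truth) {
    idx <<- idx + 1L
    rows[[idx]] <<- list(
      record = tibble(id = ids[idx], genus = genus, species = species,
                      lineage = lineage, sequence = sequence),
      truth = tibble(id = ids[idx], !!!truth)
    )
  }
  tax <- function(which) {
    if (which == 1L) {
      list(genus = cfg$genus_class1, species = cfg$species_class1,
           lineage = cfg$lineage_class1)
    } else {
      list(genus = cfg$genus_class2, species = cfg$species_class2,
           lineage = cfg$lineage_class2)
    }
  }
  for (m in ev$members) {
    t <- tax(if (identical(m$lineage, cfg$lineage_class1)) 1L else 2L)
    seq <- paste0("M", random_signal(cfg), m$mature_sequence)
    add_row(t$genus, t$species, t$lineage, seq, list(
      lineage = m$lineage, planted_motif = m$motif,
      cleavage_pos = cfg$signal_length + 1L,
      motif_planted = !identical(m$motif, "none"),
      anchor_positions = paste(m$anchors + cfg$signal_length, collapse = ";"),
      decoy_type = "none"
    ))
  }
  t1 <- tax(1L)
  # decoys lacking a signal peptide: Met followed directly by a polar residue
  for (i in seq_len(cfg$n_decoy_no_signal)) {
    body <- sample(AA19_NOCYS, cfg$mature_length, replace = TRUE)
    body[1] <- sample(POLAR, 1L)
    add_row(t1$genus, t1$species, t1$lineage, paste0("M", join_residues(body)), list(
      lineage = NA_character_, planted_motif = "none", cleavage_pos = NA_integer_,
      motif_planted = FALSE, anchor_positions = "", decoy_type = "no_signal"
    ))
  }
  # decoys with a stop codon inside the mature region
  for (i in seq_len(cfg$n_decoy_stop)) {
    anc <- ev$ancestors$anc1
    res <- mutate_body(anc$res, cfg$substitution_rate_within, anc$anchors)
    stop_at <- sample(2:length(res), 1L)
    res[stop_at] <- "*"
    seq <- paste0("M", random_signal(cfg), join_residues(res))
    add_row(t1$genus, t1$species, t1$lineage, seq, list(
      lineage = NA_character_, planted_motif = "none",
      cleavage_pos = cfg$signal_length + 1L,
      motif_planted = FALSE, anchor_positions = "", decoy_type = "stop"
    ))
  }
  # decoys with a valid signal but no homology to either lineage
  for (i in seq_len(cfg$n_decoy_unrelated)) {
    body <- sample(AA19_NOCYS, cfg$mature_length, replace = TRUE)
    body[1] <- sample(POLAR, 1L)
    seq <- paste0("M", random_signal(cfg), join_residues(body))
    add_row(t1$genus, t1$species, t1$lineage, seq, list(
      lineage = NA_character_, planted_motif = "none",
      cleavage_pos = cfg$signal_length + 1L,
      motif_planted = FALSE, anchor_positions = "", decoy_type = "unrelated"
    ))
  }

  records <- purrr::map_dfr(rows, "record")
  truth <- purrr::map_dfr(rows, "truth")
  cleavage <- truth |>
    filter(!is.na(.data$cleavage_pos)) |>
    select("id", mature_start = "cleavage_pos")
  queries <- tibble(
    id = c("QRY_L1", "QRY_L2"),
    class = c("A", "B"),
    lineage = c(cfg$lineage_class1, cfg$lineage_class2),
    sequence = unname(c(join_residues(ev$ancestors$anc1$res),
                        join_residues(ev$ancestors$anc2$res)))
  )
  list(records = records, truth = truth, cleavage = cleavage, queries = queries)
}

# FASTA with key=value header attributes, as produced for every record table
write_records_fasta <- function(records, path) {
  headers <- sprintf("%s genus=%s species=%s lineage=%s",
                     records$id, records$genus, records$species, records$lineage)
  x <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
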