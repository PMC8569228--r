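#' Configure an end-to-end classification run
#'
#' Bundles inputs, stage toggles and parameters for [run_pipeline()]. Inputs
#' come either from files (`fasta`, `cleavage`, `queries`) or from a
#' [synthetic_config()] whose generated dataset stands in for downloaded
#' transcriptome data. One invocation processes one dataset into one tree
#' (class A and class B data are two separate runs).
#'
#' @param out_dir Output directory (created if needed).
#' @param fasta,cleavage,queries,binding Input file paths: precursor FASTA,
#'   cleavage TSV (`id`, `mature_start`), query FASTA of characterized
#'   evasins, and optional binding-annotation TSV.
#' @param synthetic Optional [synthetic_config()]; when set, the dataset is
#'   generated first and its files become the inputs.
#' @param stages Stages to run, in order, from
#'   `c("ingest", "screen", "motifs", "align", "tree", "classify", "summarize")`.
#' @param provider Cleavage provider: `"heuristic"` or `"table"`.
#' @param scheme Class-labelling scheme, `"A"` or `"B"`.
#' @param evalue_threshold Homology-screen E-value threshold.
#' @param matrix Substitution matrix for screening and alignment.
#' @param bootstrap_reps Bootstrap replicates for edge support.
#' @param mature_fasta Pre-derived mature FASTA, needed only when both
#'   `ingest` and `screen` are disabled.
#' @param seed Top-level seed; every stochastic stage derives its own seed
#'   from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            fasta = NULL, cleavage = NULL, queries = NULL,
                            binding = NULL, synthetic = NULL,
                            stages = c("ingest", "screen", "motifs", "align",
                                       "tree", "classify", "summarize"),
                            provider = c("heuristic", "table"),
                            scheme = c("A", "B"),
                            evalue_threshold = 1e-4,
                            matrix = "BLOSUM62",
                            bootstrap_reps = 100,
                            mature_fasta = NULL,
                            seed = 1) {
  provider <- match.arg(provider)
  scheme <- match.arg(scheme)
  known <- c("ingest", "screen", "motifs", "align", "tree", "classify", "summarize")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")))
  structure(
    list(out_dir = out_dir, fasta = fasta, cleavage = cleavage,
         queries = queries, binding = binding, synthetic = synthetic,
         stages = stages, provider = provider, scheme = scheme,
         evalue_threshold = evalue_threshold, matrix = matrix,
         bootstrap_reps = bootstrap_reps, mature_fasta = mature_fasta,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the classification pipeline
#'
#' Executes the enabled stages in order — synthetic generation (when
#' configured), ingest and filtering, homology screen and deduplication,
#' motif profiling, progressive alignment, NJ tree with bootstrap support
#' and midpoint rooting, clade-based class assignment, and count summaries —
#' writing every artifact under `out_dir` plus a `manifest.json` with MD5
#' checksums. Reruns with the same config and seed reproduce identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  results <- list()
  enabled <- function(stage) stage %in% config$stages
  fail <- function(stage, msg) {
    abort(sprintf("Pipeline stage '%s' cannot run: %s", stage, msg))
  }

  fasta <- config$fasta
  cleavage <- config$cleavage
  queries_path <- config$queries
  if (!is.null(config$synthetic)) {
    syn <- generate_dataset(config$synthetic, out_prefix = out("synthetic"))
    results$synthetic <- syn
    for (p in unlist(syn$paths)) note(p)
    fasta <- syn$paths$fasta
    cleavage <- syn$paths$cleavage
    queries_path <- queries_path %||% syn$paths$queries
  }

  kept <- NULL
  if (enabled("ingest")) {
    if (is.null(fasta)) fail("ingest", "no input FASTA (set `fasta` or `synthetic`).")
    provider <- if (config$provider == "table") {
      if (is.null(cleavage)) fail("ingest", "table provider requires a cleavage TSV.")
      cleavage_table(cleavage)
    } else {
      cleavage_heuristic()
    }
    records <- read_protein_fasta(fasta) |>
      locate_protein_start() |>
      derive_mature(provider)
    flt <- filter_records(records)
    kept <- flt$kept
    readr::write_tsv(flt$dropped, out("dropped.tsv")); note(out("dropped.tsv"))
    results$ingest <- flt
  }

  if (enabled("screen")) {
    if (is.null(kept)) fail("screen", "no ingest output (enable 'ingest' or disable 'screen').")
    if (is.null(queries_path)) fail("screen", "no query FASTA provided.")
    qr <- read_protein_fasta(queries_path)
    queries <- tibble(id = qr$id, sequence = qr$raw_sequence)
    scr <- screen_candidates(kept, queries,
                             screen_config(matrix = config$matrix,
                                           evalue_threshold = config$evalue_threshold))
    kept <- kept |> filter(.data$id %in% scr$kept)
    dd <- deduplicate_records(kept)
    kept <- dd$distinct
    readr::write_tsv(scr$hits, out("best_hits.tsv")); note(out("best_hits.tsv"))
    readr::write_tsv(dd$collapse_map, out("collapse_map.tsv")); note(out("collapse_map.tsv"))
    results$screen <- list(hits = scr$hits, collapse_map = dd$collapse_map)
  }

  if (is.null(kept) && any(vapply(c("motifs", "align"), enabled, logical(1)))) {
    if (is.null(config$mature_fasta)) {
      fail("align", "no mature sequences: enable 'ingest' (and optionally 'screen') or set `mature_fasta`.")
    }
    mf <- read_protein_fasta(config$mature_fasta)
    kept <- mf |> mutate(mature_sequence = .data$raw_sequence, status = "ok")
  }

  if (!is.null(kept)) {
    mature_path <- out("mature.fasta")
    x <- Biostrings::AAStringSet(setNames(kept$mature_sequence, kept$id))
    Biostrings::writeXStringSet(x, mature_path); note(mature_path)
  }

  if (enabled("motifs")) {
    profiles <- profile_motifs(kept)
    readr::write_tsv(profiles, out("profiles.tsv")); note(out("profiles.tsv"))
    results$profiles <- profiles
  }

  msa <- NULL
  if (enabled("align")) {
    if (nrow(kept) < 2) fail("align", "fewer than 2 sequences survived the filters.")
    msa <- progressive_align(kept, matrix = config$matrix)
    write_msa_fasta(msa, out("aligned.fasta")); note(out("aligned.fasta"))
    results$msa <- msa
  }

  tree <- NULL
  if (enabled("tree")) {
    if (is.null(msa)) fail("tree", "no alignment (enable 'align').")
    D <- identity_distance(msa)
    readr::write_tsv(as_tibble(as.data.frame(D), rownames = "id"),
                     out("distances.tsv")); note(out("distances.tsv"))
    tree <- nj_tree(D) |> midpoint_root_tree()
    if (config$bootstrap_reps > 0 && nrow(msa) >= 4) {
      tree <- bootstrap_support(msa, tree, n_reps = config$bootstrap_reps,
                                seed = derive_seed(config$seed, 6L))
    }
    write_newick(tree, out("tree.nwk")); note(out("tree.nwk"))
    results$tree <- tree
  }

  partition <- NULL
  if (enabled("classify")) {
    if (is.null(tree)) fail("classify", "no tree (enable 'tree').")
    meta <- kept |> select("id", "genus", "species")
    partition <- assign_classes(tree, meta, scheme = config$scheme)
    readr::write_tsv(tidy(partition), out("assignments.tsv")); note(out("assignments.tsv"))
    readr::write_tsv(glance(partition), out("class_summary.tsv")); note(out("class_summary.tsv"))
    results$partition <- partition
  }

  if (enabled("summarize")) {
    if (is.null(partition)) fail("summarize", "no class assignments (enable 'classify').")
    counts <- species_class_counts(tidy(partition))
    readr::write_tsv(counts, out("class_counts.tsv")); note(out("class_counts.tsv"))
    results$counts <- counts
    if (!is.null(results$profiles)) {
      info <- heatmap_info(tidy(partition), results$profiles, config$binding)
      readr::write_tsv(info, out("heatmap_info.tsv")); note(out("heatmap_info.tsv"))
      results$heatmap_info <- info
    }
    if (!is.null(config$binding)) {
      bs <- binding_summary(tidy(partition), config$binding)
      readr::write_tsv(bs, out("binding_summary.tsv")); note(out("binding_summary.tsv"))
      results$binding <- bs
    }
  }

  manifest <- tibble(
    artifact = basename(artifacts),
    path = artifacts,
    md5 = unname(tools::md5sum(artifacts))
  ) |> arrange(.data$artifact)
  manifest_list <- list(
    package = "evasinclass",
    version = as.character(utils::packageVersion("evasinclass")),
    seed = config$seed,
    scheme = config$scheme,
    stages = config$stages,
    matrix = config$matrix,
    evalue_threshold = config$evalue_threshold,
    bootstrap_reps = config$bootstrap_reps,
    artifacts = setNames(as.list(manifest$md5), manifest$artifact)
  )
  jsonlite::write_json(manifest_list, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
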