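#' Read a chemokine-binding annotation table
#'
#' The binding table aggregates published biochemical data: one row per
#' evasin-chemokine pair with the chemokine class tag. Valid class tags are
#' CC, CXC, CX3C and XC. A small synthetic example table (ids matching the
#' synthetic generator, not real binding data) ships under
#' `inst/extdata/synthetic_binding_annotations.tsv`.
#'
#' @param path TSV with columns `id`, `chemokine`, `chemokine_class`.
#' @return Validated tibble.
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_binding_annotations.tsv",
#'                  package = "evasinclass")
#' read_binding_annotations(f)
read_binding_annotations <- function(path) {
  tab <- if (is.character(path)) readr::read_tsv(path, show_col_types = FALSE) else as_tibble(path)
  needed <- c("id", "chemokine", "chemokine_class")
  if (!all(needed %in% names(tab))) {
    abort(sprintf("Binding table needs columns: %s.", paste(needed, collapse = ", ")))
  }
  bad <- setdiff(unique(tab$chemokine_class), c("CC", "CXC", "CX3C", "XC"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown chemokine class tag(s): %s.", paste(bad, collapse = ", ")))
  }
  tab[, needed]
}

#' Count distinct records per species and class
#'
#' The per-species stacked-bar summary: distinct records per species per
#' class, plus lineage-level rollups.
#'
#' @param assignments Per-leaf assignment tibble (from
#'   [tidy.clade_partition()]) with `id`, `genus`, `species`, `lineage`,
#'   `class`.
#' @return Tibble with `level` (`"species"` or `"lineage"`), `group`,
#'   `class`, `n`.
#' @export
species_class_counts <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(level = character(), group = character(),
                  class = character(), n = integer()))
  }
  by_species <- assignments |>
    distinct(.data$id, .keep_all = TRUE) |>
    mutate(group = paste(.data$genus, .data$species)) |>
    count(.data$group, .data$class, name = "n") |>
    mutate(level = "species")
  by_lineage <- assignments |>
    distinct(.data$id, .keep_all = TRUE) |>
    count(group = .data$lineage, .data$class, name = "n") |>
    mutate(level = "lineage")
  bind_rows(by_species, by_lineage) |>
    select("level", "group", "class", "n")
}

#' Count distinct chemokines bound per species and lineage
#'
#' For each species (and lineage rollup), the number of distinct chemokines
#' bound by its characterized evasins, split by chemokine class. A chemokine
#' is counted once per group no matter how many evasins bind it; records
#' with no annotation contribute zero.
#'
#' @param assignments Per-leaf assignment tibble.
#' @param annotations Binding table from [read_binding_annotations()].
#' @return Tibble with `level`, `group`, `chemokine_class`, `n_chemokines`.
#' @export
binding_summary <- function(assignments, annotations) {
  annotations <- read_binding_annotations(annotations)
  joined <- assignments |>
    distinct(.data$id, .keep_all = TRUE) |>
    dplyr::inner_join(annotations, by = "id")
  if (nrow(joined) == 0) {
    return(tibble(level = character(), group = character(),
                  chemokine_class = character(), n_chemokines = integer()))
  }
  by_species <- joined |>
    mutate(group = paste(.data$genus, .data$species)) |>
    distinct(.data$group, .data$chemokine_class, .data$chemokine) |>
    count(.data$group, .data$chemokine_class, name = "n_chemokines") |>
    mutate(level = "species")
  by_lineage <- joined |>
    distinct(.data$lineage, .data$chemokine_class, .data$chemokine) |>
    count(group = .data$lineage, .data$chemokine_class, name = "n_chemokines") |>
    mutate(level = "lineage")
  bind_rows(by_species, by_lineage) |>
    select("level", "group", "chemokine_class", "n_chemokines")
}

#' Assemble the heatmap information table
#'
#' One row per record with the four annotation rings drawn around the
#' classification trees: lineage, motif presence, cysteine count, and the
#' number of distinct chemokines bound (NA for uncharacterized records).
#'
#' @param assignments Per-leaf assignment tibble.
#' @param profiles Motif profile tibble from [profile_motifs()].
#' @param annotations Optional binding table.
#' @return Tibble with `id`, `lineage`, `class`, motif flags, `cys_count`,
#'   `n_chemokines_bound`.
#' @export
heatmap_info <- function(assignments, profiles, annotations = NULL) {
  orphan <- c(setdiff(assignments$id, profiles$id), setdiff(profiles$id, assignments$id))
  if (length(orphan) > 0) {
    abort(sprintf("Ids present in only one input: %s.", paste(unique(orphan), collapse = ", ")))
  }
  out <- assignments |>
    select("id", "lineage", "class") |>
    left_join(profiles, by = "id")
  if (!is.null(annotations)) {
    annotations <- read_binding_annotations(annotations)
    nb <- annotations |>
      distinct(.data$id, .data$chemokine) |>
      count(.data$id, name = "n_chemokines_bound")
    out <- left_join(out, nb, by = "id")
  } else {
    out$n_chemokines_bound <- NA_integer_
  }
  out
}

#' Plot per-species class counts as stacked bars
#' @param counts Output of [species_class_counts()].
#' @param level `"species"` or `"lineage"`.
#' @return A ggplot.
#' @export
plot_class_counts <- function(counts, level = "species") {
  dat <- counts |> filter(.data$level == !!level)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Distinct records", fill = "Class") +
    ggplot2::theme_minimal()
}
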