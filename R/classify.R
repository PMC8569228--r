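#' Genus-to-lineage lookup table
#'
#' Built-in mapping of hard-tick genera to the two major ixodid lineages:
#' Ixodes is Prostriate; Amblyomma, Dermacentor, Hyalomma and Rhipicephalus
#' are Metastriate. Extend or override by passing a data frame (or TSV path)
#' with columns `genus`, `lineage`.
#'
#' @param extra Optional data frame or TSV path with additional mappings.
#' @return Tibble with `genus`, `lineage`.
#' @export
lineage_map <- function(extra = NULL) {
  base <- tibble(
    genus = c("Ixodes", "Amblyomma", "Dermacentor", "Hyalomma", "Rhipicephalus"),
    lineage = c("Prostriate", rep("Metastriate", 4))
  )
  if (is.null(extra)) return(base)
  if (is.character(extra)) extra <- readr::read_tsv(extra, show_col_types = FALSE)
  if (!all(c("genus", "lineage") %in% names(extra))) {
    abort("Lineage map extension needs columns `genus` and `lineage`.")
  }
  bind_rows(as_tibble(extra[, c("genus", "lineage")]), base) |>
    distinct(.data$genus, .keep_all = TRUE)
}

#' Look up the lineage of a tick genus
#'
#' Case-insensitive lookup; an unmapped genus is an explicit error (soft
#' ticks and unknown genera are never silently assigned).
#'
#' @param genus Character vector of genus names.
#' @param map A [lineage_map()].
#' @return Character vector of lineage labels.
#' @export
#' @examples
#' lineage_of("Ixodes") # "Prostriate"
lineage_of <- function(genus, map = lineage_map()) {
  idx <- match(tolower(genus), tolower(map$genus))
  if (anyNA(idx)) {
    abort(sprintf("Unmapped genus/genera: %s.",
                  paste(unique(genus[is.na(idx)]), collapse = ", ")))
  }
  map$lineage[idx]
}

#' Leaf sets of the two clades descending from the root
#'
#' The two nodes immediately following the ancestral (root) node define the
#' top-level classes; this returns their leaf sets, larger set first (ties
#' by lexicographically smallest leaf).
#'
#' @param tree A rooted `ape::phylo` (degree-2 root, e.g. from
#'   [midpoint_root_tree()]).
#' @return List of two character vectors of tip labels.
#' @export
root_partition <- function(tree) {
  if (!ape::is.rooted(tree)) {
    abort("Tree is unrooted; apply midpoint_root_tree() first.")
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(children) != 2) {
    abort("Root must have exactly two children.")
  }
  sets <- lapply(children, function(ch) {
    if (ch <= ntip) {
      tree$tip.label[ch]
    } else {
      tips <- ape::extract.clade(tree, ch)$tip.label
      tips
    }
  })
  sizes <- lengths(sets)
  if (sizes[1] < sizes[2] ||
      (sizes[1] == sizes[2] && min(sets[[2]]) < min(sets[[1]]))) {
    sets <- rev(sets)
  }
  sets
}

# majority lineage and purity of a leaf set
clade_composition <- function(leaves, meta, map) {
  lin <- lineage_of(meta$genus[match(leaves, meta$id)], map)
  tab <- sort(table(lin), decreasing = TRUE)
  list(
    majority = names(tab)[1],
    purity = as.numeric(tab[1]) / length(lin),
    lineages = lin
  )
}

#' Assign class labels from the root partition
#'
#' Implements the clade-based class definitions: the two clades descending
#' from the root are labelled by lineage majority. Under scheme `"A"` the
#' Metastriate-majority clade is A1 and the other A2 (class A evasins
#' separate perfectly by lineage, so a purity below 1 raises a warning);
#' under scheme `"B"` the same convention yields B1/B2, with mixed clades
#' permitted silently. If both clades share a majority lineage, the larger
#' clade takes the lower-numbered label.
#'
#' @param tree Rooted tree (or a precomputed two-set partition from
#'   [root_partition()]).
#' @param meta Metadata tibble with `id`, `genus` (and optionally `species`)
#'   covering every leaf.
#' @param scheme `"A"` or `"B"`.
#' @param map A [lineage_map()].
#' @return A `clade_partition` object: `assignments` (per-leaf tibble with
#'   `id`, `genus`, `lineage`, `class`), `summary` (per-class `n`, majority
#'   `lineage`, `purity`), and `scheme`.
#' @export
assign_classes <- function(tree, meta, scheme = c("A", "B"), map = lineage_map()) {
  scheme <- match.arg(scheme)
  sets <- if (is.list(tree) && !inherits(tree, "phylo")) tree else root_partition(tree)
  leaves <- unlist(sets)
  missing <- setdiff(leaves, meta$id)
  if (length(missing) > 0) {
    abort(sprintf("No metadata for leaf/leaves: %s.", paste(missing, collapse = ", ")))
  }
  comp <- lapply(sets, clade_composition, meta = meta, map = map)
  # clade order: Metastriate-majority first; same majority -> larger first
  metas_frac <- vapply(comp, function(cc) {
    mean(cc$lineages == "Metastriate")
  }, numeric(1))
  ord <- order(-metas_frac, -lengths(sets))
  sets <- sets[ord]; comp <- comp[ord]
  labels <- paste0(scheme, 1:2)
  if (scheme == "A") {
    for (k in 1:2) {
      if (comp[[k]]$purity < 1) {
        warn(sprintf("Clade %s is not lineage-pure (purity %.2f).",
                     labels[k], comp[[k]]$purity))
      }
    }
  }
  assignments <- purrr::map_dfr(1:2, function(k) {
    ids <- sets[[k]]
    tibble(
      id = ids,
      genus = meta$genus[match(ids, meta$id)],
      species = if ("species" %in% names(meta)) meta$species[match(ids, meta$id)] else NA_character_,
      lineage = comp[[k]]$lineages,
      class = labels[k]
    )
  })
  summary <- purrr::map_dfr(1:2, function(k) {
    tibble(class = labels[k], n = length(sets[[k]]),
           lineage = comp[[k]]$majority, purity = comp[[k]]$purity)
  })
  structure(
    list(assignments = assignments, summary = summary, scheme = scheme,
         tree = if (inherits(tree, "phylo")) tree else NULL),
    class = "clade_partition"
  )
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition: scheme %s, %d leaves>\n",
              x$scheme, nrow(x$assignments)))
  print(x$summary)
  invisible(x)
}

#' Split a clade into its two subclades
#'
#' The two nodes immediately following the node defining a clade partition
#' it into subclades (e.g. B1.1/B1.2). The leaf set must correspond exactly
#' to a clade of the tree.
#'
#' @param tree Rooted `ape::phylo`.
#' @param leaves Character vector of tip labels forming a clade.
#' @param label Parent clade label used to name the subclades `<label>.1`
#'   and `<label>.2`.
#' @param meta,map As in [assign_classes()]; used for the majority/size
#'   ordering convention. When `meta` is `NULL`, ordering is by size then
#'   lexicographic smallest leaf.
#' @return Named list of two leaf sets (`<label>.1`, `<label>.2`).
#' @export
subclade_partition <- function(tree, leaves, label = "B1", meta = NULL,
                               map = lineage_map()) {
  ntip <- length(tree$tip.label)
  if (length(leaves) < 2) {
    abort("Cannot split a singleton clade: it has no child clades.")
  }
  if (!all(leaves %in% tree$tip.label)) {
    abort("Some leaves are not in the tree.")
  }
  node <- ape::getMRCA(tree, leaves)
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  if (!setequal(clade_tips, leaves)) {
    abort("The leaf set is not a clade of the tree.")
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  sets <- lapply(children, function(ch) {
    if (ch <= ntip) tree$tip.label[ch] else ape::extract.clade(tree, ch)$tip.label
  })
  if (!is.null(meta)) {
    mfrac <- vapply(sets, function(s) {
      mean(lineage_of(meta$genus[match(s, meta$id)], map) == "Metastriate")
    }, numeric(1))
    ord <- order(-mfrac, -lengths(sets))
  } else {
    firsts <- vapply(sets, min, character(1))
    ord <- order(-lengths(sets), firsts)
  }
  sets <- sets[ord]
  setNames(sets, paste0(label, ".", 1:2))
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a clade partition into a per-leaf tibble
#' @param x A `clade_partition`.
#' @param ... Unused.
#' @return The per-leaf assignment tibble.
#' @exportS3Method generics::tidy
tidy.clade_partition <- function(x, ...) {
  x$assignments
}

#' One-row-per-class summary of a clade partition
#' @param x A `clade_partition`.
#' @param ... Unused.
#' @return Tibble with `class`, `n`, majority `lineage`, `purity`.
#' @exportS3Method generics::glance
glance.clade_partition <- function(x, ...) {
  x$summary
}

#' Plot class composition of a clade partition
#' @param object A `clade_partition`.
#' @param ... Unused.
#' @return A ggplot: stacked bars of lineage composition per class.
#' @exportS3Method ggplot2::autoplot
autoplot.clade_partition <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$class, fill = .data$lineage)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Class", y = "Members", fill = "Lineage") +
    ggplot2::theme_minimal()
}
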