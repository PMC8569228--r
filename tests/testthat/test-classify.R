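rooted_tree <- function(text) ape::read.tree(text = text)

meta_for <- function(ids, genera) {
  tibble::tibble(id = ids, genus = genera, species = "sp")
}

test_that("lineage lookup is case-insensitive and errors on unmapped genera", {
  expect_equal(lineage_of("Ixodes"), "Prostriate")
  expect_equal(lineage_of("ixodes"), "Prostriate")
  expect_equal(lineage_of("Rhipicephalus"), "Metastriate")
  expect_equal(lineage_of(c("Amblyomma", "Dermacentor", "Hyalomma")),
               rep("Metastriate", 3))
  # argasid (soft tick) genera are not silently assigned
  expect_error(lineage_of("Ornithodoros"), "Ornithodoros")
  custom <- lineage_map(tibble::tibble(genus = "Haemaphysalis", lineage = "Metastriate"))
  expect_equal(lineage_of("Haemaphysalis", custom), "Metastriate")
})

test_that("root partition returns the two child leaf sets, larger first", {
  tr <- rooted_tree("((A:1,B:1):1,(C:1,D:1):1);")
  sets <- root_partition(tr)
  expect_setequal(sets[[1]], c("A", "B")) # size tie: lexicographic smallest leaf
  expect_setequal(sets[[2]], c("C", "D"))

  tr2 <- rooted_tree("(A:1,(B:1,C:1):1);")
  sets2 <- root_partition(tr2)
  expect_setequal(sets2[[1]], c("B", "C"))
  expect_equal(sets2[[2]], "A")

  unrooted <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(root_partition(unrooted), "midpoint_root")
})

test_that("scheme A names the Metastriate-majority clade A1 and warns on impurity", {
  tr <- rooted_tree("((A:1,B:1):1,(C:1,D:1):1);")
  meta <- meta_for(c("A", "B", "C", "D"),
                   c("Rhipicephalus", "Amblyomma", "Ixodes", "Ixodes"))
  part <- assign_classes(tr, meta, scheme = "A")
  g <- glance(part)
  expect_equal(g$lineage[g$class == "A1"], "Metastriate")
  expect_equal(g$lineage[g$class == "A2"], "Prostriate")
  expect_equal(g$purity, c(1, 1))
  asn <- tidy(part)
  expect_setequal(asn$id[asn$class == "A1"], c("A", "B"))

  # a 60% Metastriate clade is still A1, but a warning reports the impurity
  tr2 <- rooted_tree("(((A:1,B:1):1,(E:1,(F:1,G:1):1):1):1,(C:1,D:1):1);")
  meta2 <- meta_for(c("A", "B", "C", "D", "E", "F", "G"),
                    c("Rhipicephalus", "Amblyomma", "Ixodes", "Ixodes",
                      "Rhipicephalus", "Ixodes", "Ixodes"))
  expect_warning(part2 <- assign_classes(tr2, meta2, scheme = "A"), "purity 0.60")
  g2 <- glance(part2)
  expect_equal(g2$purity[g2$class == "A1"], 0.6)
  expect_equal(g2$n[g2$class == "A1"], 5L)
})

test_that("scheme B uses the same majority convention without purity warnings", {
  tr <- rooted_tree("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  meta <- meta_for(c("A", "B", "C", "D", "E"),
                   c("Rhipicephalus", "Amblyomma", "Ixodes", "Ixodes", "Ixodes"))
  expect_no_warning(part <- assign_classes(tr, meta, scheme = "B"))
  g <- glance(part)
  expect_equal(g$class, c("B1", "B2"))
  expect_equal(g$lineage[g$class == "B1"], "Metastriate")
  expect_lt(g$purity[g$class == "B1"], 1)
})

test_that("classes partition the leaf set and are stable under input relabelling", {
  tr <- rooted_tree("((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  meta <- meta_for(c("A", "B", "C", "D", "E"),
                   c("Rhipicephalus", "Rhipicephalus", "Ixodes", "Ixodes", "Ixodes"))
  part <- assign_classes(tr, meta, scheme = "A")
  asn <- tidy(part)
  expect_setequal(asn$id, tr$tip.label)
  expect_equal(anyDuplicated(asn$id), 0L)
  expect_equal(sum(glance(part)$n), 5L)
  # same tree with permuted metadata rows: identical assignments
  part2 <- assign_classes(tr, meta[sample(5), ], scheme = "A")
  expect_equal(dplyr::arrange(tidy(part2), id), dplyr::arrange(asn, id))
})

test_that("unknown genera in the tree are reported as an error", {
  tr <- rooted_tree("((A:1,B:1):1,(C:1,D:1):1);")
  meta <- meta_for(c("A", "B", "C", "D"),
                   c("Rhipicephalus", "Ornithodoros", "Ixodes", "Ixodes"))
  expect_error(assign_classes(tr, meta, scheme = "A"), "Ornithodoros")
})

test_that("subclades split a clade at its defining node", {
  tr <- rooted_tree("(((p1:1,p2:1):1,(m1:1,m2:1):1):1,(x1:1,x2:1):1);")
  meta <- meta_for(c("p1", "p2", "m1", "m2", "x1", "x2"),
                   c("Ixodes", "Ixodes", "Rhipicephalus", "Amblyomma",
                     "Ixodes", "Ixodes"))
  sub <- subclade_partition(tr, c("p1", "p2", "m1", "m2"), label = "B1", meta = meta)
  expect_named(sub, c("B1.1", "B1.2"))
  expect_setequal(sub$B1.1, c("m1", "m2")) # Metastriate-majority side first
  expect_setequal(sub$B1.2, c("p1", "p2"))
  expect_error(subclade_partition(tr, "p1"), "singleton")
  expect_error(subclade_partition(tr, c("p1", "m1")), "not a clade")
})

test_that("autoplot produces a stacked composition plot", {
  tr <- rooted_tree("((A:1,B:1):1,(C:1,D:1):1);")
  meta <- meta_for(c("A", "B", "C", "D"),
                   c("Rhipicephalus", "Amblyomma", "Ixodes", "Ixodes"))
  part <- assign_classes(tr, meta, scheme = "A")
  p <- ggplot2::autoplot(part)
  expect_s3_class(p, "ggplot")
})
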