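write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA reading preserves order and parses header metadata", {
  f <- write_fasta_lines(c(
    ">X1 genus=Ixodes species=ricinus", "MKVACDE",
    ">X2", "mklv", # lower case is normalised
    ">X3 genus=Amblyomma species=cajennense lineage=Metastriate", "MAAAA"
  ))
  recs <- read_protein_fasta(f)
  expect_equal(recs$id, c("X1", "X2", "X3"))
  expect_equal(recs$genus[1], "Ixodes")
  expect_equal(recs$species[1], "ricinus")
  expect_true(is.na(recs$genus[2]))
  expect_equal(recs$lineage[3], "Metastriate")
  expect_equal(recs$raw_sequence[2], "MKLV")
})

test_that("malformed FASTA errors carry a line number; duplicates are listed", {
  bad <- write_fasta_lines(c("ACDE", ">X1", "MKV"))
  expect_error(read_protein_fasta(bad), "line 1")
  dup <- write_fasta_lines(c(">X1", "MKV", ">X1", "MAA"))
  expect_error(read_protein_fasta(dup), "X1")
  empty <- write_fasta_lines(character(0))
  expect_warning(recs <- read_protein_fasta(empty), "Empty")
  expect_equal(nrow(recs), 0L)
})

test_that("protein start follows the first-methionine rule", {
  f <- write_fasta_lines(c(">a", "GGMKLM", ">b", "MKV", ">c", "KKVV"))
  recs <- locate_protein_start(read_protein_fasta(f))
  expect_equal(recs$protein_start, c(3L, 1L, NA))
  expect_equal(recs$status, c("raw", "raw", "no_met"))
})

test_that("table provider sets mature coordinates; absent records lack a signal", {
  f <- write_fasta_lines(c(
    ">t1", paste0("M", strrep("L", 19), "CDEFGH"),
    ">t2", "MKVACDE"
  ))
  recs <- locate_protein_start(read_protein_fasta(f))
  prov <- cleavage_table(tibble::tibble(id = "t1", mature_start = 21))
  recs <- derive_mature(recs, prov)
  expect_equal(recs$mature_start[1], 21L)
  expect_equal(recs$mature_sequence[1], "CDEFGH")
  expect_equal(recs$status, c("ok", "no_signal"))
})

test_that("table positions are absolute even when the Met is internal", {
  f <- write_fasta_lines(c(">t1", paste0("GG", "M", strrep("V", 10), "ACD")))
  recs <- locate_protein_start(read_protein_fasta(f))
  recs <- derive_mature(recs, cleavage_table(tibble::tibble(id = "t1", mature_start = 14)))
  expect_equal(recs$mature_sequence[1], "ACD")
})

test_that("out-of-range cleavage offsets error", {
  f <- write_fasta_lines(c(">t1", "MKVACDE"))
  recs <- locate_protein_start(read_protein_fasta(f))
  expect_error(derive_mature(recs, cleavage_table(tibble::tibble(id = "t1", mature_start = 99))),
               "out of range")
})

test_that("heuristic provider recovers the generator's cleavage sites exactly", {
  cfg <- synthetic_config(n_class1 = 50, n_class2 = 50, motif_class1 = "cys6",
                          motif_class2 = "none", mature_length = 60,
                          n_decoy_no_signal = 0, n_decoy_stop = 0,
                          n_decoy_unrelated = 0, seed = 91)
  out <- generate_dataset(cfg)
  recs <- tibble::tibble(
    id = out$records$id, genus = out$records$genus,
    species = out$records$species, lineage = out$records$lineage,
    raw_sequence = out$records$sequence,
    protein_start = NA_integer_, mature_start = NA_integer_,
    mature_sequence = NA_character_, status = "raw"
  ) |> locate_protein_start() |> derive_mature(cleavage_heuristic())
  expect_equal(recs$mature_start, rep(cfg$signal_length + 1L, 100L))
})

test_that("filters partition records with one reason each and are idempotent", {
  cfg <- synthetic_config(n_class1 = 5, n_class2 = 5, seed = 37)
  out <- generate_dataset(cfg, withr::local_tempfile())
  recs <- read_protein_fasta(out$paths$fasta) |>
    locate_protein_start() |>
    derive_mature(cleavage_heuristic())
  flt <- suppressMessages(filter_records(recs))
  expect_equal(nrow(flt$kept) + nrow(flt$dropped), nrow(recs))
  # 10 true records + the unrelated decoy (removed later, by the screen)
  expect_equal(nrow(flt$kept), 11L)
  truth <- out$truth
  reasons <- dplyr::inner_join(flt$dropped, truth, by = "id")
  expect_equal(reasons$reason[reasons$decoy_type == "no_signal"], "no_signal")
  expect_equal(reasons$reason[reasons$decoy_type == "stop"], "internal_stop")
  # unrelated decoys pass ingest (they are removed later, by the screen)
  expect_true(all(truth$id[truth$decoy_type == "unrelated"] %in% flt$kept$id))
  # idempotence: filtering the kept set drops nothing
  again <- suppressMessages(filter_records(flt$kept))
  expect_equal(nrow(again$dropped), 0L)
  # kept mature sequences are clean
  expect_false(any(grepl("*", flt$kept$mature_sequence, fixed = TRUE)))
})

test_that("a stop codon upstream of the mature start does not drop a record", {
  f <- write_fasta_lines(c(">u1", paste0("MA*G", "M", strrep("L", 10), "ACDE")))
  recs <- locate_protein_start(read_protein_fasta(f))
  # first Met is position 1; table cleaves at the ACDE start
  recs <- derive_mature(recs, cleavage_table(tibble::tibble(id = "u1", mature_start = 16)))
  flt <- suppressMessages(filter_records(recs))
  expect_equal(nrow(flt$kept), 1L)
  expect_equal(flt$kept$mature_sequence, "ACDE")
})
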