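test_that("local alignment matches the matrix diagonal on identical sequences", {
  hit <- sw_align("CCK", "CCK")
  expect_equal(hit$score, 9 + 9 + 5) # BLOSUM62 C/C, C/C, K/K
  expect_equal(hit$a_start, 1L)
  expect_equal(hit$a_end, 3L)
})

test_that("all-mismatch sequences give score zero and an empty span", {
  hit <- sw_align("AAAA", "WWWW") # A/W scores negative throughout
  expect_equal(hit$score, 0)
  expect_true(is.na(hit$a_start))
  expect_equal(hit$a_aligned, "")
})

test_that("unknown residues error by name, or map to neutral scores on request", {
  expect_error(sw_align("ACDU", "ACD"), "U")
  hit <- sw_align("ACDU", "ACDU", map_unknown = TRUE)
  expect_equal(hit$score, 4 + 9 + 6) # U columns contribute 0
})

test_that("local alignment scores equal the brute-force DP oracle", {
  set.seed(42)
  cfg <- screen_config()
  for (rep in 1:80) {
    a <- random_seq(sample(5:30, 1))
    b <- random_seq(sample(5:30, 1))
    got <- sw_align(a, b, cfg)$score
    want <- oracle_local_score(a, b, blosum62, cfg$gap_open, cfg$gap_extend)
    expect_equal(got, want)
  }
})

test_that("local alignment score is symmetric", {
  set.seed(43)
  for (rep in 1:20) {
    a <- random_seq(20); b <- random_seq(25)
    expect_equal(sw_align(a, b)$score, sw_align(b, a)$score)
  }
})

test_that("Karlin-Altschul E-values follow the closed form", {
  cfg <- screen_config(search_space_m = 100, search_space_n = 100)
  expect_equal(karlin_evalue(50, cfg), 0.041 * 1e4 * exp(-0.267 * 50))
  # doubling n doubles E at fixed score
  expect_equal(karlin_evalue(30, cfg, n = 200), 2 * karlin_evalue(30, cfg))
  # monotone decreasing in score, limit 0
  expect_lt(karlin_evalue(60, cfg), karlin_evalue(50, cfg))
  expect_equal(karlin_evalue(1e6, cfg), 0)
})

test_that("screen keeps homologs, drops unrelated decoys, strict threshold", {
  set.seed(44)
  query <- random_seq(90)
  # a true homolog: the query with a handful of substitutions
  res <- strsplit(query, "")[[1]]
  idx <- sample(90, 5)
  res[idx] <- sample(setdiff(c("A", "G", "K"), res[idx]), 5, replace = TRUE)
  homolog <- paste(res, collapse = "")
  decoys <- vapply(1:50, function(i) random_seq(90), character(1))
  cand <- setNames(c(homolog, decoys), c("hom", sprintf("dec%02d", 1:50)))
  scr <- screen_candidates(cand, c(q1 = query), screen_config())
  expect_true("hom" %in% scr$kept)
  expect_false(any(startsWith(scr$kept, "dec")))
  # identical to a query: E effectively zero
  self <- screen_candidates(c(x = query), c(q1 = query))
  expect_equal(self$kept, "x")
  expect_lt(self$hits$evalue, 1e-50)
})

test_that("the E-value threshold boundary is strict and monotone", {
  # engineer a config where the candidate's E-value equals the threshold
  cand <- c(x = "CCKCCK")
  qry <- c(q = "CCKCCK")
  hit <- sw_align(cand[[1]], qry[[1]])
  at <- screen_config(evalue_threshold = hit$evalue)
  below <- screen_config(evalue_threshold = hit$evalue * 1.01)
  expect_equal(screen_candidates(cand, qry, at)$kept, character(0))
  expect_equal(screen_candidates(cand, qry, below)$kept, "x")
  # raising the threshold never shrinks the kept set
  set.seed(45)
  cands <- setNames(vapply(1:10, function(i) random_seq(40), character(1)),
                    paste0("c", 1:10))
  qs <- c(q = random_seq(40))
  kept_small <- screen_candidates(cands, qs, screen_config(evalue_threshold = 1e-6))$kept
  kept_large <- screen_candidates(cands, qs, screen_config(evalue_threshold = 1e2))$kept
  expect_true(all(kept_small %in% kept_large))
})

test_that("best hits carry the class of the best-scoring query", {
  scr <- screen_candidates(
    c(x = "CCKACDEFGHIKLMNP"),
    tibble::tibble(id = c("qa", "qb"),
                   class = c("A", "B"),
                   sequence = c("CCKACDEFGHIKLMNP", "WWWWYYYY")),
    screen_config(evalue_threshold = 1)
  )
  expect_equal(scr$hits$query, "qa")
  expect_equal(scr$hits$query_class, "A")
})

test_that("deduplication collapses identical mature sequences to the smallest id", {
  recs <- tibble::tibble(
    id = c("b2", "a1", "c3", "d4", "e5"),
    mature_sequence = c("AAA", "AAA", "AAA", "KKK", "LLL")
  )
  dd <- deduplicate_records(recs)
  expect_equal(sort(dd$distinct$id), c("a1", "d4", "e5"))
  expect_equal(dd$collapse_map$representative[dd$collapse_map$id == "c3"], "a1")
  # all-distinct input passes through
  uniq <- tibble::tibble(id = c("x", "y"), mature_sequence = c("AA", "AB"))
  expect_equal(deduplicate_records(uniq)$distinct, uniq)
})
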