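test_that("peptide-epitope overlap is quantified and classified", {
  catalog <- data.frame(protein_id = "P02662",
                        kind = c("IgE", "IgE"),
                        start = c(188L, 300L), end = c(207L, 320L),
                        stringsAsFactors = FALSE)
  m <- map_peptide_to_epitopes(list(protein_id = "P02662",
                                    start = 195L, end = 208L), catalog)
  expect_equal(nrow(m), 1L)  # the non-overlapping epitope is absent
  expect_equal(m$overlap_length, 13L)
  expect_equal(m$match_class, "partial")
  expect_equal(m$overlap_fraction_of_peptide, 13 / 14)

  # identical intervals are an exact match covering the whole peptide
  m <- map_peptide_to_epitopes(list(protein_id = "x", start = 10L, end = 20L),
                               data.frame(protein_id = "x", kind = "Tcell",
                                          start = 10L, end = 20L))
  expect_equal(m$overlap_length, 11L)
  expect_equal(m$match_class, "exact")

  m <- map_peptide_to_epitopes(list(protein_id = "x", start = 12L, end = 15L),
                               data.frame(protein_id = "x", kind = "Tcell",
                                          start = 10L, end = 20L))
  expect_equal(m$match_class, "peptide_within_epitope")
})

test_that("reference peptides recover their published epitope relations", {
  fx <- load_reference_data()
  ssn <- fx$is_peptides[fx$is_peptides$sequence == "SSNICNISCDK", ]
  m <- map_peptide_to_epitopes(ssn, fx$epitopes)
  tc <- m[m$kind == "Tcell", ]
  expect_equal(tc$epitope_start, 74L)
  expect_equal(tc$overlap_length, 4L)
  expect_equal(tc$match_class, "partial")
})

test_that("overlap length is bounded and matches never exceed the catalog", {
  fx <- load_reference_data()
  all_m <- map_all_epitopes(fx$is_peptides, fx$epitopes)
  expect_true(all(all_m$overlap_length >= 1L))
  expect_true(all(all_m$overlap_fraction_of_peptide > 0 &
                    all_m$overlap_fraction_of_peptide <= 1))
  pep_len <- nchar(all_m$peptide)
  epi_len <- all_m$epitope_end - all_m$epitope_start + 1L
  expect_true(all(all_m$overlap_length <= pmin(pep_len, epi_len)))
})

test_that("peptide-set comparison finds identity, containment and overlap", {
  a <- data.frame(sequence = "ABCDEF", protein_id = "p",
                  start = 1L, end = 6L, stringsAsFactors = FALSE)
  b <- data.frame(sequence = "CDE", protein_id = "p",
                  start = 3L, end = 5L, stringsAsFactors = FALSE)
  cmp <- compare_peptide_sets(a, b)
  expect_equal(nrow(cmp$containment), 1L)
  expect_equal(cmp$containment$direction, "b_within_a")
  expect_equal(nrow(cmp$identical), 0L)

  cmp <- compare_peptide_sets(data.frame(sequence = "AAAA"),
                              data.frame(sequence = "CCCC"))
  expect_equal(nrow(cmp$identical) + nrow(cmp$containment) +
                 nrow(cmp$overlapping), 0L)

  # coordinate overlap without substring relation
  a <- data.frame(sequence = "AACC", protein_id = "p", start = 1L, end = 4L)
  b <- data.frame(sequence = "CCGG", protein_id = "p", start = 3L, end = 6L)
  cmp <- compare_peptide_sets(a, b)
  expect_equal(nrow(cmp$overlapping), 1L)
})

test_that("set comparison is symmetric and self-comparison is identity", {
  fx <- load_reference_data()
  ab <- compare_peptide_sets(fx$is_peptides, fx$iv_peptides)
  ba <- compare_peptide_sets(fx$iv_peptides, fx$is_peptides)
  expect_equal(nrow(ab$identical), nrow(ba$identical))
  expect_equal(nrow(ab$containment), nrow(ba$containment))
  expect_equal(nrow(ab$overlapping), nrow(ba$overlapping))
  expect_setequal(paste(ab$containment$seq_a, ab$containment$seq_b),
                  paste(ba$containment$seq_b, ba$containment$seq_a))

  self <- compare_peptide_sets(fx$is_peptides, fx$is_peptides)
  expect_equal(nrow(self$identical), nrow(fx$is_peptides))
})
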