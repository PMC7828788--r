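test_that("trypsin rules honour the proline block and its exceptions", {
  expect_equal(find_cleavage_sites("AKPA", "trypsin"), integer(0))
  expect_equal(find_cleavage_sites("AKAA", "trypsin"), 2L)
  # the W-K-P exception restores the cut despite P1' = proline
  expect_equal(find_cleavage_sites("AWKPA", "trypsin"), 3L)
  # C-K-D blocks an otherwise valid tryptic site
  expect_equal(find_cleavage_sites("ACKDA", "trypsin"), integer(0))
  expect_error(find_cleavage_sites("AKAA", "papain"), "unknown enzyme")
})

test_that("digestion fragments tile the parent and respect the length filter", {
  d <- digest("AAAA", c("trypsin", "pepsin_ph2"), min_length = 1)
  expect_equal(nrow(d$fragments), 1L)
  expect_equal(d$fragments$sequence, "AAAA")
  expect_equal(d$fragments$start, 1L)
  expect_equal(d$fragments$end, 4L)

  d <- digest("AKRA", "trypsin", min_length = 1)
  expect_equal(d$fragments$sequence, c("AK", "R", "A"))
  expect_equal(d$cut_positions, c(2L, 3L))

  # a 9-mer survives the default >= 9 filter (boundary inclusive)
  d <- digest("AAAAKAAAAAAAAA", "trypsin", min_length = 9)
  expect_equal(d$fragments$sequence, c("AAAAK", "AAAAAAAAA"))
  expect_equal(d$survivors$sequence, "AAAAAAAAA")

  expect_error(digest("", "trypsin"), "empty")
})

test_that("the survivor CCTKPESER has no internal site under the default set", {
  enz <- screen_config()$enzyme_set
  sites <- unlist(lapply(enz, function(e) find_cleavage_sites("CCTKPESER", e)))
  expect_length(sites, 0L)
  expect_true(is_fixed_point("CCTKPESER", enz))
})

test_that("fixed-point detection matches its definition", {
  enz <- screen_config()$enzyme_set
  expect_true(is_fixed_point("SSNICNISCDK", enz))
  expect_false(is_fixed_point("AKA", "trypsin"))
  expect_true(is_fixed_point("A", enz))  # no bonds
  expect_error(is_fixed_point("", enz), "empty")
})

test_that("milk-protein digestion reproduces the reference survivor table", {
  fx <- load_reference_data()
  bosd4 <- fx$proteins[fx$proteins$id == "P00711", ]
  d <- digest(bosd4$sequence, screen_config()$enzyme_set, min_length = 9,
              parent_id = "P00711")
  expect_equal(d$survivors$sequence, c("DTQAIVQNNDSTE", "SSNICNISCDK"))
  expect_equal(d$survivors$start, c(56L, 88L))
  expect_equal(d$survivors$end, c(68L, 98L))
})

test_that("engine cut sets equal the brute-force oracle on random sequences", {
  set.seed(42)
  enzymes <- list_enzymes()
  for (i in seq_len(1000)) {
    s <- rand_seq(sample(2:50, 1))
    for (enz in enzymes) {
      expect_identical(find_cleavage_sites(s, enz), oracle_sites(s, enz),
                       label = sprintf("enzyme %s on %s", enz, s))
    }
  }
})

test_that("fragments always reconstruct the parent; counts match cut sites", {
  set.seed(7)
  enz <- list_enzymes()
  for (i in seq_len(200)) {
    s <- rand_seq(sample(2:80, 1))
    d <- digest(s, sample(enz, sample(1:3, 1)), min_length = 1)
    expect_equal(paste(d$fragments$sequence, collapse = ""), s)
    expect_equal(nrow(d$fragments), length(d$cut_positions) + 1L)
    expect_true(all(d$fragments$end - d$fragments$start + 1L ==
                      nchar(d$fragments$sequence)))
  }
})

test_that("adding an enzyme never removes a cut position (union semantics)", {
  set.seed(11)
  enz <- list_enzymes()
  for (i in seq_len(100)) {
    s <- rand_seq(sample(10:60, 1))
    subset <- sample(enz, 2)
    cuts_one <- digest(s, subset[1], min_length = 1)$cut_positions
    cuts_both <- digest(s, subset, min_length = 1)$cut_positions
    expect_true(all(cuts_one %in% cuts_both))
    # and the multi-enzyme cut set is exactly the union
    expect_setequal(cuts_both,
                    union(cuts_one,
                          digest(s, subset[2], min_length = 1)$cut_positions))
  }
})

test_that("all 24 reference survivors are fixed points of the default set", {
  fx <- load_reference_data()
  enz <- screen_config()$enzyme_set
  fixed <- vapply(fx$is_peptides$sequence, is_fixed_point, logical(1),
                  enzymes = enz)
  expect_true(all(fixed))
})
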